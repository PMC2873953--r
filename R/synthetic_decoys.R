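# -- synthetic decoy ensembles ------------------------------------------------
#
# Self-contained generator for end-to-end testing without structure
# downloads. The toy receptor is a Calpha+CB pseudo-atom chain folded as two
# packed helical segments whose gap forms a binding groove; the ligand is a
# helical Calpha chain seated in the groove. Receptor conformers emulate NMR
# ensemble variability by a hinge rotation between the two segments; decoys
# are rigid-body ligand poses with a planted near-native subpopulation on
# the bound conformer; pseudo-energies are negatively proportional to the
# number of recovered native residue-pair contacts plus Gaussian noise, a
# declared stand-in for an external rescoring function that is monotone in
# native-contact recovery by construction.

#' Configuration of the synthetic decoy generator
#'
#' @param seed integer master seed; every random draw in the generator flows
#'   from it.
#' @param receptor_length receptor residues (>= 7, default 60).
#' @param ligand_length ligand residues (>= 7, default 12).
#' @param n_conformers number of receptor conformers including the bound
#'   form (default 5); conformer "c0" is always the unmodified bound form.
#' @param decoys_per_conformer decoys generated per conformer (default 100).
#' @param near_native_fraction_bound fraction of the bound conformer's
#'   decoys drawn from the tight (near-native) pose distribution
#'   (default 0.15).
#' @param tight_sigma translation spread of tight poses, angstrom per
#'   component (default 1.5).
#' @param tight_angle_sigma rotation spread of tight poses, degrees
#'   (default 10).
#' @param hinge_angle_sigma inter-segment hinge rotation spread of unbound
#'   conformers, degrees (default 20).
#' @param jitter_sigma per-atom coordinate jitter of unbound conformers,
#'   angstrom (default 0.3).
#' @param n_surface_sites number of surface anchor sites per conformer over
#'   which loose poses are scattered (default 10). Rigid-body docking output
#'   is funneled into a limited number of favorable surface patches, so
#'   loose poses are drawn as a mixture over sites rather than uniformly
#'   over the whole shell; this is what makes decoy sets clusterable.
#' @param site_scatter_sigma within-site translation scatter of loose
#'   poses, angstrom per component (default 2).
#' @param site_angle_sigma within-site orientation scatter of loose poses,
#'   degrees (default 20).
#' @param contact_cutoff contact distance for synthetic structures,
#'   angstrom (default 6.0; pseudo-atom packing is sparser than all-atom, so
#'   the all-atom 3.9 A criterion is widened here).
#' @param energy_k energy gain per recovered native residue pair
#'   (default 5).
#' @param energy_sigma energy noise SD (default 8).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, receptor_length = 60L,
                             ligand_length = 12L, n_conformers = 5L,
                             decoys_per_conformer = 100L,
                             near_native_fraction_bound = 0.15,
                             tight_sigma = 1.5, tight_angle_sigma = 10,
                             hinge_angle_sigma = 20, jitter_sigma = 0.3,
                             n_surface_sites = 10L, site_scatter_sigma = 2,
                             site_angle_sigma = 20,
                             contact_cutoff = 6.0, energy_k = 5,
                             energy_sigma = 8) {
  stopifnot(receptor_length >= 7L, ligand_length >= 7L,
            near_native_fraction_bound >= 0, near_native_fraction_bound <= 1,
            tight_sigma > 0, tight_angle_sigma > 0, hinge_angle_sigma >= 0,
            n_surface_sites >= 1L, site_scatter_sigma > 0,
            contact_cutoff > 0, n_conformers >= 1L, decoys_per_conformer >= 1L)
  structure(list(
    seed = as.integer(seed), receptor_length = as.integer(receptor_length),
    ligand_length = as.integer(ligand_length),
    n_conformers = as.integer(n_conformers),
    decoys_per_conformer = as.integer(decoys_per_conformer),
    near_native_fraction_bound = near_native_fraction_bound,
    tight_sigma = tight_sigma, tight_angle_sigma = tight_angle_sigma,
    hinge_angle_sigma = hinge_angle_sigma, jitter_sigma = jitter_sigma,
    n_surface_sites = as.integer(n_surface_sites),
    site_scatter_sigma = site_scatter_sigma,
    site_angle_sigma = site_angle_sigma,
    contact_cutoff = contact_cutoff, energy_k = energy_k,
    energy_sigma = energy_sigma), class = "synthetic_config")
}

# ideal helix Calpha trace: rise 1.5 A/residue, radius 2.3 A, 100 deg/residue
helix_trace <- function(n, origin, direction = c(1, 0, 0), phase = 0,
                        radius = 2.3, rise = 1.5, turn_deg = 100) {
  direction <- direction / sqrt(sum(direction^2))
  # orthonormal frame perpendicular to the axis
  ref <- if (abs(direction[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u <- ref - sum(ref * direction) * direction
  u <- u / sqrt(sum(u^2))
  v <- c(direction[2] * u[3] - direction[3] * u[2],
         direction[3] * u[1] - direction[1] * u[3],
         direction[1] * u[2] - direction[2] * u[1])
  ang <- phase + (seq_len(n) - 1L) * turn_deg * pi / 180
  t(vapply(seq_len(n), function(i) {
    origin + (i - 1L) * rise * direction +
      radius * (cos(ang[i]) * u + sin(ang[i]) * v)
  }, numeric(3)))
}

rotation_about_axis <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c1 <- cos(angle_rad); s <- sin(angle_rad); c2 <- 1 - c1
  matrix(c(c1 + x * x * c2, x * y * c2 - z * s, x * z * c2 + y * s,
           y * x * c2 + z * s, c1 + y * y * c2, y * z * c2 - x * s,
           z * x * c2 - y * s, z * y * c2 + x * s, c1 + z * z * c2),
         3, 3, byrow = TRUE)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation_uniform <- function() {
  # uniform over SO(3) via a normalized Gaussian quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)),
         3, 3, byrow = TRUE)
}

synthetic_receptor_geometry <- function(receptor_length) {
  # two antiparallel helical segments 10.5 A apart, joined by a short loop;
  # the inter-segment gap is the binding groove
  n_loop <- 4L
  n_seg <- (receptor_length - n_loop) %/% 2L
  n_seg2 <- receptor_length - n_loop - n_seg
  span <- (n_seg - 1L) * 1.5
  seg1 <- helix_trace(n_seg, origin = c(0, 0, 0), direction = c(1, 0, 0))
  seg2 <- helix_trace(n_seg2, origin = c(span, 10.5, 0), direction = c(-1, 0, 0),
                      phase = pi)
  loop_from <- seg1[n_seg, ]
  loop_to <- seg2[1, ]
  loop <- t(vapply(seq_len(n_loop), function(i) {
    f <- i / (n_loop + 1L)
    loop_from + f * (loop_to - loop_from) + c(0, 0, 2 * sin(pi * f))
  }, numeric(3)))
  ca <- rbind(seg1, loop, seg2)
  # CB pseudo-atoms point radially away from the local segment axis
  seg_axis_point <- function(i) {
    if (i <= n_seg) c(ca[i, 1], 0, 0)
    else if (i > n_seg + n_loop) c(ca[i, 1], 10.5, 0)
    else ca[i, ] - c(0, 0, 1.5)
  }
  cb <- t(vapply(seq_len(receptor_length), function(i) {
    radial <- ca[i, ] - seg_axis_point(i)
    nr <- sqrt(sum(radial^2))
    if (nr < 1e-6) radial <- c(0, 0, 1) else radial <- radial / nr
    ca[i, ] + 1.5 * radial
  }, numeric(3)))
  list(ca = ca, cb = cb, n_seg = n_seg, n_loop = n_loop,
       hinge_point = ca[n_seg + n_loop %/% 2L, ],
       mobile = (n_seg + n_loop %/% 2L + 1L):receptor_length)
}

receptor_model_from_geometry <- function(geom, model_number = 1L) {
  n <- nrow(geom$ca)
  coords <- matrix(NA_real_, 2L * n, 3L)
  coords[seq(1L, 2L * n, by = 2L), ] <- geom$ca
  coords[seq(2L, 2L * n, by = 2L), ] <- geom$cb
  structure_from_coords(coords,
                        residue_index = rep(seq_len(n), each = 2L),
                        atom_name = rep(c("CA", "CB"), n),
                        chain_id = "R", model_number = model_number)
}

#' Generate the synthetic native receptor-ligand complex
#'
#' Builds the toy receptor (two packed helical segments, Calpha+CB) and
#' seats a helical Calpha ligand in the groove between the segments. The
#' construction is deterministic given `config$seed` and is validated to
#' form at least 10 native residue-pair contacts at the synthetic contact
#' cutoff.
#'
#' @param config a `synthetic_config`.
#' @return a `decoy_record` labeled `"native"` with conformer id `"c0"`.
#' @export
generate_complex <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  geom <- synthetic_receptor_geometry(config$receptor_length)
  receptor <- receptor_model_from_geometry(geom)
  span <- (geom$n_seg - 1L) * 1.5
  lig_span <- (config$ligand_length - 1L) * 1.5
  lig_origin <- c((span - lig_span) / 2, 5.25, 4.2)
  lig_ca <- helix_trace(config$ligand_length, origin = lig_origin,
                        direction = c(1, 0, 0), phase = -pi / 2)
  ligand <- structure_from_coords(lig_ca,
                                  residue_index = seq_len(config$ligand_length),
                                  atom_name = "CA", chain_id = "L")
  native <- decoy_record("native", receptor, ligand, "c0", "native", NA_real_)
  fp <- interaction_fingerprint(receptor, ligand, cutoff = config$contact_cutoff)
  if (length(fp$bits) < 10L) {
    stop(sprintf(paste0("synthetic native interface has only %d residue-pair ",
                        "contacts (< 10) at cutoff %.2f A; increase the cutoff ",
                        "or the ligand length"),
                 length(fp$bits), config$contact_cutoff), call. = FALSE)
  }
  native
}

#' Generate a receptor conformer ensemble from the bound form
#'
#' Each unbound conformer applies a random hinge rotation of the second
#' helical segment about the inter-segment loop plus small per-atom jitter,
#' emulating the backbone variability of an NMR ensemble. Conformer 1 in
#' the returned list is always the unmodified bound form ("c0").
#'
#' @param native_receptor the bound-form receptor `structure_model` (from
#'   [generate_complex()]).
#' @param n number of conformers including the bound form.
#' @param hinge_angle_sigma hinge angle SD in degrees.
#' @param jitter_sigma per-atom jitter SD in angstrom.
#' @param seed integer seed.
#' @return list of `structure_model`s with model numbers 1..n.
#' @export
generate_conformers <- function(native_receptor, n, hinge_angle_sigma = 20,
                                jitter_sigma = 0.3, seed = 1L) {
  set.seed(seed)
  n_res <- residue_count(native_receptor)
  geom <- synthetic_receptor_geometry(n_res)
  coords <- model_coords(native_receptor, "all")
  res_of_atom <- attr(coords, "residue_index")
  mobile_atoms <- res_of_atom %in% geom$mobile
  out <- vector("list", n)
  out[[1]] <- native_receptor
  out[[1]]$model_number <- 1L
  for (k in seq_len(n - 1L)) {
    angle <- stats::rnorm(1, 0, hinge_angle_sigma) * pi / 180
    rot <- rotation_about_axis(random_unit_vector(), angle)
    moved <- coords
    moved[mobile_atoms, ] <- sweep(
      sweep(coords[mobile_atoms, , drop = FALSE], 2, geom$hinge_point) %*% t(rot),
      2, geom$hinge_point, "+")
    if (jitter_sigma > 0) {
      moved <- moved + matrix(stats::rnorm(length(moved), 0, jitter_sigma),
                              ncol = 3L)
    }
    m <- native_receptor
    m$model_number <- k + 1L
    m$atoms$x <- moved[, 1]; m$atoms$y <- moved[, 2]; m$atoms$z <- moved[, 3]
    out[[k + 1L]] <- m
  }
  out
}

place_ligand <- function(native_lig_coords, rotation, centroid_target) {
  cen <- colMeans(native_lig_coords)
  sweep(sweep(native_lig_coords, 2, cen) %*% t(rotation), 2,
        centroid_target, "+")
}

#' Generate a labeled, scored decoy ensemble over receptor conformers
#'
#' Bound-conformer ("c0") decoys are labeled `"b"` and mix tight poses
#' (small rigid perturbations of the native ligand pose, the planted
#' near-native subpopulation) with loose poses placed uniformly on a shell
#' around the receptor; all other conformers yield `"a"` decoys with loose
#' poses only. Pseudo-energies are
#' `E = -energy_k * (native residue pairs recovered) + energy_sigma * noise`,
#' so planted near-native decoys form the low-energy tail.
#'
#' @param conformers list of receptor conformers from
#'   [generate_conformers()] (element 1 = bound form).
#' @param native the native `decoy_record` from [generate_complex()].
#' @param config a `synthetic_config`.
#' @return list with `decoys` (list of `decoy_record`), `truth` (data.frame
#'   decoy_id, conformer_id, label, planted, shared_native_bits,
#'   true_ligand_rmsd, plus the applied rigid transform r11..r33, t1..t3)
#'   and `native_fp` (the native `ifp` at the synthetic cutoff).
#' @export
generate_decoys <- function(conformers, native, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1000L)
  lig0 <- model_coords(native$ligand, "all")
  n_l <- config$ligand_length
  n_r <- config$receptor_length
  native_fp <- interaction_fingerprint(native$receptor, native$ligand,
                                       cutoff = config$contact_cutoff,
                                       receptor_length = n_r,
                                       ligand_length = n_l)
  nat_rec_ca <- model_coords(native$receptor, "CA")
  decoys <- list()
  rows <- list()
  for (ci in seq_along(conformers)) {
    receptor <- conformers[[ci]]
    conformer_id <- paste0("c", ci - 1L)
    label <- if (ci == 1L) "b" else "a"
    rc <- model_coords(receptor, "all")
    r_cen <- colMeans(rc)
    # receptor superposition onto the native frame, shared by all decoys of
    # this conformer, for the ground-truth ligand RMSD
    conf_fit <- kabsch_superpose(model_coords(receptor, "CA"), nat_rec_ca)
    # per-conformer surface anchor sites emulating non-native docking
    # funnels: loose poses are a mixture over sites with within-site
    # scatter. The loose population is by definition the non-native
    # background (near-native content is modeled only by the planted tight
    # subpopulation), so anchors avoid native-interface residues.
    # every conformer carries n_surface_sites pose funnels in total; on the
    # bound conformer the native groove is one of them (the tight
    # subpopulation), leaving n_surface_sites - 1 background funnels
    n_tight_here <- if (ci == 1L) {
      round(config$near_native_fraction_bound * config$decoys_per_conformer)
    } else 0L
    n_sites <- max(1L, config$n_surface_sites - (n_tight_here > 0L))
    interface_res <- unique(native_fp$bits %/% n_l + 1L)
    rc_res <- attr(model_coords(receptor, "all"), "residue_index")
    candidate <- which(!rc_res %in% interface_res)
    site_anchor <- rc[sample(candidate, n_sites,
                             replace = length(candidate) < n_sites),
                      , drop = FALSE]
    site_rot <- lapply(seq_len(n_sites),
                       function(s) random_rotation_uniform())
    site_target <- t(apply(site_anchor, 1L, function(a) {
      outward <- a - r_cen
      nn <- sqrt(sum(outward^2))
      outward <- if (nn < 1e-6) random_unit_vector() else outward / nn
      a + outward * stats::runif(1, 2, 6)
    }))
    n_tight <- if (ci == 1L) {
      round(config$near_native_fraction_bound * config$decoys_per_conformer)
    } else 0L
    for (j in seq_len(config$decoys_per_conformer)) {
      tight <- j <= n_tight
      if (tight) {
        rot <- rotation_about_axis(
          random_unit_vector(),
          stats::rnorm(1, 0, config$tight_angle_sigma) * pi / 180)
        target <- colMeans(lig0) + stats::rnorm(3, 0, config$tight_sigma)
      } else {
        s <- sample.int(n_sites, 1L)
        rot <- rotation_about_axis(
          random_unit_vector(),
          stats::rnorm(1, 0, config$site_angle_sigma) * pi / 180) %*%
          site_rot[[s]]
        target <- site_target[s, ] +
          stats::rnorm(3, 0, config$site_scatter_sigma)
      }
      lig_coords <- place_ligand(lig0, rot, target)
      ligand <- structure_from_coords(lig_coords,
                                      residue_index = seq_len(n_l),
                                      atom_name = "CA", chain_id = "L")
      fp <- interaction_fingerprint(receptor, ligand,
                                    cutoff = config$contact_cutoff,
                                    receptor_length = n_r, ligand_length = n_l)
      shared <- length(intersect_sorted(fp$bits, native_fp$bits))
      energy <- -config$energy_k * shared +
        stats::rnorm(1, 0, config$energy_sigma)
      id <- sprintf("%s_d%03d", conformer_id, j)
      dec <- decoy_record(id, receptor, ligand, conformer_id, label, energy)
      decoys[[length(decoys) + 1L]] <- dec
      rows[[length(rows) + 1L]] <- data.frame(
        decoy_id = id, conformer_id = conformer_id, label = label,
        planted = if (tight) "tight" else "loose",
        shared_native_bits = shared, energy = energy,
        true_ligand_rmsd = coord_rmsd(apply_transform(conf_fit, lig_coords),
                                      lig0),
        r11 = rot[1, 1], r12 = rot[1, 2], r13 = rot[1, 3],
        r21 = rot[2, 1], r22 = rot[2, 2], r23 = rot[2, 3],
        r31 = rot[3, 1], r32 = rot[3, 2], r33 = rot[3, 3],
        t1 = target[1], t2 = target[2], t3 = target[3],
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(decoys = decoys, truth = truth, native_fp = native_fp)
}

#' Generate a complete synthetic ensemble in one call
#'
#' Runs [generate_complex()], [generate_conformers()] and
#' [generate_decoys()] with seeds derived from `config$seed`.
#'
#' @param config a `synthetic_config`.
#' @return list with `config`, `native` (`decoy_record`), `conformers`,
#'   `decoys`, `truth` and `native_fp` (see [generate_decoys()]).
#' @export
simulate_ensemble <- function(config = synthetic_config()) {
  native <- generate_complex(config)
  conformers <- generate_conformers(native$receptor, config$n_conformers,
                                    hinge_angle_sigma = config$hinge_angle_sigma,
                                    jitter_sigma = config$jitter_sigma,
                                    seed = config$seed + 500L)
  gen <- generate_decoys(conformers, native, config)
  c(list(config = config, native = native, conformers = conformers), gen)
}
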