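# -- end-to-end decoy analysis workflows --------------------------------------

#' Combine receptor and ligand models into one complex model
#'
#' @param receptor,ligand `structure_model` objects with distinct chain ids.
#' @return a `structure_model` holding both chains.
#' @export
combine_chains <- function(receptor, ligand) {
  if (any(unique(receptor$atoms$chain_id) %in% unique(ligand$atoms$chain_id))) {
    stop("receptor and ligand chain ids overlap", call. = FALSE)
  }
  at <- rbind(receptor$atoms, ligand$atoms)
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  structure(list(model_number = receptor$model_number, atoms = at),
            class = "structure_model")
}

#' Compute interaction fingerprints for a decoy set
#'
#' One fingerprint per decoy over a common bit universe fixed by the
#' receptor and ligand residue counts.
#'
#' @param decoys list of `decoy_record` objects.
#' @param cutoff contact cutoff in angstrom.
#' @param receptor_length,ligand_length bit-universe dimensions; default
#'   taken from the first decoy.
#' @return named list of `ifp` objects (names = decoy ids).
#' @export
decoy_fingerprints <- function(decoys, cutoff = 3.90,
                               receptor_length = residue_count(decoys[[1]]$receptor),
                               ligand_length = residue_count(decoys[[1]]$ligand)) {
  fps <- lapply(decoys, function(d) {
    interaction_fingerprint(d$receptor, d$ligand, cutoff = cutoff,
                            receptor_length = receptor_length,
                            ligand_length = ligand_length)
  })
  names(fps) <- vapply(decoys, function(d) d$decoy_id, character(1))
  fps
}

#' Cluster a pooled decoy set by fingerprint or RMSD distance
#'
#' Builds the pairwise distance matrix (1 - Tanimoto over fingerprints, or
#' receptor-anchored ligand-CA RMSD), runs UPGMA and applies the requested
#' cut. For fingerprint distances a similarity threshold t is supplied as
#' `threshold = t` and cut at height 1 - t; for RMSD the threshold is the
#' cut height itself.
#'
#' @param decoys list of `decoy_record` objects.
#' @param fps named list of `ifp` (required for `distance = "ifp"`).
#' @param distance `"ifp"` or `"rmsd"`.
#' @param threshold similarity (ifp) or RMSD (rmsd) threshold; exactly one
#'   of `threshold` and `k` must be given.
#' @param k number of groups.
#' @param reference_receptor common frame for RMSD distances (default the
#'   first decoy's receptor).
#' @param max_n safety cap on pooled matrix size (override deliberately for
#'   larger runs; pooled matrices are O(n^2)).
#' @return list with `assignment` (`cluster_assignment`), `tree`
#'   (`upgma_tree`) and `dist` (matrix).
#' @export
cluster_decoys <- function(decoys, fps = NULL,
                           distance = c("ifp", "rmsd"),
                           threshold = NULL, k = NULL,
                           reference_receptor = decoys[[1]]$receptor,
                           max_n = 20000L) {
  distance <- match.arg(distance)
  if (is.null(threshold) == is.null(k)) {
    stop("give exactly one of threshold= or k=", call. = FALSE)
  }
  if (length(decoys) > max_n) {
    stop(sprintf(paste0("pooled clustering of %d decoys exceeds max_n = %d; ",
                        "raise max_n explicitly or cluster per conformer"),
                 length(decoys), max_n), call. = FALSE)
  }
  ids <- vapply(decoys, function(d) d$decoy_id, character(1))
  d <- if (distance == "ifp") {
    if (is.null(fps)) stop("fps required for ifp distance", call. = FALSE)
    suppressWarnings(fingerprint_distance_matrix(fps[ids], ids))
  } else {
    pairwise_rmsd_matrix(decoys, reference_receptor)
  }
  tree <- upgma(d)
  assignment <- if (!is.null(k)) cut_into_k(tree, k) else {
    h <- if (distance == "ifp") 1 - threshold else threshold
    cut_at_height(tree, h)
  }
  list(assignment = assignment, tree = tree, dist = d)
}

#' Cluster each receptor conformer's decoys separately
#'
#' Runs UPGMA with a k-group cut within every conformer's decoy set and
#' pools the assignments with globally unique group ids (numbered in
#' conformer order). This is the workflow used for blind near-native group
#' discrimination: with c conformers it yields k * c groups.
#'
#' @inheritParams cluster_decoys
#' @param k groups per conformer.
#' @return a pooled `cluster_assignment` with attribute `conformer_of_group`
#'   (named character vector group_id -> conformer_id).
#' @export
cluster_per_conformer <- function(decoys, fps = NULL, k = 10L,
                                  distance = c("ifp", "rmsd")) {
  distance <- match.arg(distance)
  conf <- vapply(decoys, function(d) d$conformer_id, character(1))
  out <- NULL
  offset <- 0L
  conformer_of_group <- character(0)
  for (cid in unique(conf)) {
    sub <- decoys[conf == cid]
    kk <- min(k, length(sub))
    if (length(sub) == 1L) {
      a <- data.frame(decoy_id = sub[[1]]$decoy_id, group_id = 1L)
    } else {
      a <- cluster_decoys(sub, fps = fps, distance = distance, k = kk,
                          reference_receptor = sub[[1]]$receptor)$assignment
      a <- as.data.frame(a)[, c("decoy_id", "group_id")]
    }
    a$group_id <- a$group_id + offset
    conformer_of_group[as.character(sort(unique(a$group_id)))] <- cid
    offset <- offset + kk
    out <- rbind(out, a)
  }
  structure(out, class = c("cluster_assignment", "data.frame"),
            cut_type = "k_per_conformer", cut_value = k,
            conformer_of_group = conformer_of_group)
}

#' Blind vs native-informed near-native group discrimination
#'
#' The full discrimination workflow on a decoy ensemble: fingerprints at the
#' given cutoff, per-conformer UPGMA with a k-group cut, group scorecards,
#' then near-native group selection both blind (lowest mean energy; no
#' native knowledge) and native-informed (highest mean S_frac). The
#' agreement flag records whether the two modes select the same group.
#'
#' @param decoys list of `decoy_record`s with energies.
#' @param native_fp native fingerprint over the same universe.
#' @param fps optional precomputed fingerprints (names = decoy ids).
#' @param cutoff contact cutoff used when `fps` is NULL.
#' @param k groups per conformer (default 10).
#' @param distance `"ifp"` or `"rmsd"` clustering distance.
#' @return list with `scorecards`, `assignment`, `blind_group`,
#'   `sfrac_group`, `agreement`, `blind_members` (decoy ids).
#' @export
discriminate_near_native <- function(decoys, native_fp, fps = NULL,
                                     cutoff = 3.90, k = 10L,
                                     distance = c("ifp", "rmsd")) {
  distance <- match.arg(distance)
  if (is.null(fps)) {
    fps <- decoy_fingerprints(decoys, cutoff = cutoff,
                              receptor_length = native_fp$receptor_length,
                              ligand_length = native_fp$ligand_length)
  }
  energies <- decoy_energies(decoys)
  labels <- vapply(decoys, function(d) d$label, character(1))
  names(labels) <- names(energies)
  assignment <- cluster_per_conformer(decoys, fps = fps, k = k,
                                      distance = distance)
  scorecards <- score_groups(assignment, fps, native_fp, energies, labels)
  blind <- find_near_native_group(scorecards, "by_energy")
  informed <- find_near_native_group(scorecards, "by_s_frac")
  list(scorecards = scorecards, assignment = assignment,
       blind_group = blind, sfrac_group = informed,
       agreement = identical(blind, informed),
       blind_members = assignment$decoy_id[assignment$group_id == blind])
}

#' Per-group energy-SD profile over threshold cuts, fingerprint vs RMSD
#'
#' Pools all decoys, builds one UPGMA tree on 1 - Tanimoto distances and
#' one on ligand-RMSD distances, cuts each tree at every requested
#' threshold (Tanimoto similarity t is cut at height 1 - t; RMSD thresholds
#' are cut heights directly), and reports the mean and SD of the per-group
#' energy SDs at each cut (groups of size >= 2). Smaller mean SD = more
#' energy-uniform groups. The defaults are the canonical threshold sets for
#' this analysis: Tc 0.6/0.8/0.9 and RMSD 3/5/8/10 angstrom.
#'
#' @param decoys list of `decoy_record`s with energies.
#' @param fps named list of `ifp` objects.
#' @param tc_thresholds Tanimoto similarity thresholds.
#' @param rmsd_thresholds RMSD cut heights in angstrom.
#' @param reference_receptor common frame for the RMSD matrix.
#' @return data.frame with one row per (method, threshold): method,
#'   threshold, n_groups, n_groups_ge2, mean_group_sd, sd_group_sd.
#' @export
group_sd_threshold_profile <- function(decoys, fps,
                                       tc_thresholds = c(0.6, 0.8, 0.9),
                                       rmsd_thresholds = c(3, 5, 8, 10),
                                       reference_receptor = decoys[[1]]$receptor) {
  energies <- decoy_energies(decoys)
  ids <- vapply(decoys, function(d) d$decoy_id, character(1))
  d_ifp <- suppressWarnings(fingerprint_distance_matrix(fps[ids], ids))
  d_rmsd <- pairwise_rmsd_matrix(decoys, reference_receptor)
  tree_ifp <- upgma(d_ifp)
  tree_rmsd <- upgma(d_rmsd)
  one_cut <- function(tree, method, threshold, height) {
    st <- group_energy_stats(cut_at_height(tree, height), energies)
    data.frame(method = method, threshold = threshold,
               n_groups = st$summary$n_groups,
               n_groups_ge2 = st$summary$n_groups_ge2,
               mean_group_sd = st$summary$mean_sd,
               sd_group_sd = st$summary$sd_sd)
  }
  rows <- c(
    lapply(tc_thresholds, function(t) one_cut(tree_ifp, "ifp", t, 1 - t)),
    lapply(rmsd_thresholds, function(t) one_cut(tree_rmsd, "rmsd", t, t)))
  do.call(rbind, rows)
}

#' Compare per-group energy uniformity of fingerprint vs RMSD clustering
#'
#' Convenience wrapper around [group_sd_threshold_profile()] for a single
#' threshold per method (the canonical example pair Tc 0.8 and 8 angstrom).
#'
#' @inheritParams group_sd_threshold_profile
#' @param tc_threshold Tanimoto similarity threshold (cut height 1 - t).
#' @param rmsd_threshold RMSD cut height in angstrom.
#' @return data.frame with one row per method: method, threshold, n_groups,
#'   n_groups_ge2, mean_group_sd, sd_group_sd.
#' @export
compare_group_energy_uniformity <- function(decoys, fps, tc_threshold = 0.8,
                                            rmsd_threshold = 8,
                                            reference_receptor = decoys[[1]]$receptor) {
  group_sd_threshold_profile(decoys, fps, tc_thresholds = tc_threshold,
                             rmsd_thresholds = rmsd_threshold,
                             reference_receptor = reference_receptor)
}
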