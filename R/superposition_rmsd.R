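# -- rigid-body superposition and ligand RMSD ---------------------------------

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rotation + translation of `mobile` onto `reference` via SVD
#' of the covariance matrix, with the usual determinant sign correction so
#' the returned rotation is proper (no reflection).
#'
#' @param mobile,reference n-by-3 coordinate matrices, n >= 3, paired row by
#'   row, non-degenerate (not all collinear).
#' @return list with `rotation` (3x3, det +1), `translation` (length-3) such
#'   that `mobile %*% t(rotation) + translation` best fits `reference`, and
#'   `rmsd` (angstrom) after fitting.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L || ncol(reference) != 3L) {
    stop("coordinate sets must be equal-length n x 3 matrices", call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points for superposition", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  x <- sweep(mobile, 2, cm); y <- sweep(reference, 2, cr)
  # collinearity check: rank of centered mobile must exceed 1
  sv_x <- svd(x, nu = 0, nv = 0)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1)) {
    stop("degenerate (collinear) point configuration", call. = FALSE)
  }
  h <- crossprod(x, y)                     # 3x3 covariance
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # y ~ x %*% t(rot)
  fitted <- x %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% t(rot)), rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param transform list with `rotation` and `translation` as returned by
#'   [kabsch_superpose()].
#' @param coords n-by-3 matrix.
#' @return transformed n-by-3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' Root-mean-square deviation between paired coordinate sets (no fitting)
#' @param a,b n-by-3 matrices paired row by row.
#' @return RMSD in angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3L, ncol(b) == 3L)
  sqrt(mean(rowSums((a - b)^2)))
}

decoy_ca_coords <- function(model, what) {
  m <- model_coords(model, what)
  if (nrow(m) == 0L) {
    stop(sprintf("no %s atoms found; cannot pair structures", what), call. = FALSE)
  }
  m
}

pair_ca_or_fail <- function(model_a, model_b, role) {
  ca_a <- decoy_ca_coords(model_a, "CA")
  ca_b <- decoy_ca_coords(model_b, "CA")
  if (nrow(ca_a) != nrow(ca_b)) {
    ra <- attr(ca_a, "residue_index"); rb <- attr(ca_b, "residue_index")
    stop(sprintf("%s CA pairing mismatch: %d vs %d residues (unpaired: %s)",
                 role, nrow(ca_a), nrow(ca_b),
                 paste(union(setdiff(ra, rb), setdiff(rb, ra)), collapse = ",")),
         call. = FALSE)
  }
  list(a = ca_a, b = ca_b)
}

#' Receptor-anchored ligand RMSD of a decoy against the native complex
#'
#' The decoy receptor is superposed onto the native receptor over the CA
#' atoms of all shared residues (positional pairing); the resulting transform
#' is applied to the decoy ligand and the RMSD over the selected ligand atoms
#' is reported without any further fitting. This is the standard
#' docking-decoy ligand-RMSD convention: the receptor frame is the anchor,
#' so the value measures the pose error of the ligand.
#'
#' @param decoy,native `decoy_record` objects (see [decoy_record()]) with
#'   identical ligand residue counts and receptors of equal residue counts.
#' @param atom_selection `"CA"` (default) or `"heavy"` ligand atoms.
#' @return ligand RMSD in angstrom.
#' @export
ligand_rmsd_to_native <- function(decoy, native, atom_selection = c("CA", "heavy")) {
  atom_selection <- match.arg(atom_selection)
  rec <- pair_ca_or_fail(decoy$receptor, native$receptor, "receptor")
  fit <- kabsch_superpose(rec$a, rec$b)
  lig_d <- model_coords(decoy$ligand, atom_selection)
  lig_n <- model_coords(native$ligand, atom_selection)
  if (nrow(lig_d) != nrow(lig_n)) {
    stop(sprintf("ligand %s-atom pairing mismatch: %d vs %d atoms",
                 atom_selection, nrow(lig_d), nrow(lig_n)), call. = FALSE)
  }
  coord_rmsd(apply_transform(fit, lig_d), lig_n)
}

#' Pairwise ligand-RMSD matrix of a decoy set in a common reference frame
#'
#' Each decoy's receptor is superposed (CA) onto `reference_receptor`, the
#' transform is applied to its ligand, and entries are the ligand-CA RMSD
#' between the mapped ligands of each decoy pair. Anchoring every decoy to
#' one declared reference conformer makes the matrix well-defined across
#' decoys built on different receptor conformers.
#'
#' @param decoys list of `decoy_record` objects (>= 2).
#' @param reference_receptor `structure_model` used as the common frame;
#'   default the first decoy's receptor.
#' @return symmetric RMSD matrix (angstrom) with decoy ids as dimnames.
#' @export
pairwise_rmsd_matrix <- function(decoys, reference_receptor = decoys[[1]]$receptor) {
  if (length(decoys) < 2L) stop("need at least 2 decoys", call. = FALSE)
  ids <- vapply(decoys, function(d) d$decoy_id, character(1))
  # decoys sharing a conformer_id share the receptor conformer by
  # definition, so the receptor superposition is computed once per conformer
  fit_cache <- new.env(parent = emptyenv())
  fit_for <- function(d) {
    key <- d$conformer_id
    if (is.null(fit_cache[[key]])) {
      rec <- pair_ca_or_fail(d$receptor, reference_receptor, "receptor")
      fit_cache[[key]] <- kabsch_superpose(rec$a, rec$b)
    }
    fit_cache[[key]]
  }
  mapped <- lapply(decoys, function(d) {
    apply_transform(fit_for(d), model_coords(d$ligand, "CA"))
  })
  nat <- nrow(mapped[[1]])
  for (m in mapped) {
    if (nrow(m) != nat) stop("ligand residue counts differ between decoys", call. = FALSE)
  }
  # RMSD between flattened poses: ||x_i - x_j|| / sqrt(n_atoms)
  flat <- t(vapply(mapped, function(m) as.numeric(m), numeric(3L * nat)))
  d <- as.matrix(stats::dist(flat)) / sqrt(nat)
  dimnames(d) <- list(ids, ids)
  d
}

#' Simplified GDT fraction curve between two conformations
#'
#' For each distance cutoff, rigid superpositions are seeded from every
#' contiguous 7-residue CA window (stride 1); each seed is iteratively
#' refit on the set of residues whose CA lies within the cutoff until that
#' set stops growing, and the curve reports the maximum residue fraction
#' over all seeds. This is a deterministic seed-and-extend approximation of
#' the global distance test used to compare conformations that differ by
#' large hinge motions; the full LGA search is intentionally not performed.
#' Fractions are reported as the running maximum over ascending cutoffs so
#' the curve is nondecreasing.
#'
#' @param model_a,model_b `structure_model` objects with equal residue
#'   counts and CA atoms present (>= 7 residues).
#' @param cutoffs ascending distance thresholds in angstrom.
#' @return data.frame with columns `cutoff` and `fraction`.
#' @export
gdt_fraction_curve <- function(model_a, model_b, cutoffs = c(1, 2, 4, 8)) {
  ca_a <- decoy_ca_coords(model_a, "CA")
  ca_b <- decoy_ca_coords(model_b, "CA")
  if (nrow(ca_a) != nrow(ca_b)) stop("residue counts differ", call. = FALSE)
  n <- nrow(ca_a)
  if (n < 7L) stop("need at least 7 residues for GDT windows", call. = FALSE)
  cutoffs <- sort(cutoffs)
  frac <- vapply(cutoffs, function(cut) {
    best <- 0L
    for (s in seq_len(n - 6L)) {
      sel <- s:(s + 6L)
      achieved <- 0L
      repeat {
        fit <- tryCatch(
          kabsch_superpose(ca_a[sel, , drop = FALSE], ca_b[sel, , drop = FALSE]),
          error = function(e) NULL)   # degenerate (collinear) seed: skip
        if (is.null(fit)) break
        moved <- apply_transform(fit, ca_a)
        within <- which(sqrt(rowSums((moved - ca_b)^2)) <= cut)
        achieved <- max(achieved, length(within))
        if (length(within) <= length(sel) || length(within) < 3L) break
        sel <- within
      }
      best <- max(best, achieved)
    }
    best / n
  }, numeric(1))
  data.frame(cutoff = cutoffs, fraction = cummax(frac))
}

#' Write a GDT curve as two-column TSV (cutoff, fraction)
#' @param curve data.frame from [gdt_fraction_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gdt_tsv <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
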