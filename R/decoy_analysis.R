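# -- discrimination of near-native decoy groups -------------------------------
#
# The discrimination logic works on two decoy populations: "a" decoys built
# on unbound receptor conformers and "b" decoys built on the bound-state
# conformer. On a similarity (or RMSD) axis, area I is the value range
# occupied only by b decoys, area II the overlap, and area III the range
# occupied only by a decoys. A grouping method discriminates well when b
# decoys with native-like poses end up in area I and when low-energy groups
# coincide with high native-recovery (S_frac) groups.

#' Classify decoy metric values into areas I / II / III
#'
#' Areas are defined by the raw population ranges, not histogram bins: with
#' a native-like-is-higher metric (Tanimoto similarity), a b decoy is in
#' area I when its value exceeds every a-decoy value, otherwise area II; an
#' a decoy is in area III when its value falls outside the whole b-decoy
#' range, otherwise area II. The orientation is mirrored for
#' native-like-is-lower metrics (RMSD). By construction a decoys are never
#' labeled I and b decoys never III.
#'
#' @param a_values,b_values numeric metric values of the two populations
#'   (both non-empty).
#' @param metric_orientation `"higher_is_nativelike"` (similarities) or
#'   `"lower_is_nativelike"` (RMSD).
#' @return list with `a_labels`, `b_labels` (character vectors in
#'   \{"I","II","III"\}) and `counts` (table of labels per population).
#' @export
classify_areas <- function(a_values, b_values,
                           metric_orientation = c("higher_is_nativelike",
                                                  "lower_is_nativelike")) {
  metric_orientation <- match.arg(metric_orientation)
  if (!length(a_values) || !length(b_values)) {
    stop("both decoy populations must be non-empty", call. = FALSE)
  }
  if (metric_orientation == "lower_is_nativelike") {
    a_values <- -a_values
    b_values <- -b_values
  }
  b_labels <- ifelse(b_values > max(a_values), "I", "II")
  a_labels <- ifelse(a_values < min(b_values) | a_values > max(b_values),
                     "III", "II")
  counts <- rbind(
    a = c(I = 0L, II = sum(a_labels == "II"), III = sum(a_labels == "III")),
    b = c(I = sum(b_labels == "I"), II = sum(b_labels == "II"), III = 0L))
  list(a_labels = a_labels, b_labels = b_labels, counts = counts,
       metric_orientation = metric_orientation)
}

#' Score decoy groups by energy and native recovery
#'
#' Per group: size, mean energy, mean per-member S_frac, the S_frac of the
#' union fingerprint (all residue pairs seen anywhere in the group), and the
#' fraction of members that are b decoys. Scorecards are sorted by mean
#' energy ascending, so the blind candidate group comes first.
#'
#' @param assignment a `cluster_assignment` (decoy_id, group_id).
#' @param fps named list of `ifp` objects (names = decoy ids).
#' @param native_fp native-complex fingerprint (popcount > 0).
#' @param energies named numeric vector of decoy energies.
#' @param labels optional named character vector of population labels
#'   ("a"/"b") for the b-fraction column.
#' @return data.frame with columns group_id, n_decoys, mean_energy,
#'   mean_s_frac, union_s_frac, b_fraction.
#' @export
score_groups <- function(assignment, fps, native_fp, energies, labels = NULL) {
  ids <- assignment$decoy_id
  miss <- setdiff(ids, names(fps))
  if (length(miss)) {
    stop(sprintf("missing fingerprint for decoy(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  miss_e <- setdiff(ids, names(energies))
  if (length(miss_e)) {
    stop(sprintf("missing energy for decoy(s): %s",
                 paste(utils::head(miss_e, 5), collapse = ", ")), call. = FALSE)
  }
  sf <- vapply(fps[ids], function(fp) s_frac(native_fp, fp), numeric(1))
  e <- energies[ids]
  gids <- sort(unique(assignment$group_id))
  rows <- lapply(gids, function(g) {
    sel <- assignment$group_id == g
    members <- ids[sel]
    union_bits <- sort(unique(unlist(lapply(fps[members], function(fp) fp$bits))))
    union_fp <- structure(list(receptor_length = native_fp$receptor_length,
                               ligand_length = native_fp$ligand_length,
                               bits = union_bits), class = "ifp")
    data.frame(
      group_id = g, n_decoys = sum(sel), mean_energy = mean(e[sel]),
      mean_s_frac = mean(sf[sel]),
      union_s_frac = s_frac(native_fp, union_fp),
      b_fraction = if (is.null(labels)) NA_real_ else
        mean(labels[members] == "b"))
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_energy, out$group_id), , drop = FALSE]
}

#' Pick the near-native group from a set of group scorecards
#'
#' Two modes: `by_s_frac` selects the group with the highest mean S_frac and
#' requires knowledge of the native complex (the evaluation mode);
#' `by_energy` selects the group with the lowest mean energy using only
#' energies and cluster structure, never the native fingerprint (the blind
#' prediction mode). Ties are broken by larger group size, then smaller
#' group id.
#'
#' @param scorecards data.frame from [score_groups()] (for `by_energy` the
#'   `mean_s_frac` column may be absent or NA).
#' @param mode `"by_s_frac"` or `"by_energy"`.
#' @return the selected `group_id`.
#' @export
find_near_native_group <- function(scorecards, mode = c("by_s_frac", "by_energy")) {
  mode <- match.arg(mode)
  if (!nrow(scorecards)) stop("no scorecards", call. = FALSE)
  key <- switch(mode,
                by_s_frac = scorecards$mean_s_frac,
                by_energy = -scorecards$mean_energy)
  o <- order(-key, -scorecards$n_decoys, scorecards$group_id)
  scorecards$group_id[o[1]]
}

#' Per-residue interaction frequency profile of a decoy group
#'
#' For each receptor residue, the fraction of group members whose
#' fingerprint sets any bit involving that residue. The profile of a native
#' singleton group is exactly the native contact indicator vector; darker
#' residues in an interface rendering correspond to values near 1.
#'
#' @param fps non-empty list of `ifp` objects over a common universe.
#' @return data.frame with columns residue_index (1..N receptor residues)
#'   and frequency in \[0, 1\].
#' @export
residue_interaction_frequency <- function(fps) {
  if (!length(fps)) stop("empty group", call. = FALSE)
  for (fp in fps) check_same_universe(fps[[1]], fp)
  n <- fps[[1]]$receptor_length
  l <- fps[[1]]$ligand_length
  counts <- integer(n)
  for (fp in fps) {
    res <- unique(fp$bits %/% l + 1L)
    counts[res] <- counts[res] + 1L
  }
  data.frame(residue_index = seq_len(n), frequency = counts / length(fps))
}

#' Write a residue interaction frequency profile as TSV
#' @param profile data.frame from [residue_interaction_frequency()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequency_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
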