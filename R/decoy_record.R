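# -- decoy records ------------------------------------------------------------

#' Construct a decoy record
#'
#' One candidate receptor-ligand complex: a receptor conformer plus a ligand
#' pose, labeled by the population it came from. Decoys built on the
#' bound-state receptor conformer are "b" decoys; decoys built on unbound
#' conformers are "a" decoys; the native complex itself is labeled "native".
#'
#' @param decoy_id unique identifier string.
#' @param receptor,ligand `structure_model` objects.
#' @param conformer_id identifier of the receptor conformer that produced
#'   this decoy.
#' @param label one of `"a"`, `"b"`, `"native"`.
#' @param energy interaction energy score (dimensionless, lower = better);
#'   may be NA until an energy-based analysis requires it.
#' @return a `decoy_record`.
#' @export
decoy_record <- function(decoy_id, receptor, ligand, conformer_id,
                         label = c("a", "b", "native"), energy = NA_real_) {
  label <- match.arg(label)
  stopifnot(inherits(receptor, "structure_model"),
            inherits(ligand, "structure_model"))
  structure(list(decoy_id = as.character(decoy_id), receptor = receptor,
                 ligand = ligand, conformer_id = as.character(conformer_id),
                 label = label, energy = as.numeric(energy)),
            class = "decoy_record")
}

#' @export
print.decoy_record <- function(x, ...) {
  cat(sprintf("<decoy_record> %s [%s] conformer %s, energy %s\n",
              x$decoy_id, x$label, x$conformer_id,
              ifelse(is.na(x$energy), "NA", format(x$energy, digits = 4))))
  invisible(x)
}

decoy_energies <- function(decoys) {
  e <- vapply(decoys, function(d) d$energy, numeric(1))
  names(e) <- vapply(decoys, function(d) d$decoy_id, character(1))
  e
}

#' Write a per-decoy energy table as TSV
#' @param decoys list of `decoy_record` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energies_tsv <- function(decoys, path) {
  tab <- data.frame(
    decoy_id = vapply(decoys, function(d) d$decoy_id, character(1)),
    conformer_id = vapply(decoys, function(d) d$conformer_id, character(1)),
    label = vapply(decoys, function(d) d$label, character(1)),
    energy = vapply(decoys, function(d) d$energy, numeric(1)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
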