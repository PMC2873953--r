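# -- interface contacts and interaction fingerprints --------------------------
#
# An interaction fingerprint (IFP) is a bit vector over the Cartesian product
# of receptor residues (1..N) x ligand residues (1..L): bit (r-1)*L + (l-1)
# is set iff residue pair (r, l) is in non-bonded heavy-atom contact. The
# universe is fixed by (N, L) for a whole receptor-ligand system, so
# fingerprints from decoys built on different receptor conformers remain
# directly comparable.

#' Detect non-bonded heavy-atom contacts across a receptor-ligand interface
#'
#' An atom-atom contact is any receptor heavy atom / ligand heavy atom pair
#' within `cutoff` angstrom (Euclidean distance, no lower bound, no atom-type
#' restriction; LIGPLOT's default non-bonded contact maximum of 3.90 A is the
#' default). Hydrogens are excluded. Atom contacts are aggregated into
#' residue pairs keyed by positional residue index.
#'
#' @param receptor,ligand `structure_model` objects.
#' @param cutoff contact distance cutoff in angstrom (> 0).
#' @return list with `contacts` (data.frame: receptor_residue_index,
#'   ligand_residue_index, atom_contact_count, min_distance, ordered by the
#'   index pair) and `total_atom_contacts` (integer).
#' @export
detect_nonbonded_contacts <- function(receptor, ligand, cutoff = 3.90) {
  stopifnot(cutoff > 0)
  rc <- model_coords(receptor, "heavy")
  lc <- model_coords(ligand, "heavy")
  if (nrow(rc) == 0L || nrow(lc) == 0L) {
    stop("empty heavy-atom set in receptor or ligand", call. = FALSE)
  }
  rres <- attr(rc, "residue_index")
  lres <- attr(lc, "residue_index")

  # exact all-pairs squared distances, chunked over receptor atoms to bound
  # memory; |x - y|^2 = |x|^2 + |y|^2 - 2 x.y
  cut2 <- cutoff^2
  l2 <- rowSums(lc^2)
  pairs_r <- integer(0); pairs_l <- integer(0); d2 <- numeric(0)
  chunk <- 2048L
  for (s in seq(1L, nrow(rc), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(rc))
    rr <- rc[s:e, , drop = FALSE]
    dm <- outer(rowSums(rr^2), l2, "+") - 2 * tcrossprod(rr, lc)
    hit <- which(dm <= cut2, arr.ind = TRUE)
    if (nrow(hit)) {
      pairs_r <- c(pairs_r, rres[s:e][hit[, 1]])
      pairs_l <- c(pairs_l, lres[hit[, 2]])
      d2 <- c(d2, pmax(dm[hit], 0))
    }
  }
  total <- length(pairs_r)
  if (total == 0L) {
    contacts <- data.frame(receptor_residue_index = integer(0),
                           ligand_residue_index = integer(0),
                           atom_contact_count = integer(0),
                           min_distance = numeric(0))
    return(list(contacts = contacts, total_atom_contacts = 0L))
  }
  key <- paste(pairs_r, pairs_l, sep = "\r")
  agg_count <- tapply(rep(1L, total), key, sum)
  agg_min <- tapply(sqrt(d2), key, min)
  uk <- names(agg_count)
  parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  contacts <- data.frame(
    receptor_residue_index = as.integer(parts[, 1]),
    ligand_residue_index = as.integer(parts[, 2]),
    atom_contact_count = as.integer(agg_count),
    min_distance = as.numeric(agg_min)
  )
  o <- order(contacts$receptor_residue_index, contacts$ligand_residue_index)
  contacts <- contacts[o, , drop = FALSE]
  rownames(contacts) <- NULL
  list(contacts = contacts, total_atom_contacts = as.integer(total))
}

#' Build a residue-pair interaction fingerprint from contacts
#'
#' One bit per residue pair over the fixed N x L universe; the bit for pair
#' (r, l) has index (r-1)*L + (l-1). Duplicate pairs collapse to one bit.
#'
#' @param contacts data.frame with columns receptor_residue_index and
#'   ligand_residue_index (as from [detect_nonbonded_contacts()]).
#' @param receptor_length,ligand_length residue counts N and L fixing the
#'   bit universe.
#' @return an `ifp` object: list(receptor_length, ligand_length, bits) where
#'   `bits` is a sorted integer vector of set 0-based bit indices.
#' @export
build_fingerprint <- function(contacts, receptor_length, ligand_length) {
  r <- contacts$receptor_residue_index
  l <- contacts$ligand_residue_index
  if (length(r) && (any(r < 1L | r > receptor_length) ||
                    any(l < 1L | l > ligand_length))) {
    stop(sprintf("contact residue index outside universe [1,%d]x[1,%d]",
                 receptor_length, ligand_length), call. = FALSE)
  }
  bits <- sort(unique((as.integer(r) - 1L) * as.integer(ligand_length) +
                        (as.integer(l) - 1L)))
  structure(list(receptor_length = as.integer(receptor_length),
                 ligand_length = as.integer(ligand_length),
                 bits = bits),
            class = "ifp")
}

#' Interaction fingerprint of a receptor-ligand complex
#'
#' Convenience wrapper: contact detection followed by fingerprint encoding,
#' with the bit universe taken from the residue counts of the two models
#' unless fixed explicitly (fix it when comparing decoys across receptor
#' conformers of unequal modeled length).
#'
#' @inheritParams detect_nonbonded_contacts
#' @param receptor_length,ligand_length bit-universe dimensions; default the
#'   models' residue counts.
#' @return an `ifp` object.
#' @export
interaction_fingerprint <- function(receptor, ligand, cutoff = 3.90,
                                    receptor_length = residue_count(receptor),
                                    ligand_length = residue_count(ligand)) {
  det <- detect_nonbonded_contacts(receptor, ligand, cutoff)
  build_fingerprint(det$contacts, receptor_length, ligand_length)
}

#' @export
print.ifp <- function(x, ...) {
  cat(sprintf("<ifp> universe %d x %d, %d set bits\n",
              x$receptor_length, x$ligand_length, length(x$bits)))
  invisible(x)
}

#' Number of set bits in a fingerprint
#' @param fp an `ifp`.
#' @return integer popcount.
#' @export
popcount <- function(fp) length(fp$bits)

check_same_universe <- function(fp_a, fp_b) {
  if (fp_a$receptor_length != fp_b$receptor_length ||
      fp_a$ligand_length != fp_b$ligand_length) {
    stop("fingerprints live in different bit universes", call. = FALSE)
  }
}

#' Tversky similarity between two interaction fingerprints
#'
#' S = c / (alpha * (a - c) + beta * (b - c) + c), with a and b the popcounts
#' of the two fingerprints and c the number of common set bits. alpha = beta
#' = 1 gives the Tanimoto index; alpha = 1, beta = 0 gives the native
#' recovery fraction c / a. When both fingerprints are empty the similarity
#' is defined as 0 (with a warning) so that distance matrices never contain
#' undefined entries.
#'
#' @param fp_a,fp_b `ifp` objects over the same universe.
#' @param alpha,beta weights in \[0, 1\] on the bits unique to `fp_a` and
#'   `fp_b` respectively.
#' @return similarity in \[0, 1\].
#' @export
tversky <- function(fp_a, fp_b, alpha = 1, beta = 1) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  check_same_universe(fp_a, fp_b)
  a <- length(fp_a$bits)
  b <- length(fp_b$bits)
  cc <- length(intersect_sorted(fp_a$bits, fp_b$bits))
  denom <- alpha * (a - cc) + beta * (b - cc) + cc
  if (denom == 0) {
    if (a == 0 && b == 0) {
      warning("both fingerprints empty; similarity defined as 0", call. = FALSE)
    }
    return(0)
  }
  cc / denom
}

intersect_sorted <- function(x, y) x[x %in% y]

#' Tanimoto index between two interaction fingerprints
#'
#' Tc = c / (a + b - c); the Tversky similarity at alpha = beta = 1.
#' Symmetric in its arguments.
#'
#' @inheritParams tversky
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) tversky(fp_a, fp_b, alpha = 1, beta = 1)

#' Native-recovery fraction S_frac
#'
#' The fraction of the native complex's contacting residue pairs recovered
#' by a decoy: c / a_native, i.e. the Tversky similarity at alpha = 1,
#' beta = 0 with the native fingerprint as the first query. Because the
#' native bit count is fixed, S_frac takes values on the discrete grid
#' 0, 1/a, 2/a, ..., 1.
#'
#' @param native_fp native-complex fingerprint (popcount must be > 0).
#' @param decoy_fp decoy fingerprint over the same universe.
#' @return S_frac in \[0, 1\].
#' @export
s_frac <- function(native_fp, decoy_fp) {
  if (length(native_fp$bits) == 0L) {
    stop("native fingerprint is empty; S_frac undefined", call. = FALSE)
  }
  tversky(native_fp, decoy_fp, alpha = 1, beta = 0)
}

fingerprint_bit_matrix <- function(fps) {
  # dense logical members-by-universe matrix; fine for desk-scale universes
  n <- length(fps)
  u <- fps[[1]]$receptor_length * fps[[1]]$ligand_length
  for (fp in fps) check_same_universe(fps[[1]], fp)
  m <- matrix(0L, n, u)
  for (i in seq_len(n)) if (length(fps[[i]]$bits)) m[i, fps[[i]]$bits + 1L] <- 1L
  m
}

#' Pairwise fingerprint distance matrix (1 - Tanimoto)
#'
#' @param fps list of `ifp` objects over a common universe.
#' @param ids optional decoy ids for dimnames (default fp1..fpn).
#' @return symmetric numeric matrix of Jaccard/Soergel distances
#'   1 - Tc with zero diagonal.
#' @export
fingerprint_distance_matrix <- function(fps, ids = NULL) {
  if (length(fps) < 2L) stop("need at least 2 fingerprints", call. = FALSE)
  if (is.null(ids)) ids <- paste0("fp", seq_along(fps))
  m <- fingerprint_bit_matrix(fps)
  pc <- rowSums(m)
  common <- tcrossprod(m)
  denom <- outer(pc, pc, "+") - common
  sim <- ifelse(denom == 0, 0, common / denom)  # both-empty pairs: similarity 0
  diag(sim) <- 1
  d <- 1 - sim
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  if (any(pc == 0)) {
    warning(sprintf("%d empty fingerprint(s); empty-empty pairs get distance 1",
                    sum(pc == 0)), call. = FALSE)
  }
  d
}

# -- fingerprint TSV interchange ----------------------------------------------

#' Write fingerprints to a TSV file
#'
#' One row per decoy with columns decoy_id, conformer_id, label, energy,
#' popcount and the semicolon-separated set-bit indices; a `#` header line
#' records the universe dimensions N and L.
#'
#' @param fps list of `ifp` objects.
#' @param path output path.
#' @param decoy_id,conformer_id,label,energy per-decoy metadata vectors
#'   (recycled defaults: fp1..fpn, NA, NA, NA).
#' @return `path`, invisibly.
#' @export
write_fingerprints_tsv <- function(fps, path, decoy_id = NULL,
                                   conformer_id = NA, label = NA,
                                   energy = NA) {
  n <- length(fps)
  if (is.null(decoy_id)) decoy_id <- paste0("fp", seq_len(n))
  for (fp in fps) check_same_universe(fps[[1]], fp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# receptor_length=%d ligand_length=%d",
                     fps[[1]]$receptor_length, fps[[1]]$ligand_length), con)
  writeLines("decoy_id\tconformer_id\tlabel\tenergy\tpopcount\tbits", con)
  conformer_id <- rep_len(conformer_id, n)
  label <- rep_len(label, n)
  energy <- rep_len(energy, n)
  for (i in seq_len(n)) {
    writeLines(paste(decoy_id[i], conformer_id[i], label[i],
                     ifelse(is.na(energy[i]), "NA", format(energy[i], digits = 10)),
                     length(fps[[i]]$bits),
                     paste(fps[[i]]$bits, collapse = ";"), sep = "\t"), con)
  }
  invisible(path)
}

#' Read fingerprints from a TSV file written by [write_fingerprints_tsv()]
#'
#' @param path input path.
#' @return list with `fps` (list of `ifp`) and `meta` (data.frame decoy_id,
#'   conformer_id, label, energy, popcount).
#' @export
read_fingerprints_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1]
  if (!grepl("^# receptor_length=\\d+ ligand_length=\\d+$", hdr)) {
    stop("missing universe header line in fingerprint TSV", call. = FALSE)
  }
  nl <- as.integer(regmatches(hdr, gregexpr("\\d+", hdr))[[1]])
  tab <- utils::read.delim(text = lines[-1], stringsAsFactors = FALSE,
                           colClasses = c(bits = "character"))
  fps <- lapply(tab$bits, function(b) {
    bits <- if (is.na(b) || !nzchar(b)) integer(0) else
      as.integer(strsplit(b, ";", fixed = TRUE)[[1]])
    structure(list(receptor_length = nl[1], ligand_length = nl[2],
                   bits = bits), class = "ifp")
  })
  list(fps = fps, meta = tab[, c("decoy_id", "conformer_id", "label",
                                 "energy", "popcount")])
}

#' Write a distance matrix as square TSV with id header row and column
#' @param d symmetric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix_tsv()]
#' @param path input path.
#' @return symmetric numeric matrix with ids as dimnames.
#' @export
read_distance_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}
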