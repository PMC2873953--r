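# -- PDB fixed-column coordinate I/O ------------------------------------------
#
# A structure model is a plain S3 list:
#   $model_number : integer >= 1
#   $atoms        : data.frame with one row per atom, columns
#                   serial, atom_name, element, alt_loc, residue_name,
#                   chain_id, residue_seq, insertion_code, x, y, z,
#                   occupancy, is_hydrogen, residue_index
# residue_index is the positional 1-based index of the residue within its
# chain (contiguous 1..N per chain), independent of author numbering and
# insertion codes; all contact/RMSD math downstream keys on it, so
# author-numbering gaps never break residue pairing.

TWO_LETTER_ELEMENTS <- c(
  "FE", "MG", "ZN", "MN", "CU", "NI", "CO", "SE", "BR", "CL", "NA", "CD", "HG"
)

infer_element <- function(name_field) {
  # name_field is the raw 4-character atom-name field (PDB columns 13-16).
  stripped <- gsub("[0-9' ]", "", name_field)
  if (!nzchar(stripped)) return("")
  first_raw <- substr(name_field, 1L, 1L)
  up <- toupper(stripped)
  if (substr(up, 1L, 1L) %in% c("H", "D", "Q")) {
    # hydrogens (incl. deuterium / NMR pseudo-atoms); metals like HG only
    # occur in HETATM records, which are handled before element inference
    if (first_raw != " " && up %in% TWO_LETTER_ELEMENTS && nchar(stripped) == 2L) {
      return(up)
    }
    return("H")
  }
  if (first_raw != " " && nchar(up) >= 2L && substr(up, 1L, 2L) %in% TWO_LETTER_ELEMENTS) {
    return(substr(up, 1L, 2L))
  }
  substr(up, 1L, 1L)
}

parse_coord_line <- function(line, lineno) {
  if (nchar(line) < 54L) {
    stop(sprintf("malformed ATOM/HETATM record at line %d: expected at least 54 columns, got %d",
                 lineno, nchar(line)), call. = FALSE)
  }
  num <- function(a, b) {
    v <- suppressWarnings(as.numeric(substr(line, a, b)))
    if (is.na(v)) {
      stop(sprintf("malformed numeric field in columns %d-%d at line %d", a, b, lineno),
           call. = FALSE)
    }
    v
  }
  occ_str <- trimws(substr(line, 55L, 60L))
  elem_str <- trimws(substr(line, 77L, 78L))
  name_field <- substr(line, 13L, 16L)
  element <- toupper(elem_str)
  if (!nzchar(element)) element <- infer_element(name_field)
  list(
    record = substr(line, 1L, 6L),
    serial = as.integer(num(7L, 11L)),
    atom_name = trimws(name_field),
    name_field = name_field,
    alt_loc = sub(" ", "", substr(line, 17L, 17L)),
    residue_name = trimws(substr(line, 18L, 20L)),
    chain_id = substr(line, 22L, 22L),
    residue_seq = as.integer(num(23L, 26L)),
    insertion_code = sub(" ", "", substr(line, 27L, 27L)),
    x = num(31L, 38L), y = num(39L, 46L), z = num(47L, 54L),
    occupancy = if (nzchar(occ_str)) as.numeric(occ_str) else 1.0,
    element = element
  )
}

finalize_model <- function(rows, model_number) {
  at <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      serial = r$serial, atom_name = r$atom_name, element = r$element,
      alt_loc = r$alt_loc, residue_name = r$residue_name,
      chain_id = r$chain_id, residue_seq = r$residue_seq,
      insertion_code = r$insertion_code,
      x = r$x, y = r$y, z = r$z, occupancy = r$occupancy,
      stringsAsFactors = FALSE
    )
  }))
  # alt-loc resolution: within one residue keep, for each atom name, the
  # highest-occupancy conformation; ties go to the first encountered
  key <- paste(at$chain_id, at$residue_seq, at$insertion_code, at$atom_name, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -at$occupancy,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain_id, at$residue_seq, at$insertion_code,
                             at$atom_name, sep = "\r")), , drop = FALSE]
  at <- at[order(match(paste(at$chain_id, at$residue_seq, at$insertion_code, sep = "\r"),
                       unique(paste(at$chain_id, at$residue_seq, at$insertion_code, sep = "\r"))),
                 at$serial), , drop = FALSE]
  rownames(at) <- NULL
  at$is_hydrogen <- at$element %in% c("H", "D")
  at$residue_index <- residue_positional_index(at)
  structure(list(model_number = model_number, atoms = at),
            class = "structure_model")
}

residue_positional_index <- function(atoms) {
  idx <- integer(nrow(atoms))
  for (ch in unique(atoms$chain_id)) {
    sel <- atoms$chain_id == ch
    rk <- paste(atoms$residue_seq[sel], atoms$insertion_code[sel], sep = "\r")
    idx[sel] <- match(rk, unique(rk))
  }
  idx
}

#' Parse a PDB-format coordinate file into structure models
#'
#' Reads fixed-column PDB v3 coordinate records. Multi-model files (NMR
#' ensembles delimited by MODEL/ENDMDL) yield one structure model per MODEL
#' block; a file without MODEL records yields a single model. Water HETATM
#' records are skipped; other HETATM residues are kept only when they carry a
#' CA atom (modified residues inside a polymer chain). Hydrogens are parsed
#' and flagged, with the element inferred from the atom-name columns when the
#' element field is blank. Alternate locations are resolved to the
#' highest-occupancy conformation, ties broken by first occurrence.
#'
#' @param text character: PDB file content, either a single string or a
#'   vector of lines.
#' @return list of `structure_model` objects, one per MODEL.
#' @seealso [read_pdb()], [write_pdb()], [select_model_chain()]
#' @export
parse_pdb <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  rec <- substr(text, 1L, 6L)
  models <- list()
  current <- list()
  current_number <- NA_integer_
  in_model <- FALSE
  seen_model_records <- FALSE
  n_atom_lines <- 0L

  for (i in seq_along(text)) {
    r <- rec[i]
    if (r == "MODEL ") {
      if (in_model) stop("unbalanced MODEL records: MODEL before ENDMDL", call. = FALSE)
      in_model <- TRUE
      seen_model_records <- TRUE
      current_number <- suppressWarnings(as.integer(trimws(substr(text[i], 7L, 14L))))
      if (is.na(current_number)) current_number <- length(models) + 1L
      current <- list()
    } else if (r == "ENDMDL") {
      if (!in_model) stop("unbalanced MODEL records: ENDMDL without MODEL", call. = FALSE)
      in_model <- FALSE
      if (length(current)) {
        models[[length(models) + 1L]] <- finalize_model(current, current_number)
      }
      current <- list()
    } else if (r == "ATOM  " || r == "HETATM") {
      a <- parse_coord_line(text[i], i)
      if (r == "HETATM") {
        if (a$residue_name %in% c("HOH", "WAT", "DOD")) next
      }
      n_atom_lines <- n_atom_lines + 1L
      current[[length(current) + 1L]] <- c(a, list(is_het = r == "HETATM"))
    }
  }
  if (in_model) stop("unbalanced MODEL records: file ends inside a MODEL block", call. = FALSE)
  if (!seen_model_records) {
    if (length(current)) models[[1L]] <- finalize_model(current, 1L)
  } else if (length(current)) {
    # coordinate records outside MODEL blocks in a multi-model file
    stop("ATOM records outside MODEL/ENDMDL in a multi-model file", call. = FALSE)
  }
  if (n_atom_lines == 0L) stop("no ATOM records found", call. = FALSE)

  # drop HETATM residues without a CA atom (ions, cofactors); keep modified
  # residues embedded in the polymer
  models <- lapply(models, drop_nonpolymer_het)
  models
}

drop_nonpolymer_het <- function(model) {
  at <- model$atoms
  # a residue is polymer-like if it contains a CA atom or came from ATOM
  # records; parse stage only tags HETATMs implicitly via residue names not
  # found with CA
  reskey <- paste(at$chain_id, at$residue_seq, at$insertion_code, sep = "\r")
  has_ca <- tapply(at$atom_name == "CA", reskey, any)
  standard <- !(at$residue_name %in% HET_NONPOLYMER) | has_ca[reskey]
  at <- at[standard, , drop = FALSE]
  rownames(at) <- NULL
  at$residue_index <- residue_positional_index(at)
  model$atoms <- at
  model
}

HET_NONPOLYMER <- c("CA", "ZN", "MG", "NA", "CL", "K", "SO4", "PO4", "GOL",
                    "EDO", "ACT", "HEM", "NAG", "MAN", "ADP", "ATP", "GTP", "GDP")

#' Read a PDB file from disk
#'
#' @param path path to a PDB coordinate file.
#' @return list of `structure_model` objects (see [parse_pdb()]).
#' @export
read_pdb <- function(path) {
  parse_pdb(readLines(path, warn = FALSE))
}

#' Select one model and one chain from a parsed PDB ensemble
#'
#' @param models list of structure models as returned by [parse_pdb()].
#' @param model_number the MODEL number to select.
#' @param chain_id single-character chain identifier.
#' @return a `structure_model` restricted to the requested chain, with
#'   `residue_index` renumbered 1..N.
#' @export
select_model_chain <- function(models, model_number, chain_id) {
  nums <- vapply(models, function(m) m$model_number, integer(1))
  k <- match(model_number, nums)
  if (is.na(k)) {
    stop(sprintf("model %s not found; available models: %s", model_number,
                 paste(nums, collapse = ", ")), call. = FALSE)
  }
  m <- models[[k]]
  chains <- unique(m$atoms$chain_id)
  if (!chain_id %in% chains) {
    stop(sprintf("chain '%s' not found in model %s; available chains: %s",
                 chain_id, model_number, paste(chains, collapse = ", ")),
         call. = FALSE)
  }
  at <- m$atoms[m$atoms$chain_id == chain_id, , drop = FALSE]
  rownames(at) <- NULL
  at$residue_index <- residue_positional_index(at)
  structure(list(model_number = m$model_number, atoms = at),
            class = "structure_model")
}

#' Number of residues in a structure model
#' @param model a `structure_model`.
#' @return integer residue count (across all chains).
#' @export
residue_count <- function(model) {
  length(unique(paste(model$atoms$chain_id, model$atoms$residue_index, sep = "\r")))
}

#' Coordinate matrix of a structure model
#'
#' @param model a `structure_model`.
#' @param selection `"all"`, `"heavy"` (non-hydrogen) or `"CA"`.
#' @return numeric matrix with one row per atom and columns x, y, z; the
#'   `residue_index` attribute maps rows to residues.
#' @export
model_coords <- function(model, selection = c("all", "heavy", "CA")) {
  selection <- match.arg(selection)
  at <- model$atoms
  keep <- switch(selection,
                 all = rep(TRUE, nrow(at)),
                 heavy = !at$is_hydrogen,
                 CA = at$atom_name == "CA" & !at$is_hydrogen)
  m <- as.matrix(at[keep, c("x", "y", "z")])
  rownames(m) <- NULL
  attr(m, "residue_index") <- at$residue_index[keep]
  m
}

format_pdb_atom_name <- function(name, element) {
  # element symbols of one letter start in column 14; longer names and
  # two-letter elements start in column 13
  if (nchar(name) >= 4L) return(substr(sprintf("%-4s", name), 1L, 4L))
  if (nchar(element) == 2L || nchar(name) == 0L) {
    sprintf("%-4s", name)
  } else {
    sprintf(" %-3s", name)
  }
}

#' Write a structure model (or list of models) as a PDB file
#'
#' Emits canonical fixed-column PDB v3 records with a TER record per chain,
#' and MODEL/ENDMDL blocks when more than one model is given. Coordinates are
#' written with 3 decimals, so a parse/write round trip is stable from the
#' first rewrite onward.
#'
#' @param model a `structure_model` or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  models <- if (inherits(model, "structure_model")) list(model) else model
  multi <- length(models) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    if (!inherits(m, "structure_model")) stop("expected structure_model objects", call. = FALSE)
    if (multi) writeLines(sprintf("MODEL %8d", m$model_number), con)
    at <- m$atoms
    if (any(at$serial > 99999L)) {
      stop("atom serial exceeds 99999; not encodable in fixed-column PDB", call. = FALSE)
    }
    serial <- 0L
    for (ch in unique(at$chain_id)) {
      rows <- which(at$chain_id == ch)
      for (i in rows) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial,
          format_pdb_atom_name(at$atom_name[i], at$element[i]),
          ifelse(nzchar(at$alt_loc[i]), at$alt_loc[i], " "),
          at$residue_name[i], at$chain_id[i], at$residue_seq[i],
          ifelse(nzchar(at$insertion_code[i]), at$insertion_code[i], " "),
          at$x[i], at$y[i], at$z[i], at$occupancy[i], 0,
          at$element[i]), con)
      }
      last <- rows[length(rows)]
      serial <- serial + 1L
      writeLines(sprintf("TER   %5d      %3s %s%4d", serial,
                         at$residue_name[last], ch, at$residue_seq[last]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  at <- x$atoms
  chains <- unique(at$chain_id)
  cat(sprintf("<structure_model> model %d: %d atoms, %d chain(s)\n",
              x$model_number, nrow(at), length(chains)))
  for (ch in chains) {
    sel <- at$chain_id == ch
    cat(sprintf("  chain %s: %d residues, %d atoms\n", ch,
                length(unique(at$residue_index[sel])), sum(sel)))
  }
  invisible(x)
}

#' Construct a structure model from coordinates
#'
#' Convenience builder used by the synthetic decoy generator and by tests: a
#' single-chain model from a coordinate matrix, one or more atoms per
#' residue.
#'
#' @param coords numeric n-by-3 matrix of atom positions (angstrom).
#' @param residue_index integer vector (length n) of 1-based positional
#'   residue indices, contiguous per chain.
#' @param atom_name character vector of atom names (default "CA").
#' @param chain_id single character chain id.
#' @param residue_name 3-letter residue name recycled over atoms.
#' @param model_number model number.
#' @return a `structure_model`.
#' @export
structure_from_coords <- function(coords, residue_index,
                                  atom_name = "CA", chain_id = "A",
                                  residue_name = "ALA", model_number = 1L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, length(residue_index) == nrow(coords))
  if (any(diff(unique(residue_index)) != 1L) || residue_index[1] != 1L) {
    stop("residue_index must be contiguous and start at 1", call. = FALSE)
  }
  n <- nrow(coords)
  atom_name <- rep_len(atom_name, n)
  at <- data.frame(
    serial = seq_len(n), atom_name = atom_name,
    element = substr(atom_name, 1L, 1L), alt_loc = "",
    residue_name = rep_len(residue_name, n), chain_id = chain_id,
    residue_seq = residue_index, insertion_code = "",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, stringsAsFactors = FALSE
  )
  at$is_hydrogen <- at$element %in% c("H", "D")
  at$residue_index <- as.integer(residue_index)
  structure(list(model_number = as.integer(model_number), atoms = at),
            class = "structure_model")
}
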