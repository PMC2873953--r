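# Independent reference implementations and fixture builders used across the
# test files. These deliberately take different computational routes from the
# package code they check.

# brute-force all-pairs contact detection: scalar double loop over atoms
brute_force_contacts <- function(receptor, ligand, cutoff) {
  rc <- model_coords(receptor, "heavy")
  lc <- model_coords(ligand, "heavy")
  rres <- attr(rc, "residue_index")
  lres <- attr(lc, "residue_index")
  total <- 0L
  pairs <- list()
  for (i in seq_len(nrow(rc))) {
    for (j in seq_len(nrow(lc))) {
      dij <- sqrt(sum((rc[i, ] - lc[j, ])^2))
      if (dij <= cutoff) {
        total <- total + 1L
        key <- paste(rres[i], lres[j])
        prev <- pairs[[key]]
        pairs[[key]] <- if (is.null(prev)) {
          c(rres[i], lres[j], 1, dij)
        } else {
          c(prev[1], prev[2], prev[3] + 1, min(prev[4], dij))
        }
      }
    }
  }
  if (!length(pairs)) {
    return(list(contacts = data.frame(receptor_residue_index = integer(0),
                                      ligand_residue_index = integer(0),
                                      atom_contact_count = integer(0),
                                      min_distance = numeric(0)),
                total_atom_contacts = 0L))
  }
  m <- do.call(rbind, pairs)
  contacts <- data.frame(receptor_residue_index = as.integer(m[, 1]),
                         ligand_residue_index = as.integer(m[, 2]),
                         atom_contact_count = as.integer(m[, 3]),
                         min_distance = as.numeric(m[, 4]))
  contacts <- contacts[order(contacts$receptor_residue_index,
                             contacts$ligand_residue_index), , drop = FALSE]
  rownames(contacts) <- NULL
  list(contacts = contacts, total_atom_contacts = total)
}

# naive UPGMA reference: cluster distances recomputed from the ORIGINAL
# matrix as the arithmetic mean over all member pairs at every step
naive_upgma_heights <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best[1]) best <- c(dij, i, j)
      }
    }
    heights[step] <- best[1]
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# quaternion-method rigid superposition RMSD (eigen decomposition of the
# 4x4 key matrix), independent of the SVD route in the package
quaternion_rmsd <- function(mobile, reference) {
  x <- sweep(mobile, 2, colMeans(mobile))
  y <- sweep(reference, 2, colMeans(reference))
  n <- nrow(x)
  s <- crossprod(x, y)
  k <- matrix(0, 4, 4)
  k[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  k[1, 2] <- k[2, 1] <- s[2, 3] - s[3, 2]
  k[1, 3] <- k[3, 1] <- s[3, 1] - s[1, 3]
  k[1, 4] <- k[4, 1] <- s[1, 2] - s[2, 1]
  k[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  k[2, 3] <- k[3, 2] <- s[1, 2] + s[2, 1]
  k[2, 4] <- k[4, 2] <- s[1, 3] + s[3, 1]
  k[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  k[3, 4] <- k[4, 3] <- s[2, 3] + s[3, 2]
  k[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  lambda_max <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(x^2) + sum(y^2) - 2 * lambda_max) / n
  sqrt(max(msd, 0))
}

# random well-conditioned point cloud
random_points <- function(n, scale = 10) {
  matrix(stats::runif(3 * n, -scale, scale), ncol = 3)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)),
         3, 3, byrow = TRUE)
}

# random symmetric distance matrix with zero diagonal
random_distance_matrix <- function(n) {
  d <- matrix(stats::runif(n * n, 0.1, 5), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# random single-chain structure: n_res residues, 1-3 atoms each
random_structure <- function(n_res, max_atoms_per_res = 3, scale = 15,
                             chain_id = "A") {
  n_atoms <- sample(seq_len(max_atoms_per_res), n_res, replace = TRUE)
  coords <- random_points(sum(n_atoms), scale)
  residx <- rep(seq_len(n_res), n_atoms)
  names_pool <- c("CA", "CB", "CG")
  atom_name <- unlist(lapply(n_atoms, function(k) names_pool[seq_len(k)]))
  structure_from_coords(coords, residue_index = residx,
                        atom_name = atom_name, chain_id = chain_id)
}

# random fingerprint over an N x L universe
random_fp <- function(n = 8, l = 5, density = 0.3) {
  u <- n * l
  bits <- which(stats::runif(u) < density) - 1L
  structure(list(receptor_length = as.integer(n), ligand_length = as.integer(l),
                 bits = as.integer(bits)), class = "ifp")
}

fp_from_bits <- function(bits, n = 8, l = 5) {
  structure(list(receptor_length = as.integer(n), ligand_length = as.integer(l),
                 bits = as.integer(sort(unique(bits)))), class = "ifp")
}

# hand-written multi-model PDB fixture: 2 models x 1 chain x 3 residues
two_model_pdb_text <- function() {
  atom_line <- function(serial, name, resname, chain, resseq, x, y, z) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, paste0(" ", name), resname, chain, resseq, x, y, z, 1, 0)
  }
  c("MODEL        1",
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    atom_line(3, "CA", "SER", "A", 3, 7.6, 0, 0),
    "ENDMDL",
    "MODEL        2",
    atom_line(4, "CA", "ALA", "A", 1, 0, 0, 1),
    atom_line(5, "CA", "GLY", "A", 2, 3.8, 0, 1),
    atom_line(6, "CA", "SER", "A", 3, 7.6, 0, 1),
    "ENDMDL",
    "END")
}

# small ensemble used by several pipeline tests (cached per test run)
small_ensemble <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) {
      cache <<- simulate_ensemble(synthetic_config(
        seed = seed, n_conformers = 3L, decoys_per_conformer = 40L))
    }
    cache
  }
})
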