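# -- UPGMA dendrograms, cuts and per-group energy statistics ------------------

validate_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || nrow(d) < 2L) {
    stop("distance matrix must be square with n >= 2", call. = FALSE)
  }
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("d", seq_len(nrow(d))), paste0("d", seq_len(nrow(d))))
  }
  d
}

#' UPGMA (average-linkage) hierarchical clustering of a distance matrix
#'
#' Agglomerates by repeatedly merging the closest pair of clusters; the
#' distance from the merged cluster to any other is the size-weighted
#' arithmetic mean of its members' distances, and the merge height is the
#' merged pair's distance. Ties in the minimum distance are broken by the
#' lexicographically lowest (i, j) cluster-index pair, so results are
#' deterministic across platforms. UPGMA heights are nondecreasing along the
#' merge sequence.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal
#'   (decoy ids as dimnames; generated if absent).
#' @return an `upgma_tree`: list with `merges` (data.frame node_i, node_j,
#'   height, size; leaves are nodes 0..n-1, internal nodes n..2n-2 in merge
#'   order), `labels`, and `n_leaves`.
#' @export
upgma <- function(d) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  # active clusters live in slots 1..n of an upper-triangular working matrix
  # (lower triangle, diagonal and retired slots are Inf); the merged cluster
  # reuses the lower slot, so each step is O(n) plus one O(n^2) min scan in C
  work <- d
  work[lower.tri(work, diag = TRUE)] <- Inf
  node_id <- 0:(n - 1L)      # node id of the cluster currently in slot k
  sizes <- rep(1L, n)
  merges <- data.frame(node_i = integer(n - 1L), node_j = integer(n - 1L),
                       height = numeric(n - 1L), size = integer(n - 1L))
  next_node <- n
  getd <- function(a, b) work[cbind(pmin(a, b), pmax(a, b))]
  for (step in seq_len(n - 1L)) {
    h <- min(work)
    hit <- which(work == h, arr.ind = TRUE)
    # lexicographic (i, j) tie-break on slot indices
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    i <- hit[[1]]; j <- hit[[2]]                # i < j by construction
    merges$node_i[step] <- node_id[i]
    merges$node_j[step] <- node_id[j]
    merges$height[step] <- h
    merges$size[step] <- sizes[i] + sizes[j]
    # merged cluster occupies slot i; distance to others = size-weighted mean
    others <- which(sizes > 0L)
    others <- others[others != i & others != j]
    if (length(others)) {
      newd <- (sizes[i] * getd(i, others) + sizes[j] * getd(j, others)) /
        (sizes[i] + sizes[j])
      work[cbind(pmin(i, others), pmax(i, others))] <- newd
    }
    sizes[i] <- sizes[i] + sizes[j]
    sizes[j] <- 0L
    work[j, ] <- Inf
    work[, j] <- Inf
    node_id[i] <- next_node
    next_node <- next_node + 1L
  }
  structure(list(merges = merges, labels = labels, n_leaves = n),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, %d merges, height range [%g, %g]\n",
              x$n_leaves, nrow(x$merges), min(x$merges$height),
              max(x$merges$height)))
  invisible(x)
}

# leaf sets of every node (list indexed by node id + 1)
tree_leaf_sets <- function(tree) {
  n <- tree$n_leaves
  sets <- vector("list", 2L * n - 1L)
  for (k in seq_len(n)) sets[[k]] <- k - 1L
  for (s in seq_len(nrow(tree$merges))) {
    sets[[n + s]] <- c(sets[[tree$merges$node_i[s] + 1L]],
                       sets[[tree$merges$node_j[s] + 1L]])
  }
  sets
}

assignment_from_roots <- function(tree, roots) {
  sets <- tree_leaf_sets(tree)
  groups <- lapply(roots, function(r) sort(sets[[r + 1L]]))
  # deterministic numbering by smallest member leaf index
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  gid <- integer(tree$n_leaves)
  for (g in seq_along(groups)) gid[groups[[g]] + 1L] <- g
  data.frame(decoy_id = tree$labels, group_id = gid, stringsAsFactors = FALSE)
}

cut_roots <- function(tree, keep_merge) {
  # roots = nodes that are never absorbed by a kept merge
  n <- tree$n_leaves
  absorbed <- rep(FALSE, 2L * n - 1L)
  roots_alive <- rep(c(TRUE, FALSE), c(n, n - 1L))
  for (s in seq_len(nrow(tree$merges))) {
    if (keep_merge[s]) {
      absorbed[tree$merges$node_i[s] + 1L] <- TRUE
      absorbed[tree$merges$node_j[s] + 1L] <- TRUE
      roots_alive[n + s] <- TRUE
    }
  }
  which(roots_alive & !absorbed) - 1L
}

#' Cut a UPGMA tree at a height threshold
#'
#' Groups are the connected components remaining after removing all merges
#' whose height exceeds the cutoff. For fingerprint trees built on
#' 1 - Tanimoto distances, a Tanimoto similarity threshold t corresponds to
#' height 1 - t (e.g. Tc thresholds 0.6/0.8/0.9 are cuts at 0.4/0.2/0.1).
#' Group numbering is deterministic: groups are ordered by their smallest
#' member leaf index.
#'
#' @param tree an `upgma_tree`.
#' @param height cut height (>= 0).
#' @return a `cluster_assignment`: data.frame (decoy_id, group_id) with the
#'   cut recorded in attributes `cut_type` and `cut_value`.
#' @export
cut_at_height <- function(tree, height) {
  stopifnot(height >= 0)
  out <- assignment_from_roots(tree, cut_roots(tree, tree$merges$height <= height))
  structure(out, class = c("cluster_assignment", "data.frame"),
            cut_type = "height", cut_value = height)
}

#' Cut a UPGMA tree into exactly k groups
#'
#' Removes the k - 1 highest merges (the last k - 1 in merge order, heights
#' being nondecreasing).
#'
#' @param tree an `upgma_tree`.
#' @param k number of groups, 1 <= k <= n.
#' @return a `cluster_assignment` (see [cut_at_height()]).
#' @export
cut_into_k <- function(tree, k) {
  n <- tree$n_leaves
  if (k < 1L || k > n) {
    stop(sprintf("k must be in [1, %d], got %s", n, k), call. = FALSE)
  }
  keep <- rep(TRUE, n - 1L)
  if (k > 1L) keep[seq(n - k + 1L, n - 1L)] <- FALSE
  out <- assignment_from_roots(tree, cut_roots(tree, keep))
  structure(out, class = c("cluster_assignment", "data.frame"),
            cut_type = "k", cut_value = k)
}

#' Per-group energy statistics of a cluster assignment
#'
#' For each group: size, mean energy and sample standard deviation (n - 1
#' denominator; singleton groups report SD 0 and are flagged). The ensemble
#' summary (mean and SD of the per-group SDs) aggregates only groups of
#' size >= 2 — this is the quantity used to compare the uniformity of
#' fingerprint-based against RMSD-based groupings.
#'
#' @param assignment a `cluster_assignment`.
#' @param energies named numeric vector, names = decoy ids.
#' @return list with `groups` (data.frame group_id, size, mean_energy,
#'   sd_energy, singleton) and `summary` (data.frame mean_sd, sd_sd,
#'   n_groups, n_groups_ge2).
#' @export
group_energy_stats <- function(assignment, energies) {
  miss <- setdiff(assignment$decoy_id, names(energies))
  if (length(miss)) {
    stop(sprintf("missing energy for decoy(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  e <- energies[assignment$decoy_id]
  gids <- sort(unique(assignment$group_id))
  rows <- lapply(gids, function(g) {
    eg <- e[assignment$group_id == g]
    data.frame(group_id = g, size = length(eg), mean_energy = mean(eg),
               sd_energy = if (length(eg) > 1L) stats::sd(eg) else 0,
               singleton = length(eg) == 1L)
  })
  groups <- do.call(rbind, rows)
  sds <- groups$sd_energy[groups$size >= 2L]
  summary <- data.frame(
    mean_sd = if (length(sds)) mean(sds) else NA_real_,
    sd_sd = if (length(sds) > 1L) stats::sd(sds) else NA_real_,
    n_groups = nrow(groups), n_groups_ge2 = length(sds))
  list(groups = groups, summary = summary)
}

#' Convert a UPGMA tree to a base-R hclust object
#'
#' Heights follow hclust convention (merge height of each internal node);
#' useful for plotting and for Newick export via ape.
#'
#' @param tree an `upgma_tree`.
#' @return an object of class `hclust`.
#' @export
as_hclust <- function(tree) {
  n <- tree$n_leaves
  conv <- function(node) if (node < n) -(node + 1L) else node - n + 1L
  merge <- cbind(vapply(tree$merges$node_i, conv, integer(1)),
                 vapply(tree$merges$node_j, conv, integer(1)))
  # leaf display order by recursive traversal
  order_of <- function(node) {
    if (node < n) return(node + 1L)
    s <- node - n + 1L
    c(order_of(tree$merges$node_i[s]), order_of(tree$merges$node_j[s]))
  }
  structure(list(merge = merge, height = tree$merges$height,
                 order = order_of(2L * n - 2L), labels = tree$labels,
                 method = "average", call = match.call(),
                 dist.method = "precomputed"),
            class = "hclust")
}

#' Export a UPGMA tree as a Newick string or file
#'
#' Branch lengths are height differences between parent and child merges
#' (ultrametric tree, leaf depth = half merge height, matching the standard
#' phylogenetic reading of UPGMA).
#'
#' @param tree an `upgma_tree`.
#' @param path optional output path; when NULL the Newick string is returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(as_hclust(tree))
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write a cluster assignment as TSV (decoy_id, group_id)
#' @param assignment a `cluster_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignment_tsv <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment)[, c("decoy_id", "group_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
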