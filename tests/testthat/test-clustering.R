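# UPGMA construction, cuts, and group energy statistics

three_point_matrix <- function() {
  d <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, 3, byrow = TRUE)
  dimnames(d) <- list(c("p1", "p2", "p3"), c("p1", "p2", "p3"))
  d
}

test_that("hand-executed 3-point example: merge (1,2) at 1, then with 3 at 4", {
  tree <- upgma(three_point_matrix())
  expect_equal(tree$merges$height, c(1, 4))
  expect_equal(sort(c(tree$merges$node_i[1], tree$merges$node_j[1])), c(0, 1))
  expect_equal(tree$merges$size, c(2L, 3L))
})

test_that("all-equal distances merge at the common height", {
  n <- 5
  d <- matrix(2.5, n, n); diag(d) <- 0
  tree <- upgma(d)
  expect_equal(tree$merges$height, rep(2.5, n - 1))
})

test_that("merge heights match the naive from-scratch reference on random matrices", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    d <- random_distance_matrix(n)
    tree <- upgma(d)
    expect_equal(tree$merges$height, naive_upgma_heights(d), tolerance = 1e-9)
    expect_true(all(diff(tree$merges$height) >= -1e-12))  # monotone
  }
})

test_that("merge heights match stats::hclust average linkage", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    d <- random_distance_matrix(n)
    tree <- upgma(d)
    ref <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(tree$merges$height, ref$height, tolerance = 1e-9)
  }
})

test_that("invalid matrices are rejected", {
  d <- random_distance_matrix(4)
  d[1, 2] <- d[1, 2] + 1e-3             # asymmetric
  expect_error(upgma(d), "symmetric")
  d2 <- random_distance_matrix(4)
  d2[2, 3] <- d2[3, 2] <- -0.1
  expect_error(upgma(d2), "negative")
  d3 <- random_distance_matrix(4)
  diag(d3)[2] <- 0.5
  expect_error(upgma(d3), "diagonal")
})

test_that("height cuts: below first merge all singletons, above last one group", {
  d <- three_point_matrix()
  tree <- upgma(d)
  lo <- cut_at_height(tree, 0.5)
  expect_equal(sort(unique(lo$group_id)), 1:3)
  hi <- cut_at_height(tree, 10)
  expect_equal(unique(hi$group_id), 1L)
  mid <- cut_at_height(tree, 2)
  expect_equal(mid$group_id[mid$decoy_id == "p1"],
               mid$group_id[mid$decoy_id == "p2"])
  expect_false(mid$group_id[mid$decoy_id == "p3"] ==
                 mid$group_id[mid$decoy_id == "p1"])
})

test_that("k-cuts: k=1, k=n, k=2 on the worked example; out-of-range k errors", {
  tree <- upgma(three_point_matrix())
  expect_equal(unique(cut_into_k(tree, 1)$group_id), 1L)
  expect_equal(sort(cut_into_k(tree, 3)$group_id), 1:3)
  k2 <- cut_into_k(tree, 2)
  expect_equal(k2$group_id, c(1L, 1L, 2L))
  expect_error(cut_into_k(tree, 0), "k must be")
  expect_error(cut_into_k(tree, 4), "k must be")
})

test_that("cut_at_height(Inf) agrees with cut_into_k(1); height 0- with k=n", {
  set.seed(23)
  d <- random_distance_matrix(7)
  tree <- upgma(d)
  expect_equal(cut_at_height(tree, Inf)$group_id, cut_into_k(tree, 1)$group_id)
  eps <- min(tree$merges$height) / 2
  expect_equal(cut_at_height(tree, eps)$group_id, cut_into_k(tree, 7)$group_id)
})

test_that("partitions are invariant under leaf permutation", {
  set.seed(24)
  d <- random_distance_matrix(8)
  dimnames(d) <- list(letters[1:8], letters[1:8])
  perm <- sample(8)
  dp <- d[perm, perm]
  part_of <- function(assign) {
    unname(lapply(split(assign$decoy_id, assign$group_id),
                  function(g) sort(g)))
  }
  for (k in c(2, 4, 6)) {
    a <- part_of(cut_into_k(upgma(d), k))
    b <- part_of(cut_into_k(upgma(dp), k))
    expect_setequal(a, b)
  }
})

test_that("group energy stats: closed-form means and SDs, singleton flag, summary", {
  assignment <- structure(
    data.frame(decoy_id = c("a", "b", "c", "d", "e"),
               group_id = c(1L, 1L, 2L, 2L, 3L)),
    class = c("cluster_assignment", "data.frame"))
  energies <- c(a = -10, b = -20, c = -5, d = -5, e = -99)
  st <- group_energy_stats(assignment, energies)
  expect_equal(st$groups$mean_energy, c(-15, -5, -99))
  expect_equal(st$groups$sd_energy[1], sqrt(50), tolerance = 1e-9)  # 7.0711
  expect_equal(st$groups$sd_energy[2], 0)
  expect_equal(st$groups$singleton, c(FALSE, FALSE, TRUE))
  expect_equal(st$summary$n_groups_ge2, 2)
  expect_error(group_energy_stats(assignment, energies[-1]), "missing energy")
  # summary over per-group SDs 2 and 4: mean 3, SD sqrt(2)
  a2 <- structure(data.frame(decoy_id = letters[1:4],
                             group_id = c(1L, 1L, 2L, 2L)),
                  class = c("cluster_assignment", "data.frame"))
  e2 <- c(a = 0, b = 2 * sqrt(2), c = 0, d = 4 * sqrt(2))
  st2 <- group_energy_stats(a2, e2)
  expect_equal(st2$groups$sd_energy, c(2, 4), tolerance = 1e-9)
  expect_equal(st2$summary$mean_sd, 3, tolerance = 1e-9)
  expect_equal(st2$summary$sd_sd, sqrt(2), tolerance = 1e-9)
})

test_that("newick export round-trips through ape with correct tips and depths", {
  d <- three_point_matrix()
  tree <- upgma(d)
  txt <- write_newick(tree)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, c("p1", "p2", "p3"))
  depths <- ape::node.depth.edgelength(phy)
  # ultrametric: all leaves at depth = last merge height / 2
  expect_equal(unname(depths[1:3]), rep(2, 3), tolerance = 1e-9)
})

test_that("as_hclust produces a valid hclust whose cutree matches cut_into_k sizes", {
  set.seed(25)
  d <- random_distance_matrix(9)
  tree <- upgma(d)
  hc <- as_hclust(tree)
  for (k in c(2, 5)) {
    expect_equal(sort(unname(table(stats::cutree(hc, k)))),
                 sort(unname(table(cut_into_k(tree, k)$group_id))))
  }
})
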