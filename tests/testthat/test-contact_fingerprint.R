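# contact detection, fingerprint encoding and Tversky-family similarities

test_that("three stacked receptor residues, one nearby ligand atom: exactly one contact", {
  rec <- structure_from_coords(rbind(c(0, 0, 0), c(0, 0, 10), c(0, 0, 20)),
                               residue_index = 1:3, chain_id = "R")
  lig <- structure_from_coords(rbind(c(0, 0, 1)), residue_index = 1L,
                               chain_id = "L")
  det <- detect_nonbonded_contacts(rec, lig, cutoff = 3.9)
  expect_equal(det$total_atom_contacts, 1L)
  expect_equal(det$contacts$receptor_residue_index, 1L)
  expect_equal(det$contacts$ligand_residue_index, 1L)
  expect_equal(det$contacts$min_distance, 1)
})

test_that("atoms beyond the cutoff yield no contacts", {
  rec <- structure_from_coords(rbind(c(0, 0, 0)), 1L, chain_id = "R")
  lig <- structure_from_coords(rbind(c(5, 0, 0)), 1L, chain_id = "L")
  det <- detect_nonbonded_contacts(rec, lig, cutoff = 3.9)
  expect_equal(det$total_atom_contacts, 0L)
  expect_equal(nrow(det$contacts), 0)
})

test_that("contact detection matches the brute-force double loop on random structures", {
  set.seed(101)
  for (i in 1:20) {
    rec <- random_structure(sample(5:40, 1), chain_id = "R")
    lig <- random_structure(sample(2:20, 1), chain_id = "L")
    cutoff <- runif(1, 2, 8)
    got <- detect_nonbonded_contacts(rec, lig, cutoff)
    want <- brute_force_contacts(rec, lig, cutoff)
    expect_equal(got$total_atom_contacts, want$total_atom_contacts)
    expect_equal(got$contacts, want$contacts, tolerance = 1e-12)
  }
})

test_that("fingerprint bit indexing follows (r-1)*L + (l-1) and collapses duplicates", {
  contacts <- data.frame(receptor_residue_index = c(1L, 1L, 2L),
                         ligand_residue_index = c(1L, 1L, 3L))
  fp <- build_fingerprint(contacts, receptor_length = 4, ligand_length = 3)
  expect_equal(fp$bits, c(0L, 5L))
  expect_equal(popcount(fp), 2L)
  expect_equal(popcount(build_fingerprint(contacts[0, ], 4, 3)), 0L)
  bad <- data.frame(receptor_residue_index = 5L, ligand_residue_index = 1L)
  expect_error(build_fingerprint(bad, 4, 3), "universe")
})

test_that("popcount never exceeds total atom contacts", {
  set.seed(77)
  for (i in 1:10) {
    rec <- random_structure(sample(5:25, 1), chain_id = "R")
    lig <- random_structure(sample(2:10, 1), chain_id = "L")
    det <- detect_nonbonded_contacts(rec, lig, 5)
    fp <- build_fingerprint(det$contacts, residue_count(rec), residue_count(lig))
    expect_lte(popcount(fp), det$total_atom_contacts)
  }
})

test_that("tversky reproduces set-arithmetic values", {
  # explicit sets {1,2,3,4} and {2,3,4,5,6}: a=4, b=5, c=3
  fa <- fp_from_bits(c(1, 2, 3, 4))
  fb <- fp_from_bits(c(2, 3, 4, 5, 6))
  expect_equal(tversky(fa, fb, 1, 1), 3 / (4 + 5 - 3))  # 0.5
  expect_equal(tversky(fa, fa, 1, 1), 1)
  # superset decoy recovers all native bits: S_frac 1
  native <- fp_from_bits(c(1, 2))
  superset <- fp_from_bits(c(1, 2, 3, 7))
  expect_equal(tversky(native, superset, 1, 0), 1)
  expect_warning(v <- tversky(fp_from_bits(integer(0)), fp_from_bits(integer(0))),
                 "empty")
  expect_equal(v, 0)
  expect_error(tversky(fp_from_bits(1, n = 8, l = 5),
                       fp_from_bits(1, n = 8, l = 6)), "universe")
})

test_that("tanimoto identities: disjoint 0, self 1, {0,1} vs {1,2} is 1/3", {
  expect_equal(tanimoto(fp_from_bits(c(0, 1)), fp_from_bits(c(2, 3))), 0)
  f <- fp_from_bits(c(3, 9, 14))
  expect_equal(tanimoto(f, f), 1)
  expect_equal(tanimoto(fp_from_bits(c(0, 1)), fp_from_bits(c(1, 2))), 1 / 3)
})

test_that("s_frac is c/a_native and lives on the discrete grid", {
  native <- fp_from_bits(0:24, n = 25, l = 5)
  decoy <- fp_from_bits(c(0:4, 60:70), n = 25, l = 5)  # shares 5 of 25
  expect_equal(s_frac(native, decoy), 0.2)
  expect_equal(s_frac(native, native), 1)
  expect_equal(s_frac(native, fp_from_bits(80:90, n = 25, l = 5)), 0)
  expect_error(s_frac(fp_from_bits(integer(0)), decoy), "empty")
  set.seed(2)
  a <- popcount(native)
  for (i in 1:50) {
    v <- s_frac(native, random_fp(25, 5, runif(1, 0, 0.5)))
    expect_true(any(abs(v - (0:a) / a) < 1e-12))
  }
})

test_that("tversky algebra: alpha=beta=1 is tanimoto, alpha=1 beta=0 is s_frac", {
  set.seed(31)
  for (i in 1:50) {
    fa <- random_fp(10, 6, 0.3)
    fb <- random_fp(10, 6, 0.3)
    if (popcount(fa) == 0 || popcount(fb) == 0) next
    expect_identical(tversky(fa, fb, 1, 1), tanimoto(fa, fb))
    expect_identical(tversky(fa, fb, 1, 0), s_frac(fa, fb))
    expect_equal(tanimoto(fa, fb), tanimoto(fb, fa))
  }
})

test_that("fingerprint distance matrix: values, symmetry, triangle inequality", {
  f1 <- fp_from_bits(c(0, 1))
  f2 <- fp_from_bits(c(1, 2))
  d <- fingerprint_distance_matrix(list(f1, f1))
  expect_equal(unname(d), matrix(0, 2, 2))
  d2 <- fingerprint_distance_matrix(list(f1, f2), ids = c("x", "y"))
  expect_equal(d2["x", "y"], 2 / 3)
  set.seed(9)
  fps <- replicate(15, random_fp(6, 4, 0.4), simplify = FALSE)
  dm <- suppressWarnings(fingerprint_distance_matrix(fps))
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 15))
  for (i in 1:15) for (j in 1:15) for (k in 1:15) {
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }
})

test_that("distance matrix agrees with pairwise tanimoto calls", {
  set.seed(12)
  fps <- replicate(8, random_fp(7, 5, 0.35), simplify = FALSE)
  dm <- suppressWarnings(fingerprint_distance_matrix(fps))
  for (i in 1:8) for (j in 1:8) {
    if (i == j) next
    if (popcount(fps[[i]]) == 0 && popcount(fps[[j]]) == 0) next
    expect_equal(dm[i, j], 1 - tanimoto(fps[[i]], fps[[j]]), tolerance = 1e-12)
  }
})

test_that("fingerprint TSV round trip preserves bits and metadata", {
  set.seed(4)
  fps <- replicate(6, random_fp(9, 4, 0.3), simplify = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints_tsv(fps, p, decoy_id = paste0("d", 1:6),
                         conformer_id = "c0", label = "a",
                         energy = seq(-10, -5))
  back <- read_fingerprints_tsv(p)
  expect_equal(back$meta$decoy_id, paste0("d", 1:6))
  expect_equal(back$meta$energy, seq(-10, -5))
  for (i in 1:6) expect_equal(back$fps[[i]]$bits, fps[[i]]$bits)
  expect_equal(back$fps[[1]]$receptor_length, 9L)
})

test_that("distance matrix TSV round trip", {
  set.seed(6)
  fps <- replicate(4, random_fp(5, 4, 0.5), simplify = FALSE)
  d <- suppressWarnings(fingerprint_distance_matrix(fps, ids = letters[1:4]))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix_tsv(d, p)
  expect_equal(read_distance_matrix_tsv(p), d, tolerance = 1e-12)
})
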