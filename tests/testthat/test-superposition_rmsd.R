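# Kabsch superposition, receptor-anchored ligand RMSD, GDT curves

test_that("kabsch on identical point sets gives zero rmsd and identity rotation", {
  set.seed(1)
  x <- random_points(10)
  fit <- kabsch_superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, rep(0, 3), tolerance = 1e-10)
})

test_that("kabsch recovers a known rotation + translation exactly", {
  set.seed(2)
  x <- random_points(12)
  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  y <- sweep(x %*% t(rot90), 2, c(5, -3, 2), "+")
  fit <- kabsch_superpose(x, y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, rot90, tolerance = 1e-9)
  expect_equal(apply_transform(fit, x), y, tolerance = 1e-9)
})

test_that("kabsch rmsd equals the quaternion-method oracle", {
  # unit tetrahedron with one vertex displaced by 1 A
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  tet2 <- tet
  tet2[4, ] <- tet2[4, ] + c(0, 0, 1)
  expect_equal(kabsch_superpose(tet, tet2)$rmsd, quaternion_rmsd(tet, tet2),
               tolerance = 1e-9)
  set.seed(3)
  for (i in 1:20) {
    a <- random_points(sample(4:30, 1))
    b <- a + matrix(rnorm(length(a), 0, 0.5), ncol = 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-8)
  }
})

test_that("fitted rmsd never exceeds unfitted rmsd and is rigid-motion invariant", {
  set.seed(4)
  for (i in 1:20) {
    a <- random_points(10)
    b <- a + matrix(rnorm(30, 0, 1), ncol = 3)
    fitted <- kabsch_superpose(a, b)$rmsd
    expect_lte(fitted, coord_rmsd(a, b) + 1e-12)
    rot <- random_rotation()
    shift <- runif(3, -20, 20)
    a2 <- sweep(a %*% t(rot), 2, shift, "+")
    b2 <- sweep(b %*% t(rot), 2, shift, "+")
    expect_equal(kabsch_superpose(a2, b2)$rmsd, fitted, tolerance = 1e-6)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(kabsch_superpose(random_points(2), random_points(2)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("ligand rmsd to native: identity is 0, pure ligand translation is its norm", {
  ens <- small_ensemble()
  nat <- ens$native
  expect_equal(ligand_rmsd_to_native(nat, nat), 0, tolerance = 1e-9)
  shifted <- nat
  shifted$ligand$atoms$x <- shifted$ligand$atoms$x + 2
  expect_equal(ligand_rmsd_to_native(shifted, nat), 2, tolerance = 1e-9)
})

test_that("ligand rmsd matches direct recomputation for a planted transform", {
  ens <- small_ensemble()
  nat <- ens$native
  dec <- ens$decoys[[3]]
  got <- ligand_rmsd_to_native(dec, nat)
  # brute-force recomputation from raw coordinates
  fit <- kabsch_superpose(model_coords(dec$receptor, "CA"),
                          model_coords(nat$receptor, "CA"))
  lig <- apply_transform(fit, model_coords(dec$ligand, "CA"))
  ref <- model_coords(nat$ligand, "CA")
  expect_equal(got, sqrt(mean(rowSums((lig - ref)^2))), tolerance = 1e-9)
  # and the generator's ground-truth table agrees
  expect_equal(got, ens$truth$true_ligand_rmsd[3], tolerance = 1e-6)
})

test_that("pairwise rmsd matrix: duplicates, known translations, loop oracle", {
  ens <- small_ensemble()
  nat <- ens$native
  d0 <- pairwise_rmsd_matrix(list(nat, nat))
  expect_equal(unname(d0), matrix(0, 2, 2), tolerance = 1e-9)
  t1 <- c(1, 0, 0); t2 <- c(4, 0, 0)
  mk <- function(tv, id) {
    x <- nat
    x$decoy_id <- id
    x$ligand$atoms$x <- x$ligand$atoms$x + tv[1]
    x$ligand$atoms$y <- x$ligand$atoms$y + tv[2]
    x$ligand$atoms$z <- x$ligand$atoms$z + tv[3]
    x
  }
  d <- pairwise_rmsd_matrix(list(mk(t1, "p"), mk(t2, "q")), nat$receptor)
  expect_equal(d["p", "q"], sqrt(sum((t1 - t2)^2)), tolerance = 1e-9)
  sub <- ens$decoys[1:6]
  dm <- pairwise_rmsd_matrix(sub, nat$receptor)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 6))
  for (i in 1:5) for (j in (i + 1):6) {
    fit_i <- kabsch_superpose(model_coords(sub[[i]]$receptor, "CA"),
                              model_coords(nat$receptor, "CA"))
    fit_j <- kabsch_superpose(model_coords(sub[[j]]$receptor, "CA"),
                              model_coords(nat$receptor, "CA"))
    want <- coord_rmsd(apply_transform(fit_i, model_coords(sub[[i]]$ligand, "CA")),
                       apply_transform(fit_j, model_coords(sub[[j]]$ligand, "CA")))
    expect_equal(dm[i, j], want, tolerance = 1e-9)
  }
})

test_that("gdt curve is 1 for identical structures and nondecreasing in cutoff", {
  ens <- small_ensemble()
  rec <- ens$native$receptor
  curve <- gdt_fraction_curve(rec, rec, cutoffs = c(1, 2, 4, 8))
  expect_equal(curve$fraction, rep(1, 4))
  hinged <- ens$conformers[[2]]
  c2 <- gdt_fraction_curve(rec, hinged, cutoffs = c(0.5, 1, 2, 4, 8))
  expect_true(all(diff(c2$fraction) >= 0))
  expect_true(all(c2$fraction >= 0 & c2$fraction <= 1))
})

test_that("gdt on a two-domain hinge recovers at least the larger domain", {
  # 20 residues: first 12 fixed, last 8 rotated away as a rigid block
  set.seed(8)
  base <- cbind(seq(0, 38, by = 2), sin(1:20), cos(1:20))
  bent <- base
  rot <- rotation_about_axis <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3,
                                       byrow = TRUE)  # 90 deg about x
  pivot <- base[12, ]
  bent[13:20, ] <- sweep(sweep(base[13:20, ], 2, pivot) %*% t(rot), 2, pivot, "+")
  a <- structure_from_coords(base, 1:20)
  b <- structure_from_coords(bent, 1:20)
  curve <- gdt_fraction_curve(a, b, cutoffs = c(0.5, 8))
  expect_gte(curve$fraction[1], 12 / 20)
  expect_error(gdt_fraction_curve(structure_from_coords(base[1:5, ], 1:5),
                                  structure_from_coords(bent[1:5, ], 1:5)),
               "7 residues")
})
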