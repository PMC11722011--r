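test_that("self- and rigid-copy superpositions give zero RMSD", {
  set.seed(71)
  m <- as_ca_model(matrix(rnorm(60, sd = 5), ncol = 3))
  expect_equal(kabsch_superpose(m, m)$rmsd, 0, tolerance = 1e-12)
  moved <- apply_rigid(m, random_rotation(), c(4, -2, 9))
  fit <- kabsch_superpose(m, moved)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("RMSD is symmetric and invariant under rigid transforms", {
  set.seed(72)
  a <- as_ca_model(matrix(rnorm(45, sd = 5), ncol = 3))
  b <- as_ca_model(matrix(rnorm(45, sd = 5), ncol = 3))
  r_ab <- kabsch_superpose(a, b)$rmsd
  expect_equal(kabsch_superpose(b, a)$rmsd, r_ab, tolerance = 1e-9)
  b_moved <- apply_rigid(b, random_rotation(), c(-3, 7, 1))
  expect_equal(kabsch_superpose(a, b_moved)$rmsd, r_ab, tolerance = 1e-9)
})

test_that("Kabsch agrees with the quaternion oracle on toy sets", {
  # the 4-point case, solved independently by the quaternion eigenvalue
  # method, must match to numerical precision
  xa <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 1.2),
               ncol = 3, byrow = TRUE)
  xb <- matrix(c(0.1, 0, 0, 1, 0.2, 0, 0, 1.1, 0, 0.2, 0.5, 1.0),
               ncol = 3, byrow = TRUE)
  fit <- kabsch_superpose(as_ca_model(xa), as_ca_model(xb))
  expect_equal(fit$rmsd, quaternion_rmsd(xa, xb), tolerance = 1e-9)
})

test_that("selection controls the fitted atom set", {
  set.seed(73)
  m <- as_ca_model(matrix(rnorm(90, sd = 5), ncol = 3))
  shifted <- m
  shifted[shifted$residue > 20, c("x", "y", "z")] <-
    shifted[shifted$residue > 20, c("x", "y", "z")] + 3
  full <- kabsch_superpose(m, shifted)$rmsd
  sub <- kabsch_superpose(m, shifted, residues = 1:20)$rmsd
  expect_equal(sub, 0, tolerance = 1e-9)
  expect_gt(full, 0.5)
  expect_error(kabsch_superpose(m, shifted, residues = 1:2), "3")
})

test_that("ensemble RMSD matches the Gaussian-jitter expectation", {
  g <- gen_structure_ensemble(seed = 74, n_res = 200, n_models = 20,
                              jitter_sd = 0.5)
  out <- ensemble_rmsd(g$ensemble, g$reference)
  # per-atom squared deviation ~ sigma^2 * chi2_3, E[rmsd] ~ sigma*sqrt(3)
  # (superposition absorbs a little of the jitter; allow 10%)
  expect_equal(out$mean, 0.5 * sqrt(3), tolerance = 0.1)
  ident <- ensemble_rmsd(list(g$reference, g$reference), g$reference)
  expect_equal(ident$rmsd, c(0, 0), tolerance = 1e-12)
  expect_error(ensemble_rmsd(list(), g$reference), "empty")
})

test_that("rmsd_grid scans model and range combinations", {
  g <- gen_structure_ensemble(seed = 75, n_res = 81, n_models = 2,
                              jitter_sd = 0.3)
  grid <- rmsd_grid(list(g$reference), g$ensemble[1],
                    ranges = list(`1-81` = 1:81, `2-72` = 2:72))
  expect_equal(nrow(grid), 2L)
  expect_equal(grid$n_atoms, c(81L, 71L))
  expect_true(all(grid$rmsd > 0))
})
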