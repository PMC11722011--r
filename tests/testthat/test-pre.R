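test_that("alpha normalization reproduces hand-computed cases", {
  recs <- data.frame(residue = 1:5, raw_ratio = rep(1, 5))
  out <- normalize_pre(recs, reference = 1:5)
  expect_equal(out$alpha, 1)
  expect_equal(out$records$pre, rep(1, 5))

  # alpha = 1 / mean(2, 2) = 0.5; pre = [1, 1, 0.5] (padded to n >= 5)
  recs <- data.frame(residue = 1:5, raw_ratio = c(2, 2, 1, 2, 2))
  out <- normalize_pre(recs, reference = 1:2)
  expect_equal(out$alpha, 0.5)
  expect_equal(out$records$pre[1:3], c(1, 1, 0.5))

  expect_error(normalize_pre(recs, reference = c(1, 99)), "99")
  expect_error(normalize_pre(recs[1:4, ], reference = 1:4), "5")
})

test_that("reference mean is exactly 1 and normalization is idempotent", {
  set.seed(31)
  recs <- data.frame(residue = 1:60,
                     raw_ratio = c(runif(15, 0, 0.6), runif(45, 1.0, 1.4)))
  out <- normalize_pre(recs, reference = "auto")
  ref <- out$records$pre[out$records$in_reference]
  expect_equal(mean(ref), 1, tolerance = 1e-12)
  # distant (high-ratio) residues, not attenuated ones, form the reference
  expect_true(all(out$records$residue[out$records$in_reference] > 15))
  # renormalizing the normalized values with the same reference: alpha = 1
  recs2 <- out$records
  recs2$raw_ratio <- recs2$pre
  out2 <- normalize_pre(recs2,
                        reference = recs2$residue[recs2$in_reference])
  expect_equal(out2$alpha, 1, tolerance = 1e-12)
})

test_that("the linear distance calibration and its inverse agree", {
  expect_equal(pre_to_distance(0), 12)
  expect_equal(pre_to_distance(1), 30)
  expect_equal(pre_to_distance(0.5), 21)
  expect_equal(pre_to_distance(1.4), 30)   # clamped above 1
  expect_error(pre_to_distance(-0.1), "non-negative")
  d <- seq(12, 30, length.out = 2001)
  expect_equal(pre_to_distance(distance_to_pre(d)), d, tolerance = 1e-9)
  # monotone non-decreasing
  p <- seq(0, 1.2, by = 0.01)
  expect_true(all(diff(pre_to_distance(p)) >= 0))
})

test_that("restraint rules reproduce the three branches", {
  recs <- data.frame(residue = c(101L, 102L, 103L, 104L),
                     pre = c(0, 0.4, 0.95, 0.2),
                     status = c("disappeared", "ok", "ok", "ok"))
  r <- restraints_from_pre(recs, label_residue = 1L)
  # pre = 0 / disappeared -> [1.8, 12]
  expect_equal(r$lower[r$target_residue == 101], 1.8)
  expect_equal(r$upper[r$target_residue == 101], 12)
  # pre = 0.4 -> d_calc = 19.2, interval [12, 22.2]
  expect_equal(r$lower[r$target_residue == 102], 12)
  expect_equal(r$upper[r$target_residue == 102], 22.2)
  # pre = 0.95 >= 0.8 -> unrestrained
  expect_false(103 %in% r$target_residue)
  # all bounds respect the restraint invariants
  expect_true(all(r$lower >= 1.8 & r$upper <= 33 & r$lower <= r$upper))
  # written table re-reads to identical intervals
  path <- withr::local_tempfile(fileext = ".tbl")
  write_restraint_table(r, path, "cns_tbl")
  back <- read_restraint_table(path, "cns_tbl")
  expect_equal(back$lower, r$lower, tolerance = 0.05)
  expect_equal(back$upper, r$upper, tolerance = 0.1)
})

test_that("region-specific cutoffs flag strictly-below residues only", {
  cutoffs <- sis1_pre_cutoffs()
  recs <- data.frame(residue = c(100L, 200L, 150L, 300L),
                     pre = c(0.85, 0.85, 0.88, 0.70))
  flagged <- classify_pre_sites(recs, cutoffs)
  expect_true(100 %in% flagged)    # 0.85 < 0.88 in region 1-182
  expect_false(200 %in% flagged)   # 0.85 >= 0.70 in region 183-352
  expect_false(150 %in% flagged)   # exactly at cutoff: not flagged
  expect_false(300 %in% flagged)
  expect_error(classify_pre_sites(data.frame(residue = 400L, pre = 0.5),
                                  cutoffs), "400")
})

test_that("close residues yield restraints that cover the true distance", {
  # residues generated below 12 A broaden away and get the [1.8, 12] branch;
  # with 2% intensity noise the interval covers truth in >= 95% of replicates
  n_rep <- 40
  hits <- 0L; total <- 0L
  for (i in seq_len(n_rep)) {
    d_true <- stats::setNames(c(runif(6, 4, 11.5), runif(24, 13, 36)), 1:30)
    g <- gen_pre_dataset(seed = 500 + i, distances_true = d_true,
                         alpha_true = 1.1, noise_frac = 0.02)
    norm <- normalize_pre(pre_ratios(g$para, g$dia))
    restr <- restraints_from_pre(norm$records, label_residue = 1L)
    close_res <- as.integer(names(d_true)[d_true < 12])
    for (res in close_res) {
      row <- restr[restr$target_residue == res, ]
      total <- total + 1L
      if (nrow(row) == 1 && row$lower <= d_true[as.character(res)] &&
          d_true[as.character(res)] <= row$upper)
        hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
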