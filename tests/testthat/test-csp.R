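test_that("compute_csp matches hand-evaluated values and is a norm", {
  expect_equal(compute_csp(0, 0), 0)
  expect_equal(compute_csp(0.02, 0.10), sqrt(0.0004 + 0.0001))
  expect_equal(compute_csp(0.02, 0.10), 0.02236, tolerance = 1e-4)
  expect_equal(compute_csp(-0.02, -0.10), compute_csp(0.02, 0.10))

  set.seed(11)
  h <- rnorm(50, 0, 0.05); n <- rnorm(50, 0, 0.5); c <- runif(50, 0.1, 3)
  expect_true(all(compute_csp(h, n) >= 0))
  expect_equal(compute_csp(-h, n), compute_csp(h, n))
  expect_equal(compute_csp(c * h, c * n), c * compute_csp(h, n),
               tolerance = 1e-12)
})

test_that("significance threshold follows the mean + k*SD rule", {
  expect_equal(csp_significance_threshold(c(0.01, 0.01, 0.01)), 0.01)
  # sample-SD convention: mean 0.025, sd 0.05
  expect_equal(csp_significance_threshold(c(0, 0, 0, 0.1)), 0.075)
  expect_equal(csp_significance_threshold(c(0.02, 0.05, 0.08), k = 0),
               mean(c(0.02, 0.05, 0.08)))
  expect_error(csp_significance_threshold(c(0.01, 0.02)), "3")
  # monotonicity: adding a high record never drops the threshold below
  # the previous mean
  x <- c(0.01, 0.02, 0.015, 0.012)
  thr0 <- csp_significance_threshold(x)
  expect_gte(csp_significance_threshold(c(x, thr0 + 0.05)), mean(x))
})

test_that("peak matching pairs by assignment and excludes overlap", {
  a <- toy_peaks(c(10, 20, 30, 40), 8 + (1:4) / 10, 110 + 1:4,
                 status = c("ok", "ok", "overlapped", "ok"))
  m_id <- match_peaks(a, a)
  expect_equal(m_id$pairs$residue, c(10L, 20L, 40L))  # overlap excluded
  expect_equal(m_id$overlapped, 30L)
  expect_equal(m_id$pairs$h_ppm_a, m_id$pairs$h_ppm_b)

  b <- toy_peaks(c(10, 20), c(8.1, 8.2), c(111, 112))
  m <- match_peaks(a, b)
  expect_equal(m$unmatched_a, 40L)   # present only in the free list
  expect_length(m$unmatched_b, 0)
})

test_that("csp_profile flags exactly the perturbed region", {
  set.seed(21)
  n <- 81
  free <- toy_peaks(1:n, runif(n, 7.5, 9.5), runif(n, 105, 130))
  site <- 30:48
  pk <- free$peaks
  pk$h_ppm[site] <- pk$h_ppm[site] + 0.06
  pk$n_ppm[site] <- pk$n_ppm[site] + 0.4
  # small uniform jitter below the threshold everywhere else
  jit <- rnorm(n, 0, 0.001)
  pk$h_ppm <- pk$h_ppm + jit
  bound <- peak_list(pk)

  prof <- csp_profile(free, bound, sis1_domains())
  sig <- prof$residue[prof$significant]
  expect_true(all(sig %in% site))
  expect_true(length(sig) > 10)
  expect_true(all(prof$csp >= 0))

  # bound = free: every CSP is exactly zero
  prof0 <- csp_profile(free, free)
  expect_equal(prof0$csp, rep(0, n))
  expect_false(any(prof0$significant))
})

test_that("a single strongly perturbed residue is flagged", {
  set.seed(22)
  n <- 60
  free <- toy_peaks(1:n, runif(n, 7.5, 9.5), runif(n, 105, 130))
  pk <- free$peaks
  pk$h_ppm <- pk$h_ppm + rnorm(n, 0, 0.002)   # noise floor
  pk$h_ppm[17] <- pk$h_ppm[17] + 0.02         # 10x the noise
  prof <- csp_profile(free, peak_list(pk))
  expect_true(prof$significant[prof$residue == 17])
})
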