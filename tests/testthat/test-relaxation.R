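test_that("noiseless monoexponential decays are fit exactly", {
  # R1-style delays
  t1 <- c(0.02, 0.3, 0.6)
  f <- fit_monoexponential(t1, 100 * exp(-3 * t1))
  expect_equal(f$rate, 3, tolerance = 1e-9)
  expect_equal(f$i0, 100, tolerance = 1e-9)
  # R2-style delays (8.65 / 16.96 / 33.92 ms)
  t2 <- c(0.00865, 0.01696, 0.03392)
  f2 <- fit_monoexponential(t2, 100 * exp(-30 * t2))
  expect_equal(f2$rate, 30, tolerance = 1e-9)
  # constant intensities: degenerate zero rate
  fc <- fit_monoexponential(t1, c(50, 50, 50))
  expect_equal(fc$rate, 0)
  expect_true(fc$degenerate)
  expect_error(fit_monoexponential(t1, c(10, -1, 5)), "positive")
})

test_that("rate fitting is scale invariant", {
  t2 <- c(0.00865, 0.01696, 0.03392)
  y <- 7.3 * exp(-24 * t2)
  r1 <- fit_monoexponential(t2, y)$rate
  r2 <- fit_monoexponential(t2, 1e8 * y)$rate
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("Monte-Carlo sigma is reproducible and tracks the noise level", {
  t1 <- c(0.02, 0.3, 0.6)
  y <- 100 * exp(-2 * t1)
  fa <- fit_monoexponential(t1, y, noise_sigma = 2, n_mc = 200, seed = 7)
  fb <- fit_monoexponential(t1, y, noise_sigma = 2, n_mc = 200, seed = 7)
  expect_equal(fa$sigma, fb$sigma)
  f_low <- fit_monoexponential(t1, y, noise_sigma = 0.2, n_mc = 200,
                               seed = 7)
  expect_lt(f_low$sigma, fa$sigma)
})

test_that("Monte-Carlo sigma covers the true rate at roughly the 68% level", {
  set.seed(44)
  t2 <- c(0.00865, 0.01696, 0.03392)
  r_true <- 25; i0 <- 1e6; noise <- i0 / 50
  covered <- vapply(1:150, function(k) {
    y <- i0 * exp(-r_true * t2) + rnorm(3, 0, noise)
    f <- fit_monoexponential(t2, pmax(y, 1), noise_sigma = noise,
                             n_mc = 200, seed = 4000 + k)
    abs(f$rate - r_true) <= f$sigma
  }, logical(1))
  expect_gte(mean(covered), 0.58)
  expect_lte(mean(covered), 0.78)
})

test_that("tauc formula reproduces printed domain values and inverts", {
  expect_equal(tauc_from_ratio(7 / 6, 900), 0)
  expect_equal(round(tauc_from_ratio(22, 900), 1), 9.8)
  expect_equal(round(tauc_from_ratio(70, 900)), 18)
  # desk check against the explicit closed form at 91.2 MHz
  expect_equal(tauc_from_ratio(22, 900, gamma_ratio = 91.2 / 900),
               sqrt(125) / (4 * pi * 91.2e6) * 1e9, tolerance = 1e-12)
  expect_error(tauc_from_ratio(1.0, 900), "7/6")
  # algebraic inverse consistency across the physical range
  x <- seq(2, 100, length.out = 200)
  expect_equal(ratio_from_tauc(tauc_from_ratio(x, 900), 900), x,
               tolerance = 1e-9)
  # monotone increasing in the ratio
  expect_true(all(diff(tauc_from_ratio(x, 900)) > 0))
})

test_that("domain trimming retains the 1-SD core and drops outliers", {
  dm <- domain_map("D", 1, 40)
  # degenerate: all ratios equal -> trim keeps everything
  r_eq <- data.frame(residue = 1:10, ratio = rep(22, 10))
  dyn <- domain_dynamics(r_eq, dm, 900)
  expect_equal(dyn$n_used, 10L)
  expect_equal(dyn$mean_ratio, 22)
  expect_equal(dyn$tauc_ns, tauc_from_ratio(22, 900))

  # 20 ratios at 10 plus one at 100: the outlier is trimmed out
  r_out <- data.frame(residue = 1:21, ratio = c(rep(10, 20), 100))
  dyn2 <- domain_dynamics(r_out, dm, 900)
  expect_equal(dyn2$n_used, 20L)
  expect_equal(dyn2$mean_ratio, 10)

  # a domain with < 2 usable records is skipped with a warning
  dm2 <- domain_map(c("A", "B"), c(1, 30), c(29, 40))
  expect_warning(dyn3 <- domain_dynamics(r_eq, dm2, 900), "fewer than 2")
  expect_equal(dyn3$domain, "A")

  # trimming never empties a domain with >= 3 finite ratios
  r_tri <- data.frame(residue = 1:3, ratio = c(10, 20, 90))
  dyn4 <- domain_dynamics(r_tri, dm, 900)
  expect_gte(dyn4$n_used, 1L)
})

test_that("exchange flags use untrimmed mean + 1 SD", {
  dm <- domain_map("D", 1, 10)
  # mean 14, sd 8.94: only the 30 exceeds 22.94
  r <- data.frame(residue = 1:5, ratio = c(10, 10, 10, 10, 30))
  out <- flag_exchange(r, dm)
  expect_equal(out$exchange_flag, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  r_u <- data.frame(residue = 1:5, ratio = rep(12, 5))
  expect_false(any(flag_exchange(r_u, dm)$exchange_flag))
})

test_that("condition comparison is a Welch test with sane edge cases", {
  dm <- domain_map("D", 1, 100)
  set.seed(41)
  a <- data.frame(residue = 1:35, ratio = rnorm(35, 22, 1))
  expect_error(compare_conditions(a, data.frame(residue = 1:2,
                                                ratio = c(21, 22)),
                                  dm, "D"), ">= 5")
  same <- compare_conditions(a, a, dm, "D")
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_equal(same$delta_mean, 0)
  # planted -0.6 shift at n = 35/37 with exact unit SDs: the Welch
  # statistic is 0.6 / sqrt(1/35 + 1/37) = 2.55, detected at alpha 0.05
  a_x <- data.frame(residue = 1:35,
                    ratio = as.numeric(scale(rnorm(35))) + 22)
  b <- data.frame(residue = 1:37,
                  ratio = as.numeric(scale(rnorm(37))) + 21.4)
  cmp <- compare_conditions(a_x, b, dm, "D", trim_sd = Inf)
  expect_lt(cmp$p, 0.05)
  expect_lt(cmp$delta_mean, 0)
  # cross-check against stats::t.test on the same vectors
  ref <- stats::t.test(b$ratio, a_x$ratio, var.equal = FALSE)
  expect_equal(cmp$p, ref$p.value, tolerance = 1e-12)
})

test_that("fit_rates joins experiments and propagates the ratio", {
  gd <- gen_decay_dataset(seed = 55, domains = domain_map("D", 1, 30),
                          domain_tauc_true = c(D = 9.8), snr = 1e7,
                          ratio_scatter = 0)
  rt <- fit_rates(gd$r1_set, gd$r2_set, n_mc = 0)
  expect_equal(nrow(rt), 30L)
  expect_equal(rt$ratio, rt$r2 / rt$r1, tolerance = 1e-12)
  expect_equal(median(rt$ratio), ratio_from_tauc(9.8, 900),
               tolerance = 1e-3)
})
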