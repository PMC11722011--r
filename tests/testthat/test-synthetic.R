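test_that("generators are deterministic under a seed", {
  a <- gen_titration(7)
  b <- gen_titration(7)
  expect_identical(a, b)
  expect_false(identical(gen_titration(7)$series$peaklists[[2]]$peaks,
                         gen_titration(8)$series$peaklists[[2]]$peaks))
  d <- stats::setNames(runif(20, 5, 35), 1:20)
  expect_identical(gen_pre_dataset(7, d), gen_pre_dataset(7, d))
  expect_identical(gen_decay_dataset(7, snr = 30),
                   gen_decay_dataset(7, snr = 30))
  expect_identical(gen_competition_dataset(7), gen_competition_dataset(7))
})

test_that("titration generator: off-site residues never move", {
  g <- gen_titration(81, site = 30:48, noise_ppm = 0)
  off <- setdiff(1:81, 30:48)
  h0 <- g$series$peaklists[[1]]$peaks$h_ppm[off]
  for (pl in g$series$peaklists[-1])
    expect_equal(pl$peaks$h_ppm[off], h0, tolerance = 1e-12)
  # site residues saturate along the isotherm: monotone approach
  fb <- fraction_bound(1e-3, g$series$ligand_conc, 2e-3)
  site_h <- vapply(g$series$peaklists,
                   function(pl) pl$peaks$h_ppm[30], numeric(1))
  expect_equal(site_h - site_h[1], fb * g$truth$ddmax_h[30],
               tolerance = 1e-12)
})

test_that("PRE generator inverts the calibration", {
  d <- stats::setNames(c(30, 21, 5), c(1, 2, 3))
  g <- gen_pre_dataset(9, distances_true = d, alpha_true = 1,
                       noise_frac = 0)
  rr <- pre_ratios(g$para, g$dia)
  expect_equal(rr$raw_ratio[rr$residue == 1], 1)
  expect_equal(rr$raw_ratio[rr$residue == 2], 0.5)
  expect_equal(rr$status[rr$residue == 3], "disappeared")
  expect_equal(rr$raw_ratio[rr$residue == 3], 0)
  expect_equal(g$truth$disappeared, 3L)
})

test_that("decay generator hits the formula fixed points", {
  dm <- domain_map(c("zero", "mid"), c(1, 51), c(50, 120))
  g <- gen_decay_dataset(10, domains = dm,
                         domain_tauc_true = c(zero = 0, mid = 9.7514500),
                         snr = 1e9, ratio_scatter = 0)
  tr <- g$truth
  expect_equal(unname(tr$ratio[tr$domain == "zero"]),
               rep(7 / 6 + 1e-6, 50), tolerance = 1e-5)
  # tauc ~9.75 ns at 900 MHz corresponds to a ratio of 22
  expect_equal(unname(tr$ratio[tr$domain == "mid"]), rep(22, 70),
               tolerance = 1e-4)
  # a planted exchange fraction marks ~10% of residues in truth
  g2 <- gen_decay_dataset(11, domains = dm,
                          domain_tauc_true = c(zero = 5, mid = 9.75),
                          exchange_frac = 0.1, ratio_scatter = 0)
  expect_equal(length(g2$truth$exchange_residues), 12L)  # 5 + 7
})

test_that("competition generator encodes the designed classes", {
  g <- gen_competition_dataset(12, n_res = 50, shared_sites = c(5, 10),
                               client_only_sites = 20, broadened = 30L)
  expect_equal(g$plus_both$peaks$status[30], "disappeared")
  # shared sites move further in the both-ligand condition
  d_client <- abs(g$plus_client$peaks$h_ppm - g$free$peaks$h_ppm)
  d_both <- abs(g$plus_both$peaks$h_ppm - g$free$peaks$h_ppm)
  expect_true(all(d_both[c(5, 10)] > d_client[c(5, 10)]))
  expect_equal(d_both[20], d_client[20])
})
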