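#' Synthetic fast-exchange titration with known ground truth
#'
#' Simulates a two-state fast-exchange HSQC titration: peaks of binding-
#' site residues move along straight lines from their free positions
#' toward `free + ddmax`, with the fractional saturation at each ligand
#' concentration given by the exact quadratic binding isotherm; off-site
#' residues do not move. Gaussian position noise is added independently
#' in both dimensions at every point.
#'
#' Default conditions mirror a millimolar-affinity peptide titration into
#' an 81-residue domain at 1 mM protein with ligand points 0/0.5/1/2/3/4
#' mM.
#'
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @param n_res number of residues in the construct.
#' @param kd true dissociation constant (molar).
#' @param p_conc total protein concentration (molar).
#' @param l_concs ligand concentrations (molar), ascending from 0.
#' @param site integer vector of binding-site residues (nonzero ddmax).
#' @param noise_ppm SD of the additive 1H position noise (ppm); 15N noise
#'   is 5x larger, matching the wider 15N dispersion.
#' @param ddmax_h,ddmax_n limiting shift changes for site residues (ppm);
#'   recycled over the site.
#' @return List with `series` (a [titration_series()]) and `truth`
#'   (seed, kd, site, per-residue ddmax, free positions).
#' @export
gen_titration <- function(seed, n_res = 81, kd = 2e-3, p_conc = 1e-3,
                          l_concs = c(0, 0.5, 1, 2, 3, 4) * 1e-3,
                          site = 30:48, noise_ppm = 0,
                          ddmax_h = 0.08, ddmax_n = 0.5) {
  stopifnot(l_concs[1] == 0, all(diff(l_concs) > 0))
  withr_seed(seed)
  res <- seq_len(n_res)
  free_h <- stats::runif(n_res, 7.5, 9.5)
  free_n <- stats::runif(n_res, 105, 130)
  dh <- dn <- numeric(n_res)
  dh[site] <- rep_len(ddmax_h, length(site))
  dn[site] <- rep_len(ddmax_n, length(site))
  pls <- lapply(seq_along(l_concs), function(j) {
    fb <- fraction_bound(p_conc, l_concs[j], kd)
    peak_list(data.frame(
      residue = res, aa = "X",
      h_ppm = free_h + fb * dh + stats::rnorm(n_res, 0, noise_ppm),
      n_ppm = free_n + fb * dn + stats::rnorm(n_res, 0, 5 * noise_ppm),
      intensity = 1e6, status = "ok"),
      label = sprintf("L=%.3g M", l_concs[j]),
      ligand = if (j == 1) "" else "peptide",
      protein_conc = p_conc, ligand_conc = l_concs[j])
  })
  list(series = titration_series(pls, l_concs, p_conc),
       truth = list(seed = seed, kd = kd, site = site,
                    ddmax_h = dh, ddmax_n = dn,
                    free_h = free_h, free_n = free_n))
}

#' Synthetic paramagnetic/diamagnetic peak lists from true distances
#'
#' Inverts the linear PRE-distance calibration: each residue's true raw
#' intensity ratio is `clamp((d - 12)/18, 0, 1) / alpha_true`, with
#' multiplicative Gaussian noise on both intensities. Residues closer
#' than 12 angstrom to the spin label broaden beyond detection and are
#' emitted with disappeared status (always, at zero noise).
#'
#' @param seed integer seed.
#' @param distances_true named numeric vector of true label-to-amide
#'   distances (angstrom); names are residue numbers.
#' @param alpha_true true normalization factor (raw ratios are divided by
#'   it, emulating the relaxation-delay inflation of distant residues).
#' @param noise_frac SD of the multiplicative intensity noise (fraction
#'   of the mean).
#' @param i_dia_mean mean diamagnetic intensity (arbitrary units).
#' @return List with `para`, `dia` ([peak_list()]s) and `truth`.
#' @export
gen_pre_dataset <- function(seed, distances_true, alpha_true = 1,
                            noise_frac = 0, i_dia_mean = 1e6) {
  stopifnot(all(distances_true > 0), alpha_true > 0)
  withr_seed(seed)
  res <- as.integer(names(distances_true))
  if (any(is.na(res))) stop("distances_true must be named by residue number")
  n <- length(res)
  true_ratio <- distance_to_pre(distances_true) / alpha_true
  gone <- distances_true < 12
  i_dia <- i_dia_mean * (1 + stats::rnorm(n, 0, noise_frac))
  i_para <- i_dia * true_ratio * (1 + stats::rnorm(n, 0, noise_frac))
  h <- stats::runif(n, 7.5, 9.5); np <- stats::runif(n, 105, 130)
  dia <- peak_list(data.frame(residue = res, aa = "X", h_ppm = h, n_ppm = np,
                              intensity = i_dia, status = "ok"),
                   label = "diamagnetic")
  para <- peak_list(data.frame(residue = res, aa = "X", h_ppm = h, n_ppm = np,
                               intensity = ifelse(gone, 0, i_para),
                               status = ifelse(gone, "disappeared", "ok")),
                    label = "paramagnetic", ligand = "TEMPO-peptide")
  list(para = para, dia = dia,
       truth = list(seed = seed, distances = distances_true,
                    alpha = alpha_true, disappeared = res[gone]))
}

#' Synthetic 15N relaxation decay series with domain-structured dynamics
#'
#' Each domain is assigned a true apparent correlation time; the implied
#' R2/R1 ratio (inverse of the tau_c formula) is scattered across the
#' domain's residues with Gaussian residue-to-residue spread, R1 is drawn
#' around a plausible scale, and R2 = ratio * R1. A configurable fraction
#' of residues receives exchange-inflated R2. Intensity decays are then
#' sampled at the given delay lists with additive Gaussian noise at the
#' stated signal-to-noise ratio.
#'
#' @param seed integer seed.
#' @param domains a [domain_map()].
#' @param domain_tauc_true named numeric vector, ns, one entry per domain
#'   name.
#' @param nu_h_mhz 1H frequency (MHz).
#' @param delays_r1,delays_r2 delay lists in seconds (defaults: 20/300/600
#'   ms and 8.65/16.96/33.92 ms).
#' @param snr signal-to-noise ratio of the first decay point.
#' @param ratio_scatter residue-level SD of the R2/R1 ratio, as a fraction
#'   of the domain ratio.
#' @param r1_mean,r1_spread mean and fractional spread of the true R1.
#' @param exchange_frac fraction of residues per domain with
#'   exchange-inflated R2.
#' @param exchange_factor multiplicative R2 inflation for exchange
#'   residues.
#' @return List with `r1_set`, `r2_set` ([decay_set()]s) and `truth`
#'   (per-residue true rates and ratios, per-domain tau_c, exchange
#'   residues).
#' @export
gen_decay_dataset <- function(seed, domains = sis1_domains(),
                              domain_tauc_true = c("J-domain" = 9.8,
                                                   "GF" = 11.0, "GM" = 11.0,
                                                   "CTDI" = 18, "CTDII" = 18,
                                                   "DD" = 18),
                              nu_h_mhz = 900,
                              delays_r1 = c(0.020, 0.300, 0.600),
                              delays_r2 = c(0.00865, 0.01696, 0.03392),
                              snr = 50, ratio_scatter = 0.05,
                              r1_mean = 1.0, r1_spread = 0.05,
                              exchange_frac = 0, exchange_factor = 3) {
  stopifnot(inherits(domains, "domain_map"),
            all(domains$name %in% names(domain_tauc_true)))
  withr_seed(seed)
  res <- unlist(mapply(seq, domains$start, domains$end, SIMPLIFY = FALSE))
  dom <- domain_of(res, domains)
  ratio_dom <- ratio_from_tauc(domain_tauc_true[dom], nu_h_mhz)
  ratio <- ratio_dom * (1 + stats::rnorm(length(res), 0, ratio_scatter))
  ratio <- pmax(ratio, 7 / 6 + 1e-6)
  r1 <- r1_mean * (1 + stats::rnorm(length(res), 0, r1_spread))
  r2 <- ratio * r1
  exch <- logical(length(res))
  if (exchange_frac > 0) {
    for (dn in domains$name) {
      i <- which(dom == dn)
      n_ex <- round(exchange_frac * length(i))
      if (n_ex > 0) {
        pick <- sample(i, n_ex)
        r2[pick] <- r2[pick] * exchange_factor
        exch[pick] <- TRUE
      }
    }
    ratio <- r2 / r1
  }
  i0 <- 1e6
  sim_set <- function(delays, rate, experiment) {
    noise <- i0 / snr
    ints <- lapply(rate, function(r) {
      y <- i0 * exp(-r * delays) + stats::rnorm(length(delays), 0, noise)
      pmax(y, i0 * 1e-6)   # keep intensities positive for log-linear start
    })
    decay_set(res, delays, ints, noise_sigma = noise,
              experiment = experiment)
  }
  list(r1_set = sim_set(delays_r1, r1, "R1"),
       r2_set = sim_set(delays_r2, r2, "R2"),
       truth = list(seed = seed, residue = res, domain = dom,
                    r1 = r1, r2 = r2, ratio = ratio,
                    domain_tauc = domain_tauc_true,
                    exchange_residues = res[exch]))
}

#' Synthetic three-condition competition experiment
#'
#' Builds free / plus-client / plus-both peak lists. Client-site residues
#' shift in the client condition; shared-site residues shift further when
#' the competitor is added (the competitive signature); designated
#' residues are emitted as disappeared in the both-ligand list.
#'
#' @param seed integer seed.
#' @param n_res construct length.
#' @param shared_sites residues where client and competitor compete
#'   (larger CSP in the both condition).
#' @param client_only_sites residues perturbed by the client only.
#' @param broadened residues broadened beyond detection in the both
#'   condition.
#' @param shift_client combined-scale 1H shift (ppm) of client-site
#'   residues; 15N shifts are 5x larger.
#' @param boost factor by which shared-site shifts grow in the both
#'   condition.
#' @param noise_ppm additive 1H position noise SD (ppm).
#' @return List with `free`, `plus_client`, `plus_both` and `truth`.
#' @export
gen_competition_dataset <- function(seed, n_res = 352,
                                    shared_sites = c(189, 201:204, 217,
                                                     219, 231),
                                    client_only_sites = c(78, 91, 126),
                                    broadened = integer(0),
                                    shift_client = 0.05, boost = 1.6,
                                    noise_ppm = 0) {
  withr_seed(seed)
  res <- seq_len(n_res)
  free_h <- stats::runif(n_res, 7.5, 9.5)
  free_n <- stats::runif(n_res, 105, 130)
  dh <- numeric(n_res)
  dh[c(shared_sites, client_only_sites)] <- shift_client
  both_h <- dh
  both_h[shared_sites] <- dh[shared_sites] * boost
  mk <- function(delta_h, label, gone = integer(0)) {
    status <- ifelse(res %in% gone, "disappeared", "ok")
    peak_list(data.frame(
      residue = res, aa = "X",
      h_ppm = free_h + delta_h + stats::rnorm(n_res, 0, noise_ppm),
      n_ppm = free_n + 5 * delta_h + stats::rnorm(n_res, 0, 5 * noise_ppm),
      intensity = ifelse(status == "disappeared", 0, 1e6),
      status = status), label = label)
  }
  list(free = mk(numeric(n_res), "free"),
       plus_client = mk(dh, "plus_client"),
       plus_both = mk(both_h, "plus_both", gone = broadened),
       truth = list(seed = seed, shared_sites = shared_sites,
                    client_only_sites = client_only_sites,
                    broadened = broadened))
}

#' Synthetic structure-model ensemble by rigid jitter
#'
#' Builds a toy backbone (Cα trace) and an ensemble of copies with
#' isotropic Gaussian coordinate jitter, for exercising superposition
#' code without deposited structures. Clearly synthetic: coordinates are
#' a smooth helix-like curve, not a real protein.
#'
#' @param seed integer seed.
#' @param n_res number of residues.
#' @param n_models ensemble size.
#' @param jitter_sd per-coordinate Gaussian jitter (angstrom).
#' @return List with `reference` (a `structure_model`) and `ensemble`
#'   (list of jittered models).
#' @export
gen_structure_ensemble <- function(seed, n_res = 81, n_models = 20,
                                   jitter_sd = 0.5) {
  withr_seed(seed)
  t <- seq_len(n_res)
  ref <- data.frame(residue = t, aa = "A", atom = "CA", chain = "A",
                    x = 2.3 * cos(t / 1.75), y = 2.3 * sin(t / 1.75),
                    z = 1.5 * t, stringsAsFactors = FALSE)
  reference <- structure(ref, model_index = 0L,
                         class = c("structure_model", "data.frame"))
  ensemble <- lapply(seq_len(n_models), function(m) {
    jit <- ref
    jit$x <- jit$x + stats::rnorm(n_res, 0, jitter_sd)
    jit$y <- jit$y + stats::rnorm(n_res, 0, jitter_sd)
    jit$z <- jit$z + stats::rnorm(n_res, 0, jitter_sd)
    structure(jit, model_index = m,
              class = c("structure_model", "data.frame"))
  })
  list(reference = reference, ensemble = ensemble)
}

# seed the RNG for a generator call; every generator is a deterministic
# function of (seed, arguments) and shares no state across calls
withr_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            abs(seed) < 2^31)
  set.seed(as.integer(seed))
  invisible(seed)
}
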