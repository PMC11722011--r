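#' A set of intensity decay series for rate fitting
#'
#' @param residue integer vector, one entry per series.
#' @param delays list of numeric vectors (seconds), or a single vector
#'   shared by all series; each must be strictly increasing with >= 3
#'   points.
#' @param intensities list of numeric vectors matching `delays`.
#' @param noise_sigma per-series amplitude noise (scalar recycled).
#' @param experiment `"R1"` or `"R2"`.
#' @return Data-frame-backed object of class `decay_set` (one row per
#'   residue, list columns `delays`, `intensities`).
#' @export
decay_set <- function(residue, delays, intensities, noise_sigma,
                      experiment = c("R1", "R2")) {
  experiment <- match.arg(experiment)
  n <- length(residue)
  if (!is.list(delays)) delays <- rep(list(delays), n)
  stopifnot(length(delays) == n, length(intensities) == n)
  for (i in seq_len(n)) {
    d <- delays[[i]]
    if (length(d) < 3 || any(diff(d) <= 0))
      stop("each decay needs >= 3 strictly increasing delays (residue ",
           residue[i], ")")
    if (length(intensities[[i]]) != length(d))
      stop("delay/intensity length mismatch for residue ", residue[i])
  }
  noise_sigma <- rep_len(noise_sigma, n)
  structure(list(residue = as.integer(residue), delays = delays,
                 intensities = intensities, noise_sigma = noise_sigma,
                 experiment = experiment),
            class = "decay_set")
}

#' Fit a monoexponential decay I(t) = I0 * exp(-R * t)
#'
#' Nonlinear least squares with a log-linear initialization (ordinary
#' regression of log intensity on delay). The rate uncertainty is
#' estimated from the signal-to-noise ratio by Monte-Carlo resampling:
#' synthetic datasets are drawn around the fitted curve with Gaussian
#' noise of width `noise_sigma` and refit, and the standard deviation of
#' the refit rates is reported.
#'
#' @param delays delay times (seconds), strictly increasing, length >= 3.
#' @param intensities positive peak intensities at those delays.
#' @param noise_sigma amplitude noise for the Monte-Carlo error (skipped
#'   when 0 or `n_mc = 0`).
#' @param n_mc number of Monte-Carlo replicates (default 200).
#' @param seed optional integer seed for the resampling.
#' @return List with `rate` (1/s), `sigma`, `i0`, `fitted`, `degenerate`
#'   (TRUE when the decay is flat and the rate is pinned at 0).
#' @export
fit_monoexponential <- function(delays, intensities, noise_sigma = 0,
                                n_mc = 200, seed = NULL) {
  stopifnot(length(delays) == length(intensities), length(delays) >= 3,
            all(diff(delays) > 0))
  if (any(intensities <= 0))
    stop("monoexponential fit requires positive intensities")
  est <- fit_monoexp_core(delays, intensities)
  sigma <- NA_real_
  if (noise_sigma > 0 && n_mc > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed %% 2^31))
    curve <- est$i0 * exp(-est$rate * delays)
    ymat <- matrix(curve, length(delays), n_mc) +
      matrix(stats::rnorm(length(delays) * n_mc, 0, noise_sigma),
             length(delays), n_mc)
    ymat[ymat <= 0] <- .Machine$double.eps  # keep log-linear starts usable
    sigma <- stats::sd(gn_monoexp(delays, ymat)$rate)
  }
  list(rate = est$rate, sigma = sigma, i0 = est$i0,
       fitted = est$i0 * exp(-est$rate * delays),
       degenerate = est$degenerate)
}

# single-series least squares via the shared Gauss-Newton kernel
fit_monoexp_core <- function(t, y) {
  if (stats::sd(y) / mean(y) < 1e-12)
    return(list(rate = 0, i0 = mean(y), degenerate = TRUE))
  fit <- gn_monoexp(t, matrix(y, ncol = 1))
  if (fit$rate <= 0)
    return(list(rate = 0, i0 = mean(y), degenerate = TRUE))
  list(rate = fit$rate, i0 = fit$i0, degenerate = FALSE)
}

# Gauss-Newton least squares for y = a * exp(-r t), vectorized over the
# columns of ymat (each column one dataset sharing the delay vector).
# Log-linear regression of log y on t provides the start; the 2x2 normal
# equations are solved in closed form per column.
gn_monoexp <- function(t, ymat, max_iter = 60, tol = 1e-13) {
  beta <- qr.solve(cbind(1, t), log(ymat))
  beta <- matrix(beta, nrow = 2L)
  a <- exp(beta[1L, ]); r <- pmax(-beta[2L, ], 0)
  for (iter in seq_len(max_iter)) {
    e <- exp(-outer(t, r))                  # n_t x n_col
    f <- sweep(e, 2, a, `*`)
    resid <- ymat - f
    j2 <- -t * f                            # d model / d r
    s11 <- colSums(e * e); s12 <- colSums(e * j2); s22 <- colSums(j2 * j2)
    g1 <- colSums(e * resid); g2 <- colSums(j2 * resid)
    det <- s11 * s22 - s12^2
    ok <- is.finite(det) & det > 0
    da <- ifelse(ok, (s22 * g1 - s12 * g2) / det, 0)
    dr <- ifelse(ok, (s11 * g2 - s12 * g1) / det, 0)
    # damped step: halve until the rate stays finite and non-negative
    step <- rep(1, length(a))
    a_new <- a + da; r_new <- r + dr
    bad <- r_new < 0 | !is.finite(a_new) | !is.finite(r_new)
    k <- 0L
    while (any(bad) && k < 30L) {
      step[bad] <- step[bad] / 2
      a_new <- a + step * da; r_new <- r + step * dr
      bad <- r_new < 0 | !is.finite(a_new) | !is.finite(r_new)
      k <- k + 1L
    }
    a_new[bad] <- a[bad]; r_new[bad] <- r[bad]
    moved <- max(abs(a_new - a) / pmax(abs(a), 1e-300),
                 abs(r_new - r) / pmax(abs(r), 1e-300))
    a <- a_new; r <- r_new
    if (moved < tol) break
  }
  list(i0 = unname(a), rate = unname(r))
}

#' Fit R1 and R2 decay sets into a per-residue rate table
#'
#' @param r1_set,r2_set [decay_set()] objects for the longitudinal and
#'   transverse experiments; residues are matched by number.
#' @param n_mc Monte-Carlo replicates for the per-rate sigma (0 disables).
#' @param seed integer seed for the error resampling.
#' @return Data frame of class `rate_table`: `residue`, `r1`, `r1_sigma`,
#'   `r2`, `r2_sigma`, `ratio`, `ratio_sigma`, `degenerate`.
#' @export
fit_rates <- function(r1_set, r2_set, n_mc = 200, seed = NULL) {
  stopifnot(inherits(r1_set, "decay_set"), inherits(r2_set, "decay_set"))
  common <- intersect(r1_set$residue, r2_set$residue)
  if (!length(common)) stop("no residues common to the R1 and R2 sets")
  one <- function(set, res, seed_off) {
    i <- match(res, set$residue)
    fit_monoexponential(set$delays[[i]], set$intensities[[i]],
                        noise_sigma = set$noise_sigma[i], n_mc = n_mc,
                        seed = if (is.null(seed)) NULL else seed + seed_off)
  }
  rows <- lapply(seq_along(common), function(k) {
    res <- common[k]
    f1 <- one(r1_set, res, 2L * k)
    f2 <- one(r2_set, res, 2L * k + 1L)
    ratio <- if (f1$rate > 0) f2$rate / f1$rate else NA_real_
    ratio_sigma <- if (f1$rate > 0 && is.finite(f1$sigma) &&
                       is.finite(f2$sigma))
      abs(ratio) * sqrt((f1$sigma / f1$rate)^2 + (f2$sigma / f2$rate)^2)
    else NA_real_
    data.frame(residue = res, r1 = f1$rate, r1_sigma = f1$sigma,
               r2 = f2$rate, r2_sigma = f2$sigma,
               ratio = ratio, ratio_sigma = ratio_sigma,
               degenerate = f1$degenerate || f2$degenerate)
  })
  structure(do.call(rbind, rows), class = c("rate_table", "data.frame"))
}

#' Apparent rotational correlation time from the R2/R1 ratio
#'
#' For isotropic tumbling dominated by the 15N CSA/dipolar spectral
#' density, the correlation time follows from the R2/R1 ratio as
#' `tau_c = sqrt(6 * R2/R1 - 7) / (4 * pi * nu_N)` with `nu_N` the 15N
#' resonance frequency in Hz. The 15N frequency is derived from the 1H
#' field via the gyromagnetic-ratio magnitude quotient (0.1013756 by
#' default, i.e. about 91.2 MHz at 900 MHz).
#'
#' @param ratio R2/R1 ratio(s); must be >= 7/6 (the radicand is negative
#'   below that).
#' @param nu_h_mhz 1H spectrometer frequency (MHz).
#' @param gamma_ratio |gamma_15N| / |gamma_1H|.
#' @return Apparent correlation time(s) in ns.
#' @examples
#' tauc_from_ratio(22, 900)  # ~9.8 ns
#' tauc_from_ratio(70, 900)  # ~18 ns
#' @export
tauc_from_ratio <- function(ratio, nu_h_mhz, gamma_ratio = 0.1013756) {
  if (any(!is.finite(ratio)) || any(ratio < 7 / 6))
    stop("R2/R1 must be >= 7/6 for a real correlation time")
  nu_n <- gamma_ratio * nu_h_mhz * 1e6
  sqrt(6 * ratio - 7) / (4 * pi * nu_n) * 1e9
}

#' Inverse of [tauc_from_ratio()]
#'
#' @param tauc_ns correlation time(s) in ns.
#' @inheritParams tauc_from_ratio
#' @return The R2/R1 ratio(s) implied by isotropic tumbling.
#' @export
ratio_from_tauc <- function(tauc_ns, nu_h_mhz, gamma_ratio = 0.1013756) {
  stopifnot(all(tauc_ns >= 0))
  nu_n <- gamma_ratio * nu_h_mhz * 1e6
  ((4 * pi * nu_n * tauc_ns * 1e-9)^2 + 7) / 6
}

#' Per-domain dynamics: trimmed R2/R1 and apparent correlation time
#'
#' For each domain, residues with finite ratios are trimmed once to those
#' within one standard deviation of the domain mean (excluding
#' conformational exchange and thermal flexibility outliers), the mean is
#' recomputed on the retained set, and the apparent correlation time is
#' derived from that trimmed mean. The tau_c uncertainty is obtained by
#' first-order propagation of the trimmed-ratio standard error through
#' the tau_c formula.
#'
#' @param rates a `rate_table` (see [fit_rates()]) or data frame with
#'   `residue` and `ratio`.
#' @param domains a [domain_map()].
#' @param nu_h_mhz 1H frequency (MHz).
#' @param trim_sd width of the retention window in SDs (default 1).
#' @return Data frame of class `domain_dynamics`: `domain`, `n_available`,
#'   `n_used`, `mean_ratio`, `sd_ratio`, `tauc_ns`, `tauc_sigma_ns`.
#'   Domains with fewer than 2 usable records are skipped with a warning.
#' @export
domain_dynamics <- function(rates, domains, nu_h_mhz, trim_sd = 1) {
  stopifnot(inherits(domains, "domain_map"))
  dom <- domain_of(rates$residue, domains)
  rows <- lapply(domains$name, function(dn) {
    r <- rates$ratio[dom == dn & is.finite(rates$ratio)]
    if (length(r) < 2) {
      warning("domain '", dn, "' has fewer than 2 usable ratios; skipped")
      return(NULL)
    }
    mu <- mean(r); s <- stats::sd(r)
    keep <- abs(r - mu) <= trim_sd * s
    if (!any(keep)) keep <- rep(TRUE, length(r))   # never empty a domain
    rt <- r[keep]
    mu_t <- mean(rt)
    sd_t <- if (length(rt) > 1) stats::sd(rt) else 0
    tauc <- if (mu_t >= 7 / 6) tauc_from_ratio(mu_t, nu_h_mhz) else NA_real_
    # d tau/d ratio = 3 / (4 pi nu_N sqrt(6r - 7)); propagate SE of the mean
    tauc_sigma <- if (is.finite(tauc) && mu_t > 7 / 6) {
      nu_n <- 0.1013756 * nu_h_mhz * 1e6
      (3 / (4 * pi * nu_n * sqrt(6 * mu_t - 7))) * 1e9 * sd_t
    } else NA_real_
    data.frame(domain = dn, n_available = length(r), n_used = sum(keep),
               mean_ratio = mu_t, sd_ratio = sd_t,
               tauc_ns = tauc, tauc_sigma_ns = tauc_sigma,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  structure(do.call(rbind, rows),
            class = c("domain_dynamics", "data.frame"))
}

#' Flag residues in conformational exchange
#'
#' A residue is flagged when its R2/R1 ratio exceeds the untrimmed domain
#' mean by more than one untrimmed domain standard deviation — elevated
#' transverse relaxation is the signature of microsecond-to-millisecond
#' exchange broadening.
#'
#' @param rates a `rate_table` or data frame with `residue`, `ratio`.
#' @param domains a [domain_map()].
#' @param k multiplier on the domain SD (default 1).
#' @return The input with a logical `exchange_flag` column added.
#' @export
flag_exchange <- function(rates, domains, k = 1) {
  dom <- domain_of(rates$residue, domains)
  flag <- rep(FALSE, nrow(rates))
  for (dn in unique(dom[!is.na(dom)])) {
    i <- which(dom == dn & is.finite(rates$ratio))
    if (length(i) < 2) next
    mu <- mean(rates$ratio[i]); s <- stats::sd(rates$ratio[i])
    flag[i] <- rates$ratio[i] > mu + k * s
  }
  rates$exchange_flag <- flag
  rates
}

#' Compare per-domain R2/R1 between two conditions
#'
#' Welch's unequal-variance two-sample t-test on the per-residue trimmed
#' R2/R1 ratios of one domain under two conditions (e.g. free vs
#' ligand-bound).
#'
#' @param rates_a,rates_b rate tables for the two conditions.
#' @param domains a [domain_map()].
#' @param domain name of the domain to compare.
#' @param trim_sd trim window applied within each condition before the
#'   test (`Inf` to disable).
#' @return List with `delta_mean` (b minus a), `t`, `df`, `p`, `n_a`,
#'   `n_b`.
#' @export
compare_conditions <- function(rates_a, rates_b, domains, domain,
                               trim_sd = 1) {
  pick <- function(rates) {
    dom <- domain_of(rates$residue, domains)
    r <- rates$ratio[dom == domain & is.finite(rates$ratio)]
    if (is.finite(trim_sd) && length(r) > 2) {
      mu <- mean(r); s <- stats::sd(r)
      r <- r[abs(r - mu) <= trim_sd * s]
    }
    r
  }
  a <- pick(rates_a); b <- pick(rates_b)
  if (length(a) < 5 || length(b) < 5)
    stop("need >= 5 ratios per condition in domain '", domain, "' (got ",
         length(a), " and ", length(b), ")")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(delta_mean = mean(b) - mean(a),
                t = if (same) 0 else Inf, df = NA_real_,
                p = if (same) 1 else 0,
                n_a = length(a), n_b = length(b)))
  }
  tt <- stats::t.test(b, a, var.equal = FALSE)
  list(delta_mean = unname(mean(b) - mean(a)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_a = length(a), n_b = length(b))
}
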