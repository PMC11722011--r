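#' Bound fraction under the quadratic (exact two-state) binding isotherm
#'
#' For protein at total concentration `p`, ligand at total `l` and
#' dissociation constant `kd` (all in the same molarity units), the exact
#' bound fraction of protein is
#' `((p + l + kd) - sqrt((p + l + kd)^2 - 4 p l)) / (2 p)`.
#' In the weak-binding limit (`p -> 0`) this reduces to `l / (l + kd)`.
#'
#' @param p,l,kd total protein, total ligand, dissociation constant.
#' @return Bound fraction in `[0, 1]` (vectorized over `l`).
#' @export
fraction_bound <- function(p, l, kd) {
  stopifnot(p > 0, kd > 0, all(l >= 0))
  s <- p + l + kd
  # algebraically (s - sqrt(s^2 - 4pl)) / 2p; this form avoids the
  # catastrophic cancellation of the direct root at small p
  fb <- 2 * l / (s + sqrt(s^2 - 4 * p * l))
  pmin(pmax(fb, 0), 1)
}

#' Assemble a titration series
#'
#' @param peaklists list of [peak_list()] objects, ordered by ligand
#'   concentration; the first point must be ligand-free.
#' @param ligand_conc total ligand concentrations (molar), strictly
#'   increasing from 0.
#' @param protein_conc total protein concentration (molar).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(peaklists, ligand_conc, protein_conc) {
  stopifnot(length(peaklists) == length(ligand_conc),
            all(vapply(peaklists, inherits, logical(1), "peak_list")))
  if (ligand_conc[1] != 0)
    stop("first titration point must be ligand-free (ligand_conc[1] == 0)")
  if (any(diff(ligand_conc) <= 0))
    stop("ligand concentrations must be strictly increasing")
  structure(list(peaklists = peaklists, ligand_conc = ligand_conc,
                 protein_conc = protein_conc),
            class = "titration_series")
}

#' Fit a shared dissociation constant to a fast-exchange titration
#'
#' In fast exchange the observed peak position at each titration point is
#' the population-weighted average of the free and bound positions, so the
#' observed combined shift change of residue i at point j is
#' `csp_ij = f_bound(P, L_j, K_D) * ddmax_i`. All residues share one K_D;
#' each has its own limiting shift `ddmax_i`. For a trial K_D the ddmax
#' values are the exact linear least-squares solution, so the fit reduces
#' to a 1-D optimization of the profiled residual sum of squares over
#' log K_D. The asymptotic standard error of K_D comes from a finite-
#' difference second derivative of the profile at the optimum.
#'
#' @param series a [titration_series()].
#' @param residues residues to include; default all residues whose maximal
#'   observed shift exceeds `min_shift`.
#' @param min_shift inclusion threshold (ppm) on the largest observed
#'   combined shift of a residue; keeps unperturbed residues from diluting
#'   the fit.
#' @param kd_bounds search interval for K_D (molar).
#' @return An object of class `binding_fit` with components `kd`, `kd_sigma`,
#'   `ddmax` (named per-residue limiting shifts, ppm), `residues`, `rss`,
#'   `fitted`, `observed`, `series`.
#' @export
fit_kd_fast_exchange <- function(series, residues = NULL, min_shift = 1e-4,
                                 kd_bounds = c(1e-8, 1)) {
  stopifnot(inherits(series, "titration_series"))
  nl <- length(series$ligand_conc)
  if (nl < 4) stop("need at least 4 titration points to fit K_D")
  free <- series$peaklists[[1L]]
  # observed combined shift of each residue at each point, vs the free state
  obs <- lapply(series$peaklists[-1L], function(pl) {
    m <- match_peaks(free, pl)$pairs
    m <- m[m$status_b == "ok", ]
    data.frame(residue = m$residue,
               csp = compute_csp(m$h_ppm_b - m$h_ppm_a,
                                 m$n_ppm_b - m$n_ppm_a))
  })
  res_all <- sort(Reduce(intersect, lapply(obs, `[[`, "residue")))
  shift_mat <- vapply(obs, function(o) o$csp[match(res_all, o$residue)],
                      numeric(length(res_all)))
  shift_mat <- matrix(shift_mat, nrow = length(res_all))
  rownames(shift_mat) <- res_all
  if (is.null(residues)) {
    keep <- apply(shift_mat, 1L, max) > min_shift
    residues <- res_all[keep]
  }
  shift_mat <- shift_mat[match(residues, res_all), , drop = FALSE]
  if (!nrow(shift_mat) || all(abs(shift_mat) < .Machine$double.eps))
    stop("no residue shows a shift response; K_D is unidentifiable")
  l <- series$ligand_conc[-1L]
  p <- series$protein_conc

  profile_rss <- function(log_kd) {
    fb <- fraction_bound(p, l, exp(log_kd))
    ss <- sum(fb^2)
    if (ss == 0) return(sum(shift_mat^2))
    ddmax <- as.numeric(shift_mat %*% fb) / ss   # per-residue LS solution
    sum((shift_mat - outer(ddmax, fb))^2)
  }
  opt <- stats::optimize(profile_rss, log(kd_bounds), tol = 1e-12)
  log_kd <- opt$minimum
  if (min(abs(log_kd - log(kd_bounds))) < 1e-6)
    warning("K_D estimate at the edge of the search interval; ",
            "the titration may not constrain it")
  kd <- exp(log_kd)
  fb <- fraction_bound(p, l, kd)
  ddmax <- as.numeric(shift_mat %*% fb) / sum(fb^2)
  names(ddmax) <- residues
  fitted <- outer(ddmax, fb)
  rss <- sum((shift_mat - fitted)^2)
  # asymptotic sigma: curvature of the profile in log K_D, delta method
  n_obs <- length(shift_mat)
  n_par <- 1L + length(ddmax)
  sigma2 <- rss / max(n_obs - n_par, 1L)
  h <- 1e-4
  d2 <- (profile_rss(log_kd + h) - 2 * opt$objective +
           profile_rss(log_kd - h)) / h^2
  kd_sigma <- if (is.finite(d2) && d2 > 0)
    kd * sqrt(2 * sigma2 / d2) else NA_real_
  structure(list(kd = kd, kd_sigma = kd_sigma, ddmax = ddmax,
                 residues = residues, rss = rss,
                 fitted = fitted, observed = shift_mat,
                 ligand_conc = l, protein_conc = p),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit>  K_D = %.3g M (sigma %.2g), %d residues, RSS %.3g\n",
              x$kd, x$kd_sigma, length(x$ddmax), x$rss))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kd = object$kd, object$ddmax)
}

#' @export
predict.binding_fit <- function(object, ligand_conc = object$ligand_conc, ...) {
  fb <- fraction_bound(object$protein_conc, ligand_conc, object$kd)
  outer(object$ddmax, fb)
}
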