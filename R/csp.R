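#' Combined 1H/15N chemical shift perturbation
#'
#' The standard combined amide CSP with the 15N difference scaled down by
#' 10: `sqrt((d_n / 10)^2 + d_h^2)`. The scaling compensates for the wider
#' 15N dispersion so both nuclei contribute comparably.
#'
#' @param d_h backbone amide 1H shift difference (ppm), bound minus free.
#' @param d_n backbone amide 15N shift difference (ppm).
#' @param n_scale divisor applied to `d_n`; the conventional value 10 is
#'   the default and is what all other functions in the package use.
#' @return Combined CSP in ppm (vectorized); non-negative, zero only when
#'   both inputs are zero, and invariant under sign flips of either input.
#' @examples
#' compute_csp(0.02, 0.10)   # 0.02236
#' @export
compute_csp <- function(d_h, d_n, n_scale = 10) {
  stopifnot(all(is.finite(d_h)), all(is.finite(d_n)), n_scale > 0)
  sqrt((d_n / n_scale)^2 + d_h^2)
}

#' Match two peak lists by assignment
#'
#' Pairs peaks between two conditions by residue number. Only assigned,
#' non-overlapped peaks participate; overlapped peaks are excluded from
#' analysis (and reported), unassigned peaks are ignored, and residues seen
#' in one list only are reported as unmatched rather than fabricated.
#' A peak that is present in `a` but marked disappeared in `b` is matched
#' (downstream stages treat its intensity as zero).
#'
#' @param a,b two [peak_list()] objects sharing an assignment namespace.
#' @return A list with `pairs` (data frame: residue, aa, shifts and
#'   intensities in both conditions, status in b), `unmatched_a`,
#'   `unmatched_b` (residue numbers), `overlapped` (residues excluded).
#' @export
match_peaks <- function(a, b) {
  stopifnot(inherits(a, "peak_list"), inherits(b, "peak_list"))
  pa <- a$peaks[!is.na(a$peaks$residue), ]
  pb <- b$peaks[!is.na(b$peaks$residue), ]
  overlapped <- sort(unique(c(pa$residue[pa$status == "overlapped"],
                              pb$residue[pb$status == "overlapped"])))
  pa <- pa[pa$status != "overlapped", ]
  pb <- pb[pb$status != "overlapped", ]
  common <- intersect(pa$residue, pb$residue)
  ia <- match(common, pa$residue)
  ib <- match(common, pb$residue)
  pairs <- data.frame(residue = common,
                      aa = pa$aa[ia],
                      h_ppm_a = pa$h_ppm[ia], n_ppm_a = pa$n_ppm[ia],
                      intensity_a = pa$intensity[ia],
                      h_ppm_b = pb$h_ppm[ib], n_ppm_b = pb$n_ppm[ib],
                      intensity_b = pb$intensity[ib],
                      status_a = pa$status[ia],
                      status_b = pb$status[ib],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$residue), ]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_a = sort(setdiff(pa$residue, common)),
       unmatched_b = sort(setdiff(pb$residue, common)),
       overlapped = overlapped)
}

#' CSP significance threshold
#'
#' The significance rule: a residue's CSP is significant when it exceeds
#' the mean plus `k` standard deviations of the CSP distribution over all
#' matched, non-overlapped residues of the construct (one global threshold,
#' not per domain). Sample (n-1) standard deviation is used.
#'
#' @param csp numeric vector of combined CSPs (ppm).
#' @param k multiplier on the standard deviation (default 1).
#' @return Threshold in ppm.
#' @export
csp_significance_threshold <- function(csp, k = 1) {
  csp <- csp[is.finite(csp)]
  if (length(csp) < 3)
    stop("need at least 3 CSP values to set a significance threshold")
  mean(csp) + k * stats::sd(csp)
}

#' Per-residue CSP profile between two conditions
#'
#' Matches the two lists, computes the combined CSP per residue, applies
#' the mean + k*SD significance rule, and summarizes significant residues
#' by domain.
#'
#' @param free,bound [peak_list()] objects for the reference and perturbed
#'   conditions.
#' @param domains optional [domain_map()] for the per-domain summary.
#' @param k threshold multiplier (default 1 SD above the mean).
#' @return An object of class `csp_profile`: a data frame with columns
#'   `residue`, `aa`, `domain`, `d_h`, `d_n`, `csp`, `significant`, plus
#'   attributes `threshold`, `k`, `unmatched`, `overlapped`.
#' @export
csp_profile <- function(free, bound, domains = NULL, k = 1) {
  m <- match_peaks(free, bound)
  p <- m$pairs
  # disappeared peaks have no bound-state position; no CSP record for them
  gone <- p$status_b == "disappeared" | p$status_a == "disappeared"
  p <- p[!gone, ]
  d_h <- p$h_ppm_b - p$h_ppm_a
  d_n <- p$n_ppm_b - p$n_ppm_a
  csp <- compute_csp(d_h, d_n)
  thr <- csp_significance_threshold(csp, k)
  out <- data.frame(residue = p$residue, aa = p$aa,
                    domain = if (is.null(domains)) NA_character_
                             else domain_of(p$residue, domains),
                    d_h = d_h, d_n = d_n, csp = csp,
                    significant = csp > thr,
                    stringsAsFactors = FALSE)
  structure(out, class = c("csp_profile", "data.frame"),
            threshold = thr, k = k,
            unmatched = list(free = m$unmatched_a, bound = m$unmatched_b),
            overlapped = m$overlapped,
            disappeared = m$pairs$residue[gone])
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf("<csp_profile>  %d residues, threshold %.4f ppm (mean + %g SD)\n",
              nrow(x), attr(x, "threshold"), attr(x, "k")))
  sig <- x$residue[x$significant]
  cat("significant:", if (length(sig)) paste(sig, collapse = " ") else "none",
      "\n")
  invisible(x)
}

#' @export
summary.csp_profile <- function(object, ...) {
  sig <- object[object$significant, ]
  by_dom <- split(sig$residue, sig$domain)
  structure(list(n = nrow(object),
                 threshold = attr(object, "threshold"),
                 n_significant = nrow(sig),
                 significant_by_domain = by_dom,
                 overlapped = attr(object, "overlapped"),
                 disappeared = attr(object, "disappeared")),
            class = "summary.csp_profile")
}

#' @export
print.summary.csp_profile <- function(x, ...) {
  cat(sprintf("CSP profile: %d residues, %d significant (threshold %.4f ppm)\n",
              x$n, x$n_significant, x$threshold))
  for (d in names(x$significant_by_domain))
    cat(sprintf("  %s: %s\n", d,
                paste(x$significant_by_domain[[d]], collapse = " ")))
  if (length(x$disappeared))
    cat("broadened beyond detection:",
        paste(x$disappeared, collapse = " "), "\n")
  invisible(x)
}
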