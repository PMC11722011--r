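#' Classify binding-site competition across three conditions
#'
#' Given peak lists for the free protein, the protein plus a client
#' ligand, and the same sample after adding a competitor, each matched
#' residue is classified from its two CSPs against the free state:
#' \describe{
#'   \item{`none`}{client CSP below the significance threshold}
#'   \item{`client_only`}{significant client CSP, not increased by the
#'     competitor (`csp_both <= csp_client + margin`)}
#'   \item{`competitive`}{significant client CSP that grows further when
#'     the competitor is added — the signature of both ligands engaging
#'     the same site}
#'   \item{`broadened`}{peak present in the free state but disappeared in
#'     a ligand condition (exchange broadening beyond detection)}
#' }
#' The threshold is the mean + `k` SD rule computed on the client-vs-free
#' comparison.
#'
#' @param free,plus_client,plus_both [peak_list()] objects for the three
#'   conditions.
#' @param domains optional [domain_map()] for domain annotation.
#' @param k significance-threshold multiplier.
#' @param margin required excess of `csp_both` over `csp_client` for a
#'   competitive call (ppm, default 0: strict inequality).
#' @return Data frame of class `competition_profile`: `residue`, `aa`,
#'   `domain`, `csp_client`, `csp_both`, `class`; attribute `threshold`.
#' @export
competition_profile <- function(free, plus_client, plus_both,
                                domains = NULL, k = 1, margin = 0) {
  for (pl in list(free, plus_client, plus_both))
    if (!inherits(pl, "peak_list"))
      stop("all three conditions must be peak_list objects")
  mc <- match_peaks(free, plus_client)$pairs
  mb <- match_peaks(free, plus_both)$pairs
  common <- intersect(mc$residue, mb$residue)
  ic <- match(common, mc$residue); ib <- match(common, mb$residue)
  gone <- mc$status_b[ic] == "disappeared" | mb$status_b[ib] == "disappeared"
  csp_client <- ifelse(mc$status_b[ic] == "disappeared", NA_real_,
                       compute_csp(mc$h_ppm_b[ic] - mc$h_ppm_a[ic],
                                   mc$n_ppm_b[ic] - mc$n_ppm_a[ic]))
  csp_both <- ifelse(mb$status_b[ib] == "disappeared", NA_real_,
                     compute_csp(mb$h_ppm_b[ib] - mb$h_ppm_a[ib],
                                 mb$n_ppm_b[ib] - mb$n_ppm_a[ib]))
  thr <- csp_significance_threshold(csp_client[!gone], k)
  cls <- character(length(common))
  cls[gone] <- "broadened"
  sig <- !gone & csp_client > thr
  cls[!gone & !sig] <- "none"
  cls[sig & csp_both > csp_client + margin] <- "competitive"
  cls[sig & csp_both <= csp_client + margin] <- "client_only"
  out <- data.frame(residue = common, aa = mc$aa[ic],
                    domain = if (is.null(domains)) NA_character_
                             else domain_of(common, domains),
                    csp_client = csp_client, csp_both = csp_both,
                    class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$residue), ]
  rownames(out) <- NULL
  structure(out, class = c("competition_profile", "data.frame"),
            threshold = thr, k = k, margin = margin)
}

#' @export
print.competition_profile <- function(x, ...) {
  tab <- table(factor(x$class, c("none", "client_only", "competitive",
                                 "broadened")))
  cat(sprintf("<competition_profile>  %d residues, threshold %.4f ppm\n",
              nrow(x), attr(x, "threshold")))
  cat(sprintf("  none %d | client_only %d | competitive %d | broadened %d\n",
              tab["none"], tab["client_only"], tab["competitive"],
              tab["broadened"]))
  comp <- x$residue[x$class == "competitive"]
  if (length(comp))
    cat("  competitive residues:", paste(comp, collapse = " "), "\n")
  invisible(x)
}
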