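#' Domain map of a protein construct
#'
#' An ordered set of named, non-overlapping, ascending residue ranges
#' (1-based, inclusive). Used to group per-residue observables by domain
#' for relaxation summaries and site reports.
#'
#' @param name character vector of domain names.
#' @param start,end integer vectors of first/last residue numbers.
#' @return A data frame of class `domain_map` with columns
#'   `name`, `start`, `end`.
#' @examples
#' sis1_domains()
#' @export
domain_map <- function(name, start, end) {
  stopifnot(length(name) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L)) stop("domain ranges are 1-based; start must be >= 1")
  if (any(start > end)) stop("domain start must be <= end")
  o <- order(start)
  name <- name[o]; start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)]))
    stop("domain ranges must not overlap")
  structure(data.frame(name = as.character(name), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("domain_map", "data.frame"))
}

#' Domain architecture of full-length Sis1
#'
#' The class B J-domain protein Sis1 (UniProt P25294): J-domain, the
#' glycine-rich GF and GM linkers, the two beta-barrel C-terminal domains
#' and the dimerization domain.
#'
#' @return A [domain_map()] covering residues 1-352.
#' @export
sis1_domains <- function() {
  domain_map(name  = c("J-domain", "GF", "GM", "CTDI", "CTDII", "DD"),
             start = c(1L, 73L, 122L, 179L, 258L, 336L),
             end   = c(72L, 121L, 178L, 257L, 335L, 352L))
}

#' Map residue numbers to domain names
#'
#' @param residue integer vector of residue numbers.
#' @param domains a [domain_map()].
#' @return Character vector of domain names (`NA` when a residue falls in
#'   no domain).
#' @export
domain_of <- function(residue, domains) {
  stopifnot(inherits(domains, "domain_map"))
  idx <- vapply(residue, function(r) {
    hit <- which(domains$start <= r & r <= domains$end)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  domains$name[idx]
}
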