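#' Build a PRE record table from paramagnetic/diamagnetic peak lists
#'
#' Matches the two lists by assignment and forms the raw intensity ratio
#' `Ipara / Idia` per residue. Peaks marked disappeared in the paramagnetic
#' condition get ratio 0 (complete broadening); overlapped peaks are
#' excluded.
#'
#' @param para,dia [peak_list()] objects for the paramagnetic and
#'   diamagnetic (reduced spin label) samples.
#' @return Data frame with columns `residue`, `aa`, `i_para`, `i_dia`,
#'   `raw_ratio`, `status`.
#' @export
pre_ratios <- function(para, dia) {
  m <- match_peaks(dia, para)$pairs
  if (any(m$intensity_a <= 0 & m$status_b != "disappeared"))
    stop("non-positive diamagnetic intensity for residue(s): ",
         paste(m$residue[m$intensity_a <= 0 & m$status_b != "disappeared"],
               collapse = ", "))
  data.frame(residue = m$residue, aa = m$aa,
             i_para = m$intensity_b, i_dia = m$intensity_a,
             raw_ratio = ifelse(m$status_b == "disappeared", 0,
                                m$intensity_b / m$intensity_a),
             status = m$status_b, stringsAsFactors = FALSE)
}

#' Normalize PRE intensity ratios
#'
#' Raw `Ipara/Idia` ratios can exceed 1 (longer longitudinal relaxation in
#' the diamagnetic sample combined with a short recycle delay), so a
#' multiplicative correction factor alpha is applied such that the average
#' normalized PRE over residues distant from the paramagnetic center
#' equals exactly 1: `alpha = 1 / mean(raw_ratio over reference)`.
#'
#' With `reference = "auto"` the reference set is found by iterative
#' sigma-clipping: starting from all non-disappeared residues, residues
#' with raw ratio below 0.8 times the current mean are dropped and the
#' mean recomputed, for two passes. This reproduces "distant residues
#' average to 1" without needing a structure.
#'
#' @param records data frame from [pre_ratios()] (needs `residue`,
#'   `raw_ratio`).
#' @param reference `"auto"` or an integer vector of reference residue
#'   numbers.
#' @return A list with `alpha` and `records` (the input plus `pre`, the
#'   normalized ratio, and `in_reference`).
#' @export
normalize_pre <- function(records, reference = "auto") {
  stopifnot(is.data.frame(records),
            all(c("residue", "raw_ratio") %in% names(records)))
  if (nrow(records) < 5) stop("need at least 5 PRE records to normalize")
  if (identical(reference, "auto")) {
    cand <- records$residue
    for (pass in 1:2) {
      mu <- mean(records$raw_ratio[records$residue %in% cand])
      cand <- records$residue[records$residue %in% cand &
                                records$raw_ratio >= 0.8 * mu]
    }
    reference <- cand
  } else {
    missing_ref <- setdiff(reference, records$residue)
    if (length(missing_ref))
      stop("reference residue(s) absent from the data: ",
           paste(missing_ref, collapse = ", "))
  }
  ref_ratios <- records$raw_ratio[records$residue %in% reference]
  if (!length(ref_ratios) || mean(ref_ratios) <= 0)
    stop("empty or degenerate PRE reference set; cannot normalize")
  alpha <- 1 / mean(ref_ratios)
  records$pre <- alpha * records$raw_ratio
  records$in_reference <- records$residue %in% reference
  list(alpha = alpha, records = records)
}

#' Convert a normalized PRE to a calibrated distance
#'
#' The paramagnetic attenuation is mapped linearly onto distance from the
#' spin label: PRE = 0 corresponds to 12 angstrom, PRE = 1 to 30 angstrom,
#' `d_calc = 12 + 18 * min(pre, 1)`. Values above 1 are clamped for the
#' distance mapping only. The calibration is semiquantitative: it feeds
#' docking restraints, not r^-6 PRE rates.
#'
#' @param pre normalized PRE value(s), must be non-negative.
#' @return Calibrated distance(s) in angstrom, in `[12, 30]`.
#' @export
pre_to_distance <- function(pre) {
  if (any(!is.finite(pre)) || any(pre < 0))
    stop("normalized PRE must be finite and non-negative")
  12 + 18 * pmin(pre, 1)
}

#' Inverse of the PRE distance calibration
#'
#' @param d distance(s) in angstrom; clamped to the 12-30 calibrated range.
#' @return PRE value(s) in `[0, 1]`.
#' @export
distance_to_pre <- function(d) {
  pmin(pmax((d - 12) / 18, 0), 1)
}

#' Docking distance restraints from normalized PREs
#'
#' Applies the semiquantitative restraint rules: a vanished peak
#' (PRE = 0 or status disappeared) restrains the amide to
#' `[1.8, 12]` angstrom from the spin label; `0 < PRE < 0.8` restrains it
#' to `[12, d_calc + 3]` with `d_calc = 12 + 18 * PRE`; `PRE >= 0.8` gives
#' no restraint (weak attenuation is left unrestrained).
#'
#' @param records normalized records (the `records` element of
#'   [normalize_pre()]; needs `residue`, `pre`, and optionally `status`).
#' @param label_residue,label_atom spin-label attachment site used as the
#'   restraint anchor (default the label-bearing residue's backbone N).
#' @param target_atom restrained atom on each amide (default `"H"`).
#' @param weak_cutoff PRE at and above which no restraint is emitted.
#' @return A `restraint_table` (possibly with zero rows).
#' @export
restraints_from_pre <- function(records, label_residue, label_atom = "N",
                                target_atom = "H", weak_cutoff = 0.8) {
  stopifnot(all(c("residue", "pre") %in% names(records)))
  status <- if (is.null(records$status)) rep("ok", nrow(records))
            else records$status
  pre <- records$pre
  gone <- status == "disappeared" | pre == 0
  mid <- !gone & pre < weak_cutoff
  keep <- gone | mid
  if (!any(keep))
    return(distance_restraints(integer(0), character(0), integer(0),
                               character(0), numeric(0), numeric(0)))
  d_calc <- pre_to_distance(pre)
  lower <- ifelse(gone, 1.8, 12)
  upper <- ifelse(gone, 12, pmin(d_calc + 3, 33))
  distance_restraints(label_residue, label_atom,
                      records$residue[keep], target_atom,
                      lower[keep], upper[keep], source_pre = pre[keep])
}

#' Classify PRE-affected residues with region-specific cutoffs
#'
#' A residue is flagged as affected when its normalized PRE is strictly
#' below the cutoff of the sequence range containing it. Region-specific
#' cutoffs accommodate different baseline dynamics (e.g. flexible arms vs
#' the rigid core of a multidomain protein).
#'
#' @param records normalized records (`residue`, `pre`).
#' @param cutoffs data frame with columns `start`, `end`, `cutoff`; the
#'   ranges must cover every residue in `records`.
#' @return Integer vector of flagged residue numbers.
#' @export
classify_pre_sites <- function(records, cutoffs) {
  stopifnot(all(c("residue", "pre") %in% names(records)),
            all(c("start", "end", "cutoff") %in% names(cutoffs)))
  cut_of <- vapply(records$residue, function(r) {
    hit <- which(cutoffs$start <= r & r <= cutoffs$end)
    if (!length(hit)) NA_real_ else cutoffs$cutoff[hit[1L]]
  }, numeric(1))
  if (any(is.na(cut_of)))
    stop("residue(s) outside every cutoff range: ",
         paste(records$residue[is.na(cut_of)], collapse = ", "))
  sort(records$residue[records$pre < cut_of])
}

#' Default region-specific PRE cutoffs for full-length Sis1
#'
#' PRE below 0.88 flags residues 1-182 (J-domain and flexible linkers);
#' below 0.70 flags residues 183-352 (C-terminal domains and dimerization
#' domain, whose slower tumbling depresses the baseline).
#'
#' @return Data frame with columns `start`, `end`, `cutoff`.
#' @export
sis1_pre_cutoffs <- function() {
  data.frame(start = c(1L, 183L), end = c(182L, 352L),
             cutoff = c(0.88, 0.70))
}
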