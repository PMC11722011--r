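#' Assigned 2D 1H-15N peak list
#'
#' A `peak_list` is the package's in-memory form of one experimental
#' condition: a data frame of backbone amide cross-peaks (one row per peak)
#' plus acquisition metadata. Every downstream stage (CSP mapping, PRE
#' normalization, competition classification) consumes peak lists; nothing
#' else reads raw files.
#'
#' Columns of the peak data frame:
#' \describe{
#'   \item{residue}{integer residue number (1-based, construct numbering),
#'     `NA` for unassigned peaks}
#'   \item{aa}{one-letter amino-acid code, or `"X"` when unknown}
#'   \item{h_ppm, n_ppm}{1H and 15N chemical shifts (ppm)}
#'   \item{intensity}{peak amplitude (arbitrary units); 0 for disappeared
#'     peaks}
#'   \item{status}{one of `"ok"`, `"overlapped"`, `"disappeared"`}
#' }
#'
#' @param peaks data frame with the columns above (missing `aa`/`status`
#'   are filled with `"X"`/`"ok"`).
#' @param label short text label for the condition.
#' @param ligand name of the ligand present (`""` for the free state).
#' @param molar_ratio ligand:protein molar ratio.
#' @param protein_conc,ligand_conc concentrations (molar).
#' @param field_h_mhz 1H spectrometer frequency (MHz).
#' @param temperature_k sample temperature (K).
#' @return An object of class `peak_list`.
#' @examples
#' pl <- peak_list(data.frame(residue = c(32L, 40L), aa = c("K", "G"),
#'                            h_ppm = c(8.21, 8.05), n_ppm = c(121.4, 112.3),
#'                            intensity = c(1e6, 2e6)),
#'                 label = "free")
#' pl
#' @export
peak_list <- function(peaks, label = "", ligand = "", molar_ratio = NA_real_,
                      protein_conc = NA_real_, ligand_conc = NA_real_,
                      field_h_mhz = 900, temperature_k = 298) {
  stopifnot(is.data.frame(peaks))
  need <- c("residue", "h_ppm", "n_ppm", "intensity")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("peak data frame lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(peaks$aa)) peaks$aa <- "X"
  if (is.null(peaks$status)) peaks$status <- "ok"
  peaks$residue <- as.integer(peaks$residue)
  peaks$status <- as.character(peaks$status)
  bad_status <- !peaks$status %in% c("ok", "overlapped", "disappeared")
  if (any(bad_status))
    stop("unknown peak status: ",
         paste(unique(peaks$status[bad_status]), collapse = ", "))
  bad_res <- !is.na(peaks$residue) & peaks$residue < 1L
  if (any(bad_res))
    stop("residue numbers must be >= 1 (offending: ",
         paste(peaks$residue[bad_res], collapse = ", "), ")")
  if (any(!is.finite(peaks$intensity)))
    stop("all intensities must be finite")
  # disappeared peaks carry zero intensity for ratio purposes
  peaks$intensity[peaks$status == "disappeared"] <- 0
  assigned_ok <- peaks$residue[!is.na(peaks$residue) & peaks$status == "ok"]
  dup <- unique(assigned_ok[duplicated(assigned_ok)])
  if (length(dup))
    stop("duplicated assignment for residue(s): ", paste(dup, collapse = ", "))
  structure(
    list(peaks = peaks[, c("residue", "aa", "h_ppm", "n_ppm",
                           "intensity", "status")],
         label = label,
         condition = list(ligand = ligand, molar_ratio = molar_ratio,
                          protein_conc = protein_conc,
                          ligand_conc = ligand_conc),
         field_h_mhz = field_h_mhz,
         temperature_k = temperature_k),
    class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  n <- nrow(x$peaks)
  cat(sprintf("<peak_list '%s'>  %d peaks (%d assigned, %d overlapped, %d disappeared)\n",
              x$label, n,
              sum(!is.na(x$peaks$residue)),
              sum(x$peaks$status == "overlapped"),
              sum(x$peaks$status == "disappeared")))
  if (nzchar(x$condition$ligand))
    cat(sprintf("  ligand: %s (molar ratio %s)\n", x$condition$ligand,
                format(x$condition$molar_ratio)))
  cat(sprintf("  field: %g MHz (1H), T = %g K\n",
              x$field_h_mhz, x$temperature_k))
  invisible(x)
}

#' Read a peak list from disk
#'
#' Two flat-text dialects are supported. `"sparky"` is the whitespace-
#' separated Sparky list export, columns `assignment w1 w2 height` where
#' the assignment looks like `G40N-H` (residue type, number, 15N and 1H atom
#' labels) and w1/w2 are the 15N and 1H shifts. `"csv"` is a headered table
#' with columns `residue, aa, h_ppm, n_ppm, intensity` and optionally
#' `status`.
#'
#' Rows whose assignment cannot be parsed become unassigned peaks and a
#' warning names them; rows are never silently dropped. Duplicate
#' assignments among ok-status peaks are an error.
#'
#' @param path file path.
#' @param dialect `"sparky"` or `"csv"`.
#' @param ... metadata passed to [peak_list()] (label, ligand, ...).
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, dialect = c("csv", "sparky"), ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read peak list: no such file: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("residue", "h_ppm", "n_ppm", "intensity")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("csv peak list lacks column(s): ", paste(miss, collapse = ", "))
    return(peak_list(df, ...))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # drop the Sparky header line if present
  lines <- lines[!grepl("^Assignment", lines, ignore.case = TRUE)]
  if (!length(lines)) stop("empty sparky peak list: ", path)
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < 4)
      stop("malformed sparky row (need 4 columns): '", ln, "'")
    asg <- parse_sparky_assignment(f[1])
    data.frame(residue = asg$residue, aa = asg$aa,
               n_ppm = as.numeric(f[2]), h_ppm = as.numeric(f[3]),
               intensity = as.numeric(f[4]),
               status = "ok", raw = f[1], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  bad <- is.na(df$residue)
  if (any(bad))
    warning("unparseable assignment(s) kept as unassigned peaks: ",
            paste(df$raw[bad], collapse = ", "))
  peak_list(df[, setdiff(names(df), "raw")], ...)
}

# "G40N-H" / "K32HN" style Sparky labels -> residue number + one-letter code
parse_sparky_assignment <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z])([0-9]+)", s))[[1]]
  if (length(m) == 3) {
    aa <- toupper(m[2])
    if (!aa %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")) aa <- "X"
    list(residue = as.integer(m[3]), aa = aa)
  } else {
    list(residue = NA_integer_, aa = "X")
  }
}

#' Write a peak list as headered CSV
#'
#' The inverse of `read_peaklist(dialect = "csv")`: ppm values are printed
#' to 3 decimals and intensities to 6 significant digits, and a write/read
#' round trip reproduces all peak fields.
#'
#' @param x a [peak_list()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  stopifnot(inherits(x, "peak_list"))
  df <- x$peaks
  df$h_ppm <- sprintf("%.3f", df$h_ppm)
  df$n_ppm <- sprintf("%.3f", df$n_ppm)
  df$intensity <- signif(df$intensity, 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
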