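#' Read structure models from a PDB file
#'
#' Parses ATOM records (HETATM is ignored) into one `structure_model` per
#' MODEL block, in file order; a file without MODEL records yields a single
#' implicit model. Multi-chain files are restricted to one chain.
#'
#' Parsing is delegated to \pkg{bio3d}; this function only reshapes its
#' output into the package's model container.
#'
#' @param path PDB file.
#' @param chain chain identifier to keep; default the first chain present.
#' @return A list of `structure_model` objects, each a data frame with
#'   columns `residue`, `aa`, `atom`, `x`, `y`, `z` and attributes
#'   `model_index`.
#' @export
read_pdb_models <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read PDB: no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  sel <- pdb$atom$type == "ATOM"
  if (!any(sel)) stop("no ATOM records in ", path, " (empty structure)")
  atom <- pdb$atom[sel, , drop = FALSE]
  if (is.null(chain)) chain <- atom$chain[1L]
  keep <- which(sel)[atom$chain == chain]
  atom <- pdb$atom[keep, , drop = FALSE]
  if (!nrow(atom)) stop("no ATOM records for chain '", chain, "' in ", path)
  aa1 <- tryCatch(bio3d::aa321(atom$resid), warning = function(w) {
    suppressWarnings(bio3d::aa321(atom$resid))
  })
  aa1[is.na(aa1)] <- "X"
  nmod <- nrow(pdb$xyz)
  xyz_idx <- bio3d::atom2xyz(keep)
  lapply(seq_len(nmod), function(m) {
    co <- matrix(pdb$xyz[m, xyz_idx], ncol = 3L, byrow = TRUE)
    structure(
      data.frame(residue = as.integer(atom$resno), aa = aa1,
                 atom = atom$elety, chain = atom$chain,
                 x = co[, 1], y = co[, 2], z = co[, 3],
                 stringsAsFactors = FALSE),
      model_index = m, class = c("structure_model", "data.frame"))
  })
}

#' Distance restraints for docking
#'
#' Builds the restraint table consumed by [write_restraint_table()]:
#' each row is a lower/upper distance interval (in angstroms) between a
#' spin-label attachment site and a backbone amide.
#'
#' @param site_residue,site_atom spin-label attachment residue/atom.
#' @param target_residue,target_atom restrained amide residue/atom.
#' @param lower,upper interval bounds in angstroms; must satisfy
#'   `1.8 <= lower <= upper <= 33`.
#' @param source_pre the normalized PRE value that produced each row
#'   (`NA` when not PRE-derived).
#' @return Data frame of class `restraint_table`.
#' @export
distance_restraints <- function(site_residue, site_atom,
                                target_residue, target_atom,
                                lower, upper, source_pre = NA_real_) {
  source_pre <- rep_len(as.numeric(source_pre),
                        length(as.integer(target_residue)))
  df <- data.frame(site_residue = as.integer(site_residue),
                   site_atom = as.character(site_atom),
                   target_residue = as.integer(target_residue),
                   target_atom = as.character(target_atom),
                   lower = as.numeric(lower), upper = as.numeric(upper),
                   source_pre = as.numeric(source_pre),
                   stringsAsFactors = FALSE)
  bad <- df$lower > df$upper
  if (any(bad))
    stop("restraint lower bound exceeds upper bound for target residue(s): ",
         paste(df$target_residue[bad], collapse = ", "))
  if (any(df$lower < 1.8 - 1e-9) || any(df$upper > 33 + 1e-9))
    stop("restraint bounds must lie within [1.8, 33] angstrom")
  structure(df, class = c("restraint_table", "data.frame"))
}

#' Write distance restraints to disk
#'
#' `"cns_tbl"` emits one CNS/HADDOCK-style line per restraint,
#' `assign (resid i and name X) (resid j and name Y) d dminus dplus`,
#' with `d = lower`, `dminus = 0`, `dplus = upper - lower`, so that
#' `d - dminus` and `d + dplus` recover the interval. `"csv"` writes the
#' table with explicit `lower`/`upper` columns; a csv round trip through
#' [read_restraint_table()] reproduces the input.
#'
#' @param restraints a `restraint_table` (see [distance_restraints()]).
#' @param path output file.
#' @param dialect `"cns_tbl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_restraint_table <- function(restraints, path,
                                  dialect = c("cns_tbl", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(restraints, "restraint_table"))
  if (!nrow(restraints)) stop("restraint table is empty; nothing to write")
  if (any(restraints$lower > restraints$upper))
    stop("restraint lower bound exceeds upper bound")
  if (dialect == "csv") {
    df <- restraints
    df$lower <- sprintf("%.3f", df$lower)
    df$upper <- sprintf("%.3f", df$upper)
    df$source_pre <- ifelse(is.na(df$source_pre), "",
                            sprintf("%.6f", df$source_pre))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- sprintf(
      "assign (resid %d and name %s) (resid %d and name %s) %.1f %.1f %.1f",
      restraints$site_residue, restraints$site_atom,
      restraints$target_residue, restraints$target_atom,
      restraints$lower, 0, restraints$upper - restraints$lower)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a restraint table written by [write_restraint_table()]
#'
#' @param path file path.
#' @param dialect `"cns_tbl"` or `"csv"`.
#' @return A `restraint_table`.
#' @export
read_restraint_table <- function(path, dialect = c("cns_tbl", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(distance_restraints(df$site_residue, df$site_atom,
                               df$target_residue, df$target_atom,
                               df$lower, df$upper,
                               ifelse(is.na(df$source_pre) |
                                        df$source_pre == "", NA_real_,
                                      as.numeric(df$source_pre))))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^assign", lines)]
  if (!length(lines)) stop("no assign statements in ", path)
  pat <- paste0("^assign \\(resid ([0-9]+) and name ([^)]+)\\) ",
                "\\(resid ([0-9]+) and name ([^)]+)\\) ",
                "([0-9.]+) ([0-9.]+) ([0-9.]+)")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- vapply(m, length, integer(1)) != 8L
  if (any(bad)) stop("malformed assign line: ", lines[which(bad)[1L]])
  g <- function(i) vapply(m, `[[`, character(1), i)
  d <- as.numeric(g(6)); dminus <- as.numeric(g(7)); dplus <- as.numeric(g(8))
  distance_restraints(as.integer(g(2)), trimws(g(3)),
                      as.integer(g(4)), trimws(g(5)),
                      lower = d - dminus, upper = d + dplus)
}
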