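#' Pipeline configuration
#'
#' Collects and validates the inputs of a full interaction-mapping run.
#' A configuration can also be loaded from a YAML document with the same
#' keys via [read_pipeline_config()].
#'
#' @param out_dir output directory (created if absent).
#' @param domains a [domain_map()], or path to a YAML file with keys
#'   `name`, `start`, `end`.
#' @param free,bound paths to free/bound peak lists (CSV dialect) for CSP
#'   mapping; optional.
#' @param para,dia paths to paramagnetic/diamagnetic lists for PRE
#'   analysis; optional.
#' @param r1,r2 paths to relaxation series CSVs (columns `residue`,
#'   `delay_s`, `intensity`, optional `noise_sigma`); optional.
#' @param client,both paths to the plus-client and plus-client-plus-
#'   competitor lists for competition analysis (requires `free`).
#' @param field_h_mhz 1H spectrometer frequency (MHz).
#' @param csp_k CSP significance multiplier.
#' @param pre_cutoffs data frame of region cutoffs (`start`, `end`,
#'   `cutoff`); default [sis1_pre_cutoffs()].
#' @param label_residue spin-label attachment residue for restraints.
#' @param seed integer seed for stochastic steps (Monte-Carlo errors).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, domains,
                            free = NULL, bound = NULL,
                            para = NULL, dia = NULL,
                            r1 = NULL, r2 = NULL,
                            client = NULL, both = NULL,
                            field_h_mhz = 900, csp_k = 1,
                            pre_cutoffs = sis1_pre_cutoffs(),
                            label_residue = 1L, seed = 1L) {
  if (is.character(domains)) domains <- read_domain_map(domains)
  stopifnot(inherits(domains, "domain_map"))
  paths <- list(free = free, bound = bound, para = para, dia = dia,
                r1 = r1, r2 = r2, client = client, both = both)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop("configured input '", nm, "' does not exist: ", p)
  }
  if (!is.null(bound) && is.null(free))
    stop("CSP mapping needs both 'free' and 'bound'")
  if (xor(is.null(para), is.null(dia)))
    stop("PRE analysis needs both 'para' and 'dia'")
  if (xor(is.null(r1), is.null(r2)))
    stop("relaxation analysis needs both 'r1' and 'r2'")
  if ((!is.null(client) || !is.null(both)) &&
      (is.null(client) || is.null(both) || is.null(free)))
    stop("competition analysis needs 'free', 'client' and 'both'")
  stopifnot(csp_k > 0, field_h_mhz > 0,
            all(pre_cutoffs$cutoff > 0))
  structure(c(list(out_dir = out_dir, domains = domains,
                   field_h_mhz = field_h_mhz, csp_k = csp_k,
                   pre_cutoffs = pre_cutoffs,
                   label_residue = as.integer(label_residue),
                   seed = as.integer(seed)),
              paths),
            class = "pipeline_config")
}

#' Read a domain map from YAML
#'
#' @param path YAML file with parallel lists `name`, `start`, `end`.
#' @return A [domain_map()].
#' @export
read_domain_map <- function(path) {
  if (!file.exists(path)) stop("no such domain map: ", path)
  y <- yaml::read_yaml(path)
  domain_map(unlist(y$name), unlist(y$start), unlist(y$end))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; relative input paths are resolved against the
#'   file's directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  do.call(pipeline_config, c(
    list(out_dir = y$out_dir %||% file.path(base, "out"),
         domains = resolve(y$domains)),
    lapply(y[intersect(names(y), c("free", "bound", "para", "dia", "r1",
                                   "r2", "client", "both"))], resolve),
    y[intersect(names(y), c("field_h_mhz", "csp_k", "label_residue",
                            "seed"))]))
}

#' Run the full interaction-mapping pipeline
#'
#' Executes every stage for which the configuration provides inputs —
#' CSP mapping, PRE normalization + restraint generation + site
#' classification, R1/R2 fitting + per-domain dynamics + exchange
#' flagging, and competition classification — writing per-residue CSVs,
#' a CNS-style restraint table and a run log into the output directory.
#' The run is deterministic given the configuration and its seed; the log
#' records every threshold, the PRE normalization factor, trimmed counts
#' and excluded residues so that each flag decision can be re-derived.
#'
#' @param config a [pipeline_config()].
#' @return List of stage results (`csp`, `pre`, `relaxation`,
#'   `competition`, whichever ran) plus `log_path`; invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  say <- function(...) writeLines(sprintf(...), con)
  say("nmrmap pipeline | seed %d | field %g MHz", config$seed,
      config$field_h_mhz)
  out <- list(log_path = log_path)

  if (!is.null(config$free) && !is.null(config$bound)) {
    free <- read_peaklist(config$free, "csv", label = "free")
    bound <- read_peaklist(config$bound, "csv", label = "bound")
    prof <- csp_profile(free, bound, config$domains, k = config$csp_k)
    say("[csp] threshold %.5f ppm (mean + %g SD over %d residues)",
        attr(prof, "threshold"), config$csp_k, nrow(prof))
    say("[csp] excluded overlapped: %s",
        paste(attr(prof, "overlapped"), collapse = " "))
    say("[csp] significant: %s",
        paste(prof$residue[prof$significant], collapse = " "))
    utils::write.csv(as.data.frame(prof),
                     file.path(config$out_dir, "csp.csv"),
                     row.names = FALSE)
    out$csp <- prof
  }

  if (!is.null(config$para)) {
    para <- read_peaklist(config$para, "csv", label = "para")
    dia <- read_peaklist(config$dia, "csv", label = "dia")
    norm <- normalize_pre(pre_ratios(para, dia))
    say("[pre] alpha = %.6f (reference n = %d)", norm$alpha,
        sum(norm$records$in_reference))
    flagged <- classify_pre_sites(norm$records, config$pre_cutoffs)
    say("[pre] flagged below regional cutoff: %s",
        paste(flagged, collapse = " "))
    restr <- restraints_from_pre(norm$records, config$label_residue)
    say("[pre] %d restraints emitted", nrow(restr))
    utils::write.csv(norm$records,
                     file.path(config$out_dir, "pre.csv"),
                     row.names = FALSE)
    if (nrow(restr)) {
      write_restraint_table(restr,
                            file.path(config$out_dir, "restraints.tbl"),
                            "cns_tbl")
      write_restraint_table(restr,
                            file.path(config$out_dir, "restraints.csv"),
                            "csv")
    }
    out$pre <- list(alpha = norm$alpha, records = norm$records,
                    flagged = flagged, restraints = restr)
  }

  if (!is.null(config$r1)) {
    r1_set <- read_decay_csv(config$r1, "R1")
    r2_set <- read_decay_csv(config$r2, "R2")
    rates <- fit_rates(r1_set, r2_set, seed = config$seed)
    rates <- flag_exchange(rates, config$domains)
    dyn <- domain_dynamics(rates, config$domains, config$field_h_mhz)
    for (i in seq_len(nrow(dyn)))
      say("[relax] %s: R2/R1 %.2f +- %.2f (n %d/%d), tauc %.2f +- %.2f ns",
          dyn$domain[i], dyn$mean_ratio[i], dyn$sd_ratio[i], dyn$n_used[i],
          dyn$n_available[i], dyn$tauc_ns[i], dyn$tauc_sigma_ns[i])
    say("[relax] exchange-flagged: %s",
        paste(rates$residue[rates$exchange_flag], collapse = " "))
    utils::write.csv(rates, file.path(config$out_dir, "rates.csv"),
                     row.names = FALSE)
    utils::write.csv(dyn, file.path(config$out_dir, "domain_dynamics.csv"),
                     row.names = FALSE)
    out$relaxation <- list(rates = rates, domains = dyn)
  }

  if (!is.null(config$client)) {
    free <- read_peaklist(config$free, "csv", label = "free")
    client <- read_peaklist(config$client, "csv", label = "client")
    both <- read_peaklist(config$both, "csv", label = "both")
    comp <- competition_profile(free, client, both, config$domains,
                                k = config$csp_k)
    say("[compete] threshold %.5f ppm; competitive: %s",
        attr(comp, "threshold"),
        paste(comp$residue[comp$class == "competitive"], collapse = " "))
    utils::write.csv(as.data.frame(comp),
                     file.path(config$out_dir, "competition.csv"),
                     row.names = FALSE)
    out$competition <- comp
  }
  invisible(out)
}

#' Read a relaxation series CSV into a [decay_set()]
#'
#' Long format: columns `residue`, `delay_s`, `intensity`, optional
#' `noise_sigma` (constant per residue).
#'
#' @param path CSV file.
#' @param experiment `"R1"` or `"R2"`.
#' @return A [decay_set()].
#' @export
read_decay_csv <- function(path, experiment = c("R1", "R2")) {
  experiment <- match.arg(experiment)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "delay_s", "intensity")
  if (!all(need %in% names(df)))
    stop("decay csv needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$noise_sigma)) df$noise_sigma <- 0
  sp <- split(df, df$residue)
  sp <- sp[order(as.integer(names(sp)))]
  decay_set(residue = as.integer(names(sp)),
            delays = lapply(sp, function(d) d$delay_s[order(d$delay_s)]),
            intensities = lapply(sp, function(d)
              d$intensity[order(d$delay_s)]),
            noise_sigma = vapply(sp, function(d) d$noise_sigma[1],
                                 numeric(1)),
            experiment = experiment)
}

#' Write a [decay_set()] as a long-format CSV
#'
#' @param x a [decay_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(x, path) {
  stopifnot(inherits(x, "decay_set"))
  rows <- do.call(rbind, lapply(seq_along(x$residue), function(i)
    data.frame(residue = x$residue[i], delay_s = x$delays[[i]],
               intensity = x$intensities[[i]],
               noise_sigma = x$noise_sigma[i])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
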