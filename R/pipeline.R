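# Reproducible pipeline runs: a small argument parser, subcommand
# dispatch, and a run manifest. The same entry point backs the thin
# command-line wrapper shipped under inst/cli/.

parse_pipeline_args <- function(args) {
  if (length(args) == 0L) stop_ihc(pipeline_usage())
  sub <- args[1]
  args <- args[-1]
  opt <- list(subcommand = sub, config = NULL, seed = NULL, out = ".",
              verbose = FALSE)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() {
      if (i + 1L > length(args)) stop_ihc(sprintf("flag %s needs a value", a))
      args[i + 1L]
    }
    if (a == "--config") { opt$config <- take(); i <- i + 2L }
    else if (a == "--seed") {
      s <- suppressWarnings(as.integer(take()))
      if (is.na(s)) stop_ihc("--seed must be an integer")
      opt$seed <- s; i <- i + 2L
    }
    else if (a == "--out") { opt$out <- take(); i <- i + 2L }
    else if (a == "--verbose") { opt$verbose <- TRUE; i <- i + 1L }
    else stop_ihc(sprintf("unknown flag '%s'\n%s", a, pipeline_usage()))
  }
  opt
}

pipeline_usage <- function() {
  paste0("usage: ihcpanel <subcommand> [--config FILE] [--seed INT] ",
         "[--out DIR] [--verbose]\n",
         "subcommands: simulate-cohort, simulate-expression, score-ihc, ",
         "panel, survival, assoc, meta")
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

read_run_config <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stop_ihc(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) list() else cfg
}

cfg_input <- function(cfg, key, required = TRUE) {
  p <- cfg$inputs[[key]]
  if (is.null(p)) {
    if (required) stop_ihc(sprintf("config is missing inputs: %s", key))
    return(NULL)
  }
  if (!file.exists(p)) stop_ihc(sprintf("input path does not exist: %s", p))
  p
}

write_manifest <- function(out_dir, subcommand, cfg, seed, files, counts) {
  manifest <- list(subcommand = subcommand,
                   package = "ihcpanel",
                   version = as.character(utils::packageVersion("ihcpanel")),
                   r_version = as.character(getRversion()),
                   seed = seed,
                   config = cfg,
                   files = files,
                   row_counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

cox_terms_list <- function(cox) {
  lapply(seq_len(nrow(cox$terms)), function(i) as.list(cox$terms[i, ]))
}

#' Run a pipeline subcommand
#'
#' Binds the pipeline stages into reproducible command-style runs. Each
#' run writes its outputs plus a \code{manifest.json} (config echo,
#' seed, package version, row counts) into the output directory; the
#' seed is recorded so a run is reproducible from its manifest alone.
#' Input files are never mutated.
#'
#' Subcommands and their config keys (YAML, under \code{inputs:}):
#' \describe{
#'   \item{simulate-cohort}{no inputs; optional top-level
#'     \code{simulate:} overrides for \code{\link{cohort_sim_config}};
#'     writes cores.tsv, covariates.tsv, survival.tsv, truth_states.tsv,
#'     truth.yaml.}
#'   \item{simulate-expression}{no inputs; optional \code{simulate:}
#'     overrides for \code{\link{expr_sim_config}}; writes per-dataset
#'     matrix/probe-map/follow-up/covariate files plus
#'     expression_manifest.tsv.}
#'   \item{score-ihc}{\code{cores}; optional top-level \code{scoring:}
#'     thresholds; writes marker_calls.tsv.}
#'   \item{panel}{\code{marker_calls}; writes panel.tsv and, with
#'     \code{covariates}, crosstab_<variable>.tsv tables.}
#'   \item{survival}{\code{panel}, \code{survival}; writes km_<endpoint>.tsv
#'     and survival_results.json (log-rank and univariate Cox by
#'     signature for RFS and BCSS).}
#'   \item{assoc}{\code{marker_calls} or \code{panel}, \code{covariates};
#'     writes assoc_results.json (chi-square/Fisher per covariate).}
#'   \item{meta}{\code{expression_manifest}; analysis options
#'     \code{analysis: group_mode (strict|score), adjust (true|false)};
#'     writes pooled_groups.tsv and meta_results.json.}
#' }
#'
#' @param args character vector of command-line style arguments:
#'   subcommand followed by \code{--config}, \code{--seed}, \code{--out},
#'   \code{--verbose}.
#' @return 0 invisibly on success; errors otherwise.
#' @export
run_pipeline <- function(args) {
  opt <- parse_pipeline_args(args)
  sub <- opt$subcommand
  known <- c("simulate-cohort", "simulate-expression", "score-ihc",
             "panel", "survival", "assoc", "meta")
  if (!sub %in% known) {
    stop_ihc(sprintf("unknown subcommand '%s'\n%s", sub, pipeline_usage()))
  }
  cfg <- read_run_config(opt$config)
  seed <- if (!is.null(opt$seed)) opt$seed else
    if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  out_dir <- opt$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  counts <- list()

  if (sub == "simulate-cohort") {
    sim_args <- cfg$simulate
    sim_args$seed <- seed
    config <- do.call(cohort_sim_config, as.list(sim_args))
    sim <- simulate_tma_cohort(config)
    files <- c(cores = write_tsv(sim$cores, file.path(out_dir, "cores.tsv")),
               covariates = write_tsv(sim$covariates,
                                      file.path(out_dir, "covariates.tsv")),
               survival = write_tsv(sim$survival,
                                    file.path(out_dir, "survival.tsv")))
    truth_states <- data.frame(patient_id = sim$covariates$patient_id,
                               anln_high = sim$truth$marker_high[, "ANLN"],
                               pbk_high = sim$truth$marker_high[, "PBK"],
                               pdzk1_high = sim$truth$marker_high[, "PDZK1"],
                               score_true = sim$truth$score_true,
                               signature_true = sim$truth$signature_true)
    files <- c(files, truth_states = write_tsv(
      truth_states, file.path(out_dir, "truth_states.tsv")))
    truth_params <- config[!vapply(config, is.list, logical(1))]
    truth_params <- lapply(truth_params, function(x) {
      if (is.null(names(x))) unname(x) else as.list(x)
    })
    yaml::write_yaml(truth_params, file.path(out_dir, "truth.yaml"))
    files <- c(files, truth = file.path(out_dir, "truth.yaml"))
    counts <- list(cores = nrow(sim$cores), patients = nrow(sim$covariates))
    pipeline_log(opt$verbose, "simulated %d patients (%d core rows)",
                 nrow(sim$covariates), nrow(sim$cores))
  }

  if (sub == "simulate-expression") {
    sim_args <- cfg$simulate
    sim_args$seed <- seed
    config <- do.call(expr_sim_config, as.list(sim_args))
    sim <- simulate_expression_datasets(config)
    rows <- lapply(sim$datasets, function(ds) {
      stem <- file.path(out_dir, ds$dataset_id)
      mat <- data.frame(probe = rownames(ds$exprs), ds$exprs,
                        check.names = FALSE)
      write_tsv(mat, paste0(stem, "_matrix.tsv"))
      write_tsv(ds$probe_map, paste0(stem, "_probe_map.tsv"))
      write_tsv(ds$followup, paste0(stem, "_followup.tsv"))
      write_tsv(ds$covariates, paste0(stem, "_covariates.tsv"))
      data.frame(dataset_id = ds$dataset_id,
                 matrix = paste0(ds$dataset_id, "_matrix.tsv"),
                 probe_map = paste0(ds$dataset_id, "_probe_map.tsv"),
                 followup = paste0(ds$dataset_id, "_followup.tsv"),
                 covariates = paste0(ds$dataset_id, "_covariates.tsv"),
                 stringsAsFactors = FALSE)
    })
    manifest_tab <- do.call(rbind, rows)
    files <- c(expression_manifest = write_tsv(
      manifest_tab, file.path(out_dir, "expression_manifest.tsv")))
    files <- c(files, truth_groups = write_tsv(
      sim$truth$groups, file.path(out_dir, "truth_groups.tsv")))
    counts <- list(datasets = length(sim$datasets),
                   samples = sum(config$n_samples))
    pipeline_log(opt$verbose, "simulated %d datasets (%d samples)",
                 length(sim$datasets), sum(config$n_samples))
  }

  if (sub == "score-ihc") {
    scoring <- if (!is.null(cfg$scoring)) {
      do.call(scoring_config, as.list(cfg$scoring))
    } else scoring_config()
    tabs <- read_cohort_tables(cfg_input(cfg, "cores"),
                               verbose = opt$verbose)
    calls <- score_ihc_cohort(tabs$cores, scoring)
    files <- c(marker_calls = write_marker_calls(
      calls, file.path(out_dir, "marker_calls.tsv")))
    counts <- list(cores = nrow(tabs$cores), calls = nrow(calls))
    pipeline_log(opt$verbose, "scored %d patient-marker calls", nrow(calls))
  }

  if (sub == "panel") {
    calls <- read_marker_calls(cfg_input(cfg, "marker_calls"))
    pan <- build_panel(calls)
    out_pan <- pan
    out_pan$signature[is.na(out_pan$signature)] <- "missing"
    files <- c(panel = write_tsv(out_pan, file.path(out_dir, "panel.tsv")))
    counts <- list(patients = nrow(pan),
                   complete = sum(!is.na(pan$panel_score)))
    cov_path <- cfg_input(cfg, "covariates", required = FALSE)
    if (!is.null(cov_path)) {
      covs <- read_delim_auto(cov_path)
      check_columns(covs, "patient_id", cov_path)
      for (nm in setdiff(names(covs), c("patient_id", "age"))) {
        covs[[nm]] <- normalize_category_tokens(covs[[nm]])
      }
      covs <- covs[match(pan$patient_id, covs$patient_id), , drop = FALSE]
      for (nm in setdiff(names(covs), c("patient_id", "age"))) {
        ct <- crosstab_percent(pan$panel_score, covs[[nm]])
        tab <- data.frame(category = rownames(ct$counts),
                          ct$counts, check.names = FALSE)
        f <- write_tsv(tab, file.path(out_dir,
                                      sprintf("crosstab_%s.tsv", nm)))
        files <- c(files, stats::setNames(f, paste0("crosstab_", nm)))
      }
    }
    pipeline_log(opt$verbose, "panel built for %d patients (%d complete)",
                 counts$patients, counts$complete)
  }

  if (sub == "survival") {
    pan <- read_delim_auto(cfg_input(cfg, "panel"))
    check_columns(pan, c("patient_id", "signature"), "panel table")
    surv <- read_delim_auto(cfg_input(cfg, "survival"))
    check_columns(surv, c("patient_id", "rfs_time", "rfs_event",
                          "bcss_time", "bcss_event"), "survival table")
    d <- merge(pan, surv, by = "patient_id")
    d <- d[d$signature %in% c("A", "B"), , drop = FALSE]
    results <- list(n = nrow(d))
    for (ep in c("rfs", "bcss")) {
      tm <- d[[paste0(ep, "_time")]]
      ev <- d[[paste0(ep, "_event")]]
      km <- km_estimate(tm, ev, d$signature)
      files <- c(files, stats::setNames(
        write_tsv(km, file.path(out_dir, sprintf("km_%s.tsv", ep))),
        paste0("km_", ep)))
      lr <- logrank_test(tm, ev, d$signature)
      cox <- cox_fit(tm, ev,
                     data.frame(signature = factor(d$signature,
                                                   levels = c("A", "B"))))
      results[[ep]] <- list(logrank = list(statistic = lr$statistic,
                                           df = lr$df, p_value = lr$p_value),
                            cox = cox_terms_list(cox),
                            n_events = sum(ev))
    }
    jsonlite::write_json(results,
                         file.path(out_dir, "survival_results.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, results = file.path(out_dir, "survival_results.json"))
    counts <- list(patients = nrow(d))
    pipeline_log(opt$verbose, "survival analysis on %d patients", nrow(d))
  }

  if (sub == "assoc") {
    pan <- read_delim_auto(cfg_input(cfg, "panel"))
    check_columns(pan, c("patient_id", "panel_score"), "panel table")
    covs <- read_delim_auto(cfg_input(cfg, "covariates"))
    check_columns(covs, "patient_id", "covariate table")
    for (nm in setdiff(names(covs), c("patient_id", "age"))) {
      covs[[nm]] <- normalize_category_tokens(covs[[nm]])
    }
    covs <- covs[match(pan$patient_id, covs$patient_id), , drop = FALSE]
    score <- suppressWarnings(as.integer(pan$panel_score))
    results <- list()
    for (nm in setdiff(names(covs), c("patient_id", "age"))) {
      ct <- crosstab_percent(score, covs[[nm]])
      known <- rownames(ct$counts) %in% rownames(ct$pct)
      counts_known <- ct$counts[known, , drop = FALSE]
      res <- list(counts = unclass(counts_known))
      if (nrow(counts_known) >= 2L) {
        chi <- tryCatch(chi_square_test(counts_known),
                        error = function(e) NULL)
        fis <- tryCatch(fisher_exact(counts_known), error = function(e) NULL)
        if (!is.null(chi)) res$chi_square <- list(
          statistic = chi$statistic, df = chi$df, p_value = chi$p_value)
        if (!is.null(fis)) res$fisher <- list(p_value = fis$p_value)
      }
      results[[nm]] <- res
    }
    jsonlite::write_json(results, file.path(out_dir, "assoc_results.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(results = file.path(out_dir, "assoc_results.json"))
    counts <- list(patients = sum(!is.na(score)))
    pipeline_log(opt$verbose, "associations for %d scored patients",
                 counts$patients)
  }

  if (sub == "meta") {
    datasets <- read_expression_inputs(cfg_input(cfg, "expression_manifest"),
                                       verbose = opt$verbose)
    mode <- if (!is.null(cfg$analysis$group_mode)) {
      cfg$analysis$group_mode
    } else "strict"
    adjust <- isTRUE(cfg$analysis$adjust)
    grouped <- lapply(datasets, assign_groups, mode = mode)
    pooled <- pool_datasets(grouped)
    files <- c(pooled = write_tsv(as.data.frame(pooled),
                                  file.path(out_dir, "pooled_groups.tsv")))
    res <- pooled_survival_analysis(pooled, adjust = adjust)
    out <- list(group_mode = mode, n_pooled = res$n_pooled,
                n_events = res$n_events,
                n_poor = sum(pooled$group == "poor"))
    if (!is.null(res$logrank)) {
      out$logrank <- list(statistic = res$logrank$statistic,
                          df = res$logrank$df,
                          p_value = res$logrank$p_value)
    }
    if (adjust) {
      out$cox <- cox_terms_list(res$cox)
      out$n_complete <- res$n_complete
    }
    jsonlite::write_json(out, file.path(out_dir, "meta_results.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, results = file.path(out_dir, "meta_results.json"))
    km <- res$km
    files <- c(files, km = write_tsv(km, file.path(out_dir, "km_pooled.tsv")))
    counts <- list(datasets = length(datasets), pooled = res$n_pooled)
    pipeline_log(opt$verbose, "pooled %d samples from %d datasets",
                 res$n_pooled, length(datasets))
  }

  write_manifest(out_dir, sub, cfg, seed, as.list(files), counts)
  invisible(0L)
}
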