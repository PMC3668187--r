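# Delimited-text readers and writers for the pipeline's interchange
# tables. All tables are UTF-8 comma- or tab-separated text with a
# header row; the delimiter is auto-detected from the header line.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop_ihc(sprintf("empty file: %s", path))
  if (grepl("\t", header)) "\t" else ","
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop_ihc(sprintf("input file not found: %s", path))
  utils::read.table(path, header = TRUE, sep = detect_delim(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "", na.strings = "NA")
}

check_columns <- function(df, needed, path) {
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop_ihc(sprintf("%s is missing required column(s): %s",
                     path, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

coerce_numeric_col <- function(df, cols, path) {
  for (nm in cols) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- is.na(v) & !is.na(df[[nm]]) & df[[nm]] != ""
    if (any(bad)) {
      stop_ihc(sprintf("%s: unparseable numeric in column '%s' at row %d (%s)",
                       path, nm, which(bad)[1L], df[[nm]][which(bad)[1L]]))
    }
    df[[nm]] <- v
  }
  df
}

# Category-token dictionary: maps spelling variants of the
# clinicopathological labels onto the canonical tokens used internally.
.token_map <- c("N1 +" = "N1+", "n0" = "N0", "n1+" = "N1+",
                "0 - 2 +" = "0-2+", "0-2 +" = "0-2+", "3 +" = "3+",
                "0 - 10%" = "0-10%", "11 - 100%" = "11-100%",
                "ER Negative" = "neg", "ER Positive" = "pos",
                "PR Negative" = "neg", "PR Positive" = "pos",
                "Negative" = "neg", "Positive" = "pos",
                "negative" = "neg", "positive" = "pos",
                "<= 2cm" = "<=2cm", "> 2cm" = ">2cm",
                "≤2cm" = "<=2cm")
.unknown_tokens <- c("", "na", "n/a", "unknown", "missing", "?", ".")

normalize_category_tokens <- function(x) {
  x <- as.character(x)
  mapped <- .token_map[x]
  x[!is.na(mapped)] <- mapped[!is.na(mapped)]
  x[is.na(x) | tolower(trimws(x)) %in% .unknown_tokens] <- "unknown"
  x
}

#' Read the cohort input tables
#'
#' Reads and validates the per-core IHC observation table and,
#' optionally, the clinicopathological covariate table and the survival
#' follow-up table. The delimiter (comma or tab) is auto-detected,
#' numeric columns are type-checked with row-numbered errors, and
#' covariate category tokens are normalised (spelling variants of the
#' published labels, e.g. \code{"N1 +"}, map onto canonical tokens;
#' empty or NA-like values become \code{"unknown"}).
#'
#' @param core_path path to the per-core observation table (columns
#'   patient_id, core_index, marker, tissue_percent, cell_count,
#'   intensity, percent_stained).
#' @param covariate_path optional path to the covariate table (columns
#'   patient_id, age, size, histological_type, grade, nodal, ER, PR,
#'   Her2, Ki67).
#' @param survival_path optional path to the survival table (columns
#'   patient_id, rfs_time, rfs_event, bcss_time, bcss_event).
#' @param verbose log row counts via \code{message}.
#' @return list with elements \code{cores}, \code{covariates},
#'   \code{survival} (NULL where not supplied).
#' @export
read_cohort_tables <- function(core_path, covariate_path = NULL,
                               survival_path = NULL, verbose = FALSE) {
  cores <- read_delim_auto(core_path)
  check_columns(cores, c("patient_id", "core_index", "marker",
                         "tissue_percent", "cell_count", "intensity",
                         "percent_stained"), core_path)
  cores <- coerce_numeric_col(cores, c("core_index", "tissue_percent",
                                       "cell_count", "intensity",
                                       "percent_stained"), core_path)
  cores$patient_id <- as.character(cores$patient_id)
  assert_marker(unique(cores$marker))
  if (verbose) message(sprintf("read %d core rows from %s",
                               nrow(cores), core_path))

  covariates <- NULL
  if (!is.null(covariate_path)) {
    covariates <- read_delim_auto(covariate_path)
    check_columns(covariates, "patient_id", covariate_path)
    covariates$patient_id <- as.character(covariates$patient_id)
    if ("age" %in% names(covariates)) {
      covariates <- coerce_numeric_col(covariates, "age", covariate_path)
    }
    for (nm in setdiff(names(covariates), c("patient_id", "age"))) {
      covariates[[nm]] <- normalize_category_tokens(covariates[[nm]])
    }
    if (verbose) message(sprintf("read %d covariate rows from %s",
                                 nrow(covariates), covariate_path))
  }

  survival <- NULL
  if (!is.null(survival_path)) {
    survival <- read_delim_auto(survival_path)
    check_columns(survival, c("patient_id", "rfs_time", "rfs_event",
                              "bcss_time", "bcss_event"), survival_path)
    survival <- coerce_numeric_col(survival, c("rfs_time", "rfs_event",
                                               "bcss_time", "bcss_event"),
                                   survival_path)
    survival$patient_id <- as.character(survival$patient_id)
    if (verbose) message(sprintf("read %d survival rows from %s",
                                 nrow(survival), survival_path))
  }
  list(cores = cores, covariates = covariates, survival = survival)
}

#' Read expression meta-analysis inputs
#'
#' Reads one or more expression datasets, each given by a probe-by-sample
#' matrix file (first column = probe ID, header = sample IDs), a
#' two-column probe map (probe, gene), a follow-up table (sample_id,
#' time, event) and an optional covariate table (sample_id, node, grade,
#' er). Identifiers are cross-validated by
#' \code{\link{expression_dataset}}: duplicated probes or sample columns
#' and samples missing from the follow-up are rejected.
#'
#' @param manifest data frame (or path to a delimited file) with columns
#'   \code{dataset_id}, \code{matrix}, \code{probe_map}, \code{followup}
#'   and optionally \code{covariates}; paths are interpreted relative to
#'   the manifest's directory when a path is given.
#' @param verbose log per-dataset dimensions via \code{message}.
#' @return list of \code{\link{expression_dataset}} objects.
#' @export
read_expression_inputs <- function(manifest, verbose = FALSE) {
  base <- "."
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- read_delim_auto(manifest)
  }
  check_columns(manifest, c("dataset_id", "matrix", "probe_map", "followup"),
                "expression manifest")
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  lapply(seq_len(nrow(manifest)), function(i) {
    mat_path <- resolve(manifest$matrix[i])
    raw <- read_delim_auto(mat_path)
    probes <- as.character(raw[[1]])
    if (anyDuplicated(probes)) {
      stop_ihc(sprintf("%s: duplicated probe IDs", mat_path))
    }
    sample_ids <- names(raw)[-1]  # before [.data.frame uniquifies them
    exprs <- as.matrix(raw[, -1, drop = FALSE])
    dimnames(exprs) <- list(probes, sample_ids)
    storage.mode(exprs) <- "double"
    probe_map <- read_delim_auto(resolve(manifest$probe_map[i]))
    followup <- read_delim_auto(resolve(manifest$followup[i]))
    followup$sample_id <- as.character(followup$sample_id)
    covariates <- NULL
    if ("covariates" %in% names(manifest) &&
        !is.na(manifest$covariates[i]) && nzchar(manifest$covariates[i])) {
      covariates <- read_delim_auto(resolve(manifest$covariates[i]))
      covariates$sample_id <- as.character(covariates$sample_id)
    }
    ds <- expression_dataset(manifest$dataset_id[i], exprs, probe_map,
                             followup, covariates)
    if (verbose) message(sprintf("dataset %s: %d probes x %d samples",
                                 ds$dataset_id, nrow(ds$exprs),
                                 ncol(ds$exprs)))
    ds
  })
}

#' Write a table as tab-separated text
#'
#' @param df data frame to write.
#' @param path output path.
#' @param na string used for missing values.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path, na = "NA") {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = na)
  invisible(path)
}

#' Write patient-level marker calls
#'
#' Writes the marker call table with the explicit token \code{missing}
#' for patients with no evaluable core.
#'
#' @param calls marker call table from \code{\link{score_ihc_cohort}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_marker_calls <- function(calls, path) {
  calls$level[is.na(calls$level)] <- "missing"
  write_tsv(calls, path, na = "")
}

#' Read a marker call table written by \code{\link{write_marker_calls}}
#'
#' @param path path to the table.
#' @return data frame with columns patient_id, marker, score, level
#'   (NA for missing).
#' @export
read_marker_calls <- function(path) {
  calls <- read_delim_auto(path)
  check_columns(calls, c("patient_id", "marker", "score", "level"), path)
  calls$patient_id <- as.character(calls$patient_id)
  calls$level[calls$level %in% c("missing", "")] <- NA_character_
  calls$score <- suppressWarnings(as.numeric(calls$score))
  check_marker_calls(calls)
  calls
}

#' Read a scoring configuration from a YAML file
#'
#' Recognised keys are the arguments of \code{\link{scoring_config}};
#' absent keys keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a \code{\link{scoring_config}}.
#' @export
read_scoring_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scoring_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0L) {
    stop_ihc(sprintf("unknown scoring config key(s): %s",
                     paste(extra, collapse = ", ")))
  }
  do.call(scoring_config, vals)
}
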