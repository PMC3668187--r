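# Cross-platform transcriptomic meta-analysis: probe-to-gene collapsing,
# per-dataset median dichotomisation, three-gene signature groups,
# pooling, and pooled Kaplan-Meier / log-rank / adjusted Cox on RFS.
#
# Group assignment is done within each dataset before pooling, so the
# whole procedure is invariant to strictly monotone per-dataset
# transformations of the expression values (platform location/scale
# effects cancel out of the median split).

PANEL_GENES <- c("ANLN", "PBK", "PDZK1")

#' Construct an expression dataset
#'
#' Bundles one platform's normalised probe-by-sample matrix with its
#' probe-to-gene map, per-sample recurrence-free survival follow-up, and
#' optional covariates, cross-validating the identifiers.
#'
#' @param dataset_id identifier for the dataset/platform.
#' @param exprs numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample IDs); values finite where
#'   present.
#' @param probe_map data frame with columns \code{probe}, \code{gene};
#'   probes without a mapping are dropped at collapse time.
#' @param followup data frame with columns \code{sample_id}, \code{time},
#'   \code{event}; every expression sample must appear.
#' @param covariates optional data frame with columns \code{sample_id}
#'   and any of \code{node}, \code{grade}, \code{er}; NA = missing.
#' @return object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(dataset_id, exprs, probe_map, followup,
                               covariates = NULL) {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)) || is.null(colnames(exprs))) {
    stop_ihc("expression matrix needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(exprs))) {
    stop_ihc(sprintf("dataset %s: duplicated probe IDs", dataset_id))
  }
  if (anyDuplicated(colnames(exprs))) {
    stop_ihc(sprintf("dataset %s: duplicated sample columns", dataset_id))
  }
  if (any(!is.finite(exprs))) {
    stop_ihc(sprintf("dataset %s: non-finite expression values", dataset_id))
  }
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    stop_ihc("probe_map needs columns 'probe' and 'gene'")
  }
  if (anyDuplicated(probe_map$probe)) {
    stop_ihc("probe_map has duplicated probe entries")
  }
  if (!all(c("sample_id", "time", "event") %in% names(followup))) {
    stop_ihc("followup needs columns sample_id, time, event")
  }
  absent <- setdiff(colnames(exprs), followup$sample_id)
  if (length(absent) > 0L) {
    stop_ihc(sprintf("dataset %s: sample(s) %s present in matrix but %s",
                     dataset_id, paste(utils::head(absent, 3), collapse = ", "),
                     "absent from follow-up"))
  }
  followup <- followup[match(colnames(exprs), followup$sample_id), ,
                       drop = FALSE]
  check_surv_input(followup$time, followup$event)
  if (!is.null(covariates)) {
    if (!"sample_id" %in% names(covariates)) {
      stop_ihc("covariates need a sample_id column")
    }
    covariates <- covariates[match(colnames(exprs), covariates$sample_id), ,
                             drop = FALSE]
  }
  structure(list(dataset_id = as.character(dataset_id), exprs = exprs,
                 probe_map = probe_map, followup = followup,
                 covariates = covariates),
            class = "expression_dataset")
}

#' Collapse probes to genes by averaging
#'
#' Gene-centres a probe-by-sample matrix: each gene's value per sample is
#' the arithmetic mean over its mapped probes. Probes without an entry in
#' the probe map are dropped (the count is reported via \code{message}).
#' Collapsing an already gene-level matrix is the identity.
#'
#' @param dataset an \code{\link{expression_dataset}}, or a probe matrix
#'   together with \code{probe_map}.
#' @param probe_map probe-to-gene map when \code{dataset} is a bare matrix.
#' @return numeric gene-by-sample matrix.
#' @export
collapse_probes <- function(dataset, probe_map = NULL) {
  if (inherits(dataset, "expression_dataset")) {
    exprs <- dataset$exprs
    probe_map <- dataset$probe_map
  } else {
    exprs <- as.matrix(dataset)
    if (is.null(probe_map)) stop_ihc("probe_map required for a bare matrix")
  }
  gene <- probe_map$gene[match(rownames(exprs), probe_map$probe)]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    message(sprintf("collapse_probes: dropping %d unmapped probe(s)",
                    sum(unmapped)))
  }
  exprs <- exprs[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  if (nrow(exprs) == 0L) stop_ihc("no mapped probes to collapse")
  out <- rowsum(exprs, group = gene, reorder = TRUE) /
    as.vector(table(gene)[sort(unique(gene))])
  as.matrix(out)
}

#' Median dichotomisation of expression values
#'
#' Splits one gene's values across a dataset's samples at the
#' within-dataset median (midpoint of the two central order statistics
#' for even n). A value strictly greater than the median is "high";
#' values equal to the median are "low". The split depends only on
#' ranks, so any strictly increasing transform of the values yields the
#' same levels.
#'
#' @param values finite numeric vector, length >= 2.
#' @return character vector of \code{"high"}/\code{"low"} per value.
#' @export
median_dichotomize <- function(values) {
  if (length(values) < 2L) stop_ihc("median_dichotomize needs >= 2 values")
  if (any(!is.finite(values))) stop_ihc("expression values must be finite")
  if (length(unique(values)) == 1L) {
    warning("all values identical; every sample classed 'low'", call. = FALSE)
  }
  m <- stats::median(values)
  ifelse(values > m, "high", "low")
}

#' Assign the three-gene signature group within one dataset
#'
#' Collapses probes, median-dichotomises ANLN, PBK and PDZK1 within the
#' dataset, and assigns each sample a group. In \code{"strict"} mode
#' (default) the poor-prognostic group requires high ANLN AND high PBK
#' AND low PDZK1; everything else is the reference group. In
#' \code{"score"} mode the 0-3 panel score is computed from the three
#' gene levels and dichotomised into reference ({0,1}) vs poor ({2,3}).
#'
#' @param dataset an \code{\link{expression_dataset}}.
#' @param mode \code{"strict"} or \code{"score"}.
#' @return data frame with columns \code{dataset_id}, \code{sample_id},
#'   \code{anln}, \code{pbk}, \code{pdzk1} (gene levels), \code{score},
#'   \code{group} ("poor"/"reference"), \code{time}, \code{event}, and
#'   covariate columns \code{node}, \code{grade}, \code{er} when present.
#' @export
assign_groups <- function(dataset, mode = c("strict", "score")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "expression_dataset"))
  genes <- suppressMessages(collapse_probes(dataset))
  absent <- setdiff(PANEL_GENES, rownames(genes))
  if (length(absent) > 0L) {
    stop_ihc(sprintf("dataset %s: gene(s) %s missing after collapsing",
                     dataset$dataset_id, paste(absent, collapse = ", ")))
  }
  lv <- lapply(PANEL_GENES, function(g) median_dichotomize(genes[g, ]))
  names(lv) <- PANEL_GENES
  score <- panel_score(lv$ANLN, lv$PBK, lv$PDZK1)
  group <- if (mode == "strict") {
    ifelse(lv$ANLN == "high" & lv$PBK == "high" & lv$PDZK1 == "low",
           "poor", "reference")
  } else {
    ifelse(score >= 2, "poor", "reference")
  }
  out <- data.frame(dataset_id = dataset$dataset_id,
                    sample_id = colnames(genes),
                    anln = lv$ANLN, pbk = lv$PBK, pdzk1 = lv$PDZK1,
                    score = score, group = group,
                    time = dataset$followup$time,
                    event = dataset$followup$event,
                    stringsAsFactors = FALSE)
  if (!is.null(dataset$covariates)) {
    for (nm in intersect(c("node", "grade", "er"),
                         names(dataset$covariates))) {
      out[[nm]] <- dataset$covariates[[nm]]
    }
  }
  out
}

#' Pool grouped datasets into one cohort
#'
#' Concatenates per-dataset grouped sample tables (group assignment must
#' already have been done within each dataset) into a single pooled
#' cohort, preserving dataset identity. Pooling is order-invariant for
#' all downstream statistics.
#'
#' @param grouped list of data frames from \code{\link{assign_groups}}.
#' @return data frame of class \code{pooled_cohort}.
#' @export
pool_datasets <- function(grouped) {
  if (length(grouped) == 0L) stop_ihc("no datasets to pool")
  cols <- Reduce(union, lapply(grouped, names))
  grouped <- lapply(grouped, function(g) {
    for (nm in setdiff(cols, names(g))) g[[nm]] <- NA
    g[, cols, drop = FALSE]
  })
  pooled <- do.call(rbind, grouped)
  rownames(pooled) <- NULL
  key <- paste(pooled$dataset_id, pooled$sample_id)
  if (anyDuplicated(key)) {
    stop_ihc("duplicate (dataset_id, sample_id) pairs after pooling")
  }
  class(pooled) <- c("pooled_cohort", "data.frame")
  pooled
}

#' Pooled survival analysis of the signature group
#'
#' Runs the global analysis on a pooled cohort: Kaplan-Meier curves and
#' the log-rank test comparing the poor vs reference group, and, when
#' \code{adjust = TRUE}, a Cox model of group adjusted for lymph node
#' status, tumour grade and ER status on complete-case samples (the
#' complete-case n is reported alongside the pooled n).
#'
#' @param pooled a \code{\link{pool_datasets}} result.
#' @param adjust fit the covariate-adjusted Cox model?
#' @return list with elements \code{km}, \code{logrank}, \code{n_pooled},
#'   \code{n_events}, and (when adjusted) \code{cox} and \code{n_complete}.
#' @export
pooled_survival_analysis <- function(pooled, adjust = FALSE) {
  stopifnot(is.data.frame(pooled))
  if (sum(pooled$event) == 0) {
    warning("no events in the pooled cohort; survival results degenerate",
            call. = FALSE)
  }
  out <- list(km = km_estimate(pooled$time, pooled$event, pooled$group),
              logrank = if (length(unique(pooled$group)) >= 2L &&
                            sum(pooled$event) > 0) {
                logrank_test(pooled$time, pooled$event, pooled$group)
              } else NULL,
              n_pooled = nrow(pooled), n_events = sum(pooled$event))
  if (adjust) {
    needed <- c("node", "grade", "er")
    absent <- setdiff(needed, names(pooled))
    if (length(absent) > 0L) {
      stop_ihc(sprintf("adjusted analysis needs covariate(s): %s",
                       paste(absent, collapse = ", ")))
    }
    covs <- data.frame(group = factor(pooled$group,
                                      levels = c("reference", "poor")),
                       node = pooled$node, grade = pooled$grade,
                       er = pooled$er, stringsAsFactors = FALSE)
    out$cox <- cox_fit(pooled$time, pooled$event, covs)
    out$n_complete <- out$cox$n_used
  }
  out
}
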