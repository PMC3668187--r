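# The 3-marker prognostic panel: panel score 0-3, Signature A/B, cohort
# completeness summaries and Table-1-style cross-tabulations.

#' Three-marker panel score
#'
#' Sums one point for each poor-prognostic marker state present in a
#' tumour: high ANLN, high PBK, and low PDZK1, giving a 0 (good) to 3
#' (poor) score. The score is defined only for patients with a
#' non-missing call for all three markers; any missing level propagates.
#'
#' @param anln_level,pbk_level,pdzk1_level character vectors with values
#'   \code{"high"}, \code{"low"} or NA (missing).
#' @return integer vector of panel scores 0-3, NA where any input is missing.
#' @examples
#' panel_score("high", "high", "low")  # 3
#' panel_score("low", "low", "high")   # 0
#' @export
panel_score <- function(anln_level, pbk_level, pdzk1_level) {
  assert_level(anln_level, "anln_level")
  assert_level(pbk_level, "pbk_level")
  assert_level(pdzk1_level, "pdzk1_level")
  s <- (anln_level == "high") + (pbk_level == "high") + (pdzk1_level == "low")
  as.integer(s)
}

#' Signature A/B dichotomisation of the panel score
#'
#' Splits the 0-3 panel score into a good prognostic set, Signature A
#' (scores 0 and 1), and a poor prognostic set, Signature B (scores 2
#' and 3).
#'
#' @param score integer vector of panel scores in {0,1,2,3}; NA propagates.
#' @return character vector with values \code{"A"}, \code{"B"} or NA.
#' @export
panel_signature <- function(score) {
  assert_int_range(score[!is.na(score)], 0, 3, "panel score")
  ifelse(is.na(score), NA_character_, ifelse(score >= 2, "B", "A"))
}

#' Patient-level panel table from marker calls
#'
#' Pivots a long marker-call table (one row per patient and marker) to
#' one row per patient and attaches the panel score and signature.
#' Patients missing any of the three markers get NA score and signature.
#'
#' @param marker_calls data frame with columns \code{patient_id},
#'   \code{marker}, \code{level} (as produced by
#'   \code{\link{score_ihc_cohort}}).
#' @return data frame with columns \code{patient_id}, \code{anln},
#'   \code{pbk}, \code{pdzk1}, \code{panel_score}, \code{signature}.
#' @export
build_panel <- function(marker_calls) {
  check_marker_calls(marker_calls)
  ids <- unique(marker_calls$patient_id)
  lvl <- function(m) {
    v <- marker_calls$level[match(paste(ids, m),
                                  paste(marker_calls$patient_id,
                                        marker_calls$marker))]
    v
  }
  out <- data.frame(patient_id = ids,
                    anln = lvl("ANLN"), pbk = lvl("PBK"),
                    pdzk1 = lvl("PDZK1"), stringsAsFactors = FALSE)
  out$panel_score <- panel_score(out$anln, out$pbk, out$pdzk1)
  out$signature <- panel_signature(out$panel_score)
  out
}

check_marker_calls <- function(marker_calls) {
  needed <- c("patient_id", "marker", "level")
  miss <- setdiff(needed, names(marker_calls))
  if (length(miss) > 0L) {
    stop_ihc(sprintf("marker call table is missing column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  key <- paste(marker_calls$patient_id, marker_calls$marker)
  if (anyDuplicated(key)) {
    stop_ihc("duplicate patient/marker rows in marker call table")
  }
  assert_marker(unique(marker_calls$marker))
  assert_level(marker_calls$level)
  invisible(marker_calls)
}

#' Cohort completeness and high/low summary
#'
#' Per-marker counts of evaluable patients (level non-missing), high and
#' low calls, plus the number of complete cases (patients with all three
#' markers called). Percent high/low use the evaluable denominator;
#' percent evaluable and percent complete-case use the full cohort size.
#' Percentages are rounded half-up to one decimal.
#'
#' @param marker_calls data frame with columns \code{patient_id},
#'   \code{marker}, \code{level}.
#' @param cohort_size total number of patients in the cohort (>= the
#'   number of scored patients).
#' @return a list of class \code{cohort_summary} with elements
#'   \code{markers} (data frame: marker, evaluable, evaluable_pct, high,
#'   high_pct, low, low_pct), \code{complete_cases},
#'   \code{complete_pct} and \code{cohort_size}.
#' @export
completeness_summary <- function(marker_calls, cohort_size) {
  check_marker_calls(marker_calls)
  n_scored <- length(unique(marker_calls$patient_id))
  if (cohort_size < n_scored) {
    stop_ihc("cohort_size is smaller than the number of scored patients")
  }
  per_marker <- lapply(MARKERS, function(m) {
    lv <- marker_calls$level[marker_calls$marker == m]
    ev <- sum(!is.na(lv))
    hi <- sum(lv == "high", na.rm = TRUE)
    lo <- sum(lv == "low", na.rm = TRUE)
    data.frame(marker = m, evaluable = ev,
               evaluable_pct = pct1(ev, cohort_size),
               high = hi, high_pct = pct1(hi, ev),
               low = lo, low_pct = pct1(lo, ev),
               stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, per_marker)

  # complete case: all three markers non-missing for the patient
  tab <- tapply(!is.na(marker_calls$level),
                list(marker_calls$patient_id, marker_calls$marker), any)
  tab[is.na(tab)] <- FALSE
  present <- intersect(MARKERS, colnames(tab))
  cc <- if (length(present) == length(MARKERS)) {
    sum(rowSums(tab[, MARKERS, drop = FALSE]) == length(MARKERS))
  } else 0L

  structure(list(markers = markers,
                 complete_cases = cc,
                 complete_pct = pct1(cc, cohort_size),
                 cohort_size = cohort_size),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$cohort_size))
  print(x$markers, row.names = FALSE)
  cat(sprintf("Complete cases (all 3 markers): %d (%.1f%%)\n",
              x$complete_cases, x$complete_pct))
  invisible(x)
}

#' Cross-tabulation of a covariate against the panel score
#'
#' Counts patients per covariate category within each panel-score column
#' and reports within-column percentages, excluding an "unknown" category
#' from the percentage denominator (its counts are still reported).
#' Percentages are rounded half-up to one decimal.
#'
#' @param score integer vector of panel scores in {0,1,2,3}.
#' @param covariate character/factor vector of covariate categories, same
#'   length as \code{score}; the token \code{unknown_token} marks
#'   missing values.
#' @param unknown_token category label excluded from percentage
#'   denominators (default \code{"unknown"}).
#' @return a list of class \code{panel_crosstab} with \code{counts}
#'   (categories x scores matrix, unknown row last when present),
#'   \code{pct} (within-column percentages over known categories),
#'   and \code{degenerate} (logical per score column: no known
#'   observations, percentages undefined).
#' @export
crosstab_percent <- function(score, covariate, unknown_token = "unknown") {
  if (length(score) != length(covariate)) {
    stop_ihc("score and covariate must have the same length")
  }
  keep <- !is.na(score)
  score <- score[keep]
  covariate <- as.character(covariate)[keep]
  assert_int_range(score, 0, 3, "panel score")
  covariate[is.na(covariate)] <- unknown_token

  cats <- unique(covariate)
  cats <- c(setdiff(cats, unknown_token),
            intersect(unknown_token, cats))
  counts <- table(factor(covariate, levels = cats),
                  factor(score, levels = 0:3))
  counts <- unclass(counts)
  known <- rownames(counts) != unknown_token
  denom <- colSums(counts[known, , drop = FALSE])
  pct <- sweep(counts[known, , drop = FALSE], 2, denom, "/") * 100
  pct <- round_half_up(pct, 1)
  pct[, denom == 0] <- NA_real_
  structure(list(counts = counts, pct = pct, degenerate = denom == 0),
            class = "panel_crosstab")
}

#' @export
print.panel_crosstab <- function(x, ...) {
  known <- rownames(x$counts) %in% rownames(x$pct)
  disp <- x$counts
  storage.mode(disp) <- "character"
  disp[known, ] <- sprintf("%s (%.1f)", x$counts[known, ], x$pct)
  cat("Counts (within-score-column % over known categories):\n")
  print(disp, quote = FALSE)
  if (any(x$degenerate)) {
    cat("Note: score column(s)", paste(colnames(x$counts)[x$degenerate],
                                       collapse = ", "),
        "have no known observations; percentages undefined.\n")
  }
  invisible(x)
}
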