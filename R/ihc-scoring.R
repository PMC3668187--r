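# Marker-specific scoring of TMA cores and patient-level dichotomised calls.
#
# Three schemes are supported, one per marker:
#   ANLN  - nuclear marker, scored by % of nuclei stained, binned 0-3;
#   PDZK1 - cytoplasmic marker, scored directly by staining intensity 0-3;
#   PBK   - cytoplasmic marker, intensity-distribution (ID) score =
#           intensity x % cells stained, scale 0-300.
# Cores failing tissue/cell-count QC are discarded; duplicate cores are
# combined by a consensus rule (maximum over evaluable cores by default)
# and the patient-level score is dichotomised at a marker-specific cut-off.

#' Scoring configuration
#'
#' Thresholds and QC limits for IHC scoring and dichotomisation. The
#' defaults are the published cut-offs for the ANLN/PBK/PDZK1 panel:
#' cores with less than 30\% tissue or fewer than 100 cells are discarded,
#' and high expression means ANLN category > 1, PDZK1 intensity > 2, and
#' PBK ID score > 48 (all strict).
#'
#' @param qc_min_tissue_percent minimum \% tissue for a core to be evaluable.
#' @param qc_min_cells minimum cell count for a core to be evaluable.
#' @param anln_high_above ANLN category strictly above which expression is high.
#' @param pdzk1_high_above PDZK1 intensity strictly above which expression is high.
#' @param pbk_high_above PBK ID score strictly above which expression is high.
#' @param consensus rule combining duplicate cores: \code{"max"} (default)
#'   or \code{"mean"} over evaluable cores.
#' @return an object of class \code{scoring_config}.
#' @export
scoring_config <- function(qc_min_tissue_percent = 30,
                           qc_min_cells = 100,
                           anln_high_above = 1,
                           pdzk1_high_above = 2,
                           pbk_high_above = 48,
                           consensus = c("max", "mean")) {
  consensus <- match.arg(consensus)
  for (v in c(qc_min_tissue_percent, qc_min_cells, anln_high_above,
              pdzk1_high_above, pbk_high_above)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_ihc("scoring_config thresholds must be finite scalars")
    }
  }
  structure(list(qc_min_tissue_percent = qc_min_tissue_percent,
                 qc_min_cells = qc_min_cells,
                 anln_high_above = anln_high_above,
                 pdzk1_high_above = pdzk1_high_above,
                 pbk_high_above = pbk_high_above,
                 consensus = consensus),
            class = "scoring_config")
}

#' Core-level quality control
#'
#' A core is evaluable when it has at least the minimum tissue fraction
#' and at least the minimum number of cells; "less than" is strict, so a
#' core with exactly 30\% tissue and exactly 100 cells passes.
#'
#' @param tissue_percent integer vector, \% of core area with tissue (0-100).
#' @param cell_count integer vector of cell counts (>= 0).
#' @param config a \code{\link{scoring_config}}.
#' @return logical vector: \code{TRUE} where the core is evaluable.
#' @examples
#' qc_filter_core(c(29, 30, 90), c(500, 100, 99))
#' @export
qc_filter_core <- function(tissue_percent, cell_count,
                           config = scoring_config()) {
  assert_int_range(tissue_percent, 0, 100, "tissue_percent")
  assert_int_range(cell_count, 0, Inf, "cell_count")
  tissue_percent >= config$qc_min_tissue_percent &
    cell_count >= config$qc_min_cells
}

#' ANLN nuclear-percentage category
#'
#' Bins the percentage of stained nuclei into the four ANLN categories:
#' 0 for <= 1\%, 1 for 2-25\%, 2 for 26-75\%, 3 for > 75\%.
#'
#' @param percent_nuclear integer vector of \% stained nuclei (0-100).
#' @return integer vector of categories in 0-3.
#' @examples
#' anln_category(c(1, 2, 25, 26, 75, 76))
#' @export
anln_category <- function(percent_nuclear) {
  assert_int_range(percent_nuclear, 0, 100, "percent_nuclear")
  ifelse(percent_nuclear <= 1, 0L,
         ifelse(percent_nuclear <= 25, 1L,
                ifelse(percent_nuclear <= 75, 2L, 3L)))
}

#' PDZK1 cytoplasmic intensity score
#'
#' PDZK1 is scored directly on the 0-3 semi-quantitative intensity scale
#' (0 negative, 1 weak, 2 medium, 3 strong); this validates the range and
#' passes the value through.
#'
#' @param intensity integer vector of staining intensities in {0,1,2,3}.
#' @return integer vector, identical to the validated input.
#' @export
pdzk1_score <- function(intensity) {
  assert_int_range(intensity, 0, 3, "intensity")
  as.integer(intensity)
}

#' PBK intensity-distribution (ID) score
#'
#' The ID score is staining intensity (0-3) multiplied by the percentage
#' of cells stained (0-100), giving a 0-300 scale.
#'
#' @param intensity integer vector of staining intensities in {0,1,2,3}.
#' @param percent_stained integer vector of \% cells stained (0-100).
#' @return numeric vector of ID scores in [0, 300].
#' @examples
#' pbk_id_score(2, 25)   # 50
#' pbk_id_score(0, 90)   # 0
#' @export
pbk_id_score <- function(intensity, percent_stained) {
  assert_int_range(intensity, 0, 3, "intensity")
  assert_int_range(percent_stained, 0, 100, "percent_stained")
  as.numeric(intensity) * as.numeric(percent_stained)
}

#' Consensus score over duplicate cores
#'
#' Combines the per-core scores of one patient/marker into a single
#' patient-level score over the evaluable cores: the maximum (default) or
#' the mean. Returns \code{NA} when no core is evaluable.
#'
#' @param scores numeric vector of per-core scores (length >= 1).
#' @param evaluable logical vector flagging cores that passed QC.
#' @param method \code{"max"} or \code{"mean"}.
#' @return a single score, or \code{NA} if no core is evaluable.
#' @export
consensus_score <- function(scores, evaluable = rep(TRUE, length(scores)),
                            method = c("max", "mean")) {
  method <- match.arg(method)
  if (length(scores) < 1L) stop_ihc("consensus_score: empty score list")
  if (length(evaluable) != length(scores)) {
    stop_ihc("consensus_score: scores and evaluable flags differ in length")
  }
  s <- scores[evaluable & !is.na(scores)]
  if (length(s) == 0L) return(NA_real_)
  if (method == "max") max(s) else mean(s)
}

#' Dichotomise a marker score into high/low
#'
#' High expression means the score strictly exceeds the marker's cut-off
#' (ANLN category > 1, PDZK1 intensity > 2, PBK ID score > 48 at the
#' default configuration); otherwise low. Missing scores propagate.
#'
#' @param marker character vector in {"ANLN","PBK","PDZK1"}.
#' @param score numeric vector of patient-level scores (NA = missing).
#' @param config a \code{\link{scoring_config}}.
#' @return character vector with values \code{"high"}, \code{"low"} or NA.
#' @examples
#' dichotomize("ANLN", 2)           # high
#' dichotomize("PBK", c(48, 49))    # low, high
#' @export
dichotomize <- function(marker, score, config = scoring_config()) {
  assert_marker(marker)
  n <- max(length(marker), length(score))
  marker <- rep_len(marker, n)
  score <- rep_len(score, n)
  thr <- c(ANLN = config$anln_high_above,
           PBK = config$pbk_high_above,
           PDZK1 = config$pdzk1_high_above)[marker]
  out <- ifelse(score > thr, "high", "low")
  out[is.na(score)] <- NA_character_
  unname(out)
}

# Score the cores of one marker on its own scale.
score_cores_for_marker <- function(marker, intensity, percent_stained) {
  switch(marker,
         ANLN = as.numeric(anln_category(percent_stained)),
         PDZK1 = as.numeric(pdzk1_score(intensity)),
         PBK = pbk_id_score(intensity, percent_stained),
         stop_ihc(sprintf("unknown marker '%s'", marker)))
}

#' Patient-level marker calls from a per-core observation table
#'
#' Runs the full scoring pipeline: core QC, marker-specific scoring,
#' duplicate-core consensus and dichotomisation, producing one row per
#' patient and marker. Patients with no evaluable core for a marker get
#' score NA and level NA (missing) for that marker.
#'
#' @param cores data frame with columns \code{patient_id},
#'   \code{core_index}, \code{marker}, \code{tissue_percent},
#'   \code{cell_count}, \code{intensity}, \code{percent_stained}.
#' @param config a \code{\link{scoring_config}}.
#' @return data frame with columns \code{patient_id}, \code{marker},
#'   \code{score}, \code{level}.
#' @export
score_ihc_cohort <- function(cores, config = scoring_config()) {
  needed <- c("patient_id", "core_index", "marker", "tissue_percent",
              "cell_count", "intensity", "percent_stained")
  miss <- setdiff(needed, names(cores))
  if (length(miss) > 0L) {
    stop_ihc(sprintf("cores table is missing column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  assert_marker(unique(cores$marker))
  evaluable <- qc_filter_core(cores$tissue_percent, cores$cell_count, config)

  score <- numeric(nrow(cores))
  for (m in unique(cores$marker)) {
    idx <- cores$marker == m
    score[idx] <- score_cores_for_marker(m, cores$intensity[idx],
                                         cores$percent_stained[idx])
  }

  key <- interaction(cores$patient_id, cores$marker, drop = TRUE)
  parts <- split(data.frame(score = score, evaluable = evaluable,
                            stringsAsFactors = FALSE), key)
  first <- !duplicated(key)
  out <- data.frame(patient_id = cores$patient_id[first],
                    marker = cores$marker[first],
                    stringsAsFactors = FALSE)
  out$score <- vapply(parts[as.character(key[first])], function(p) {
    consensus_score(p$score, p$evaluable, method = config$consensus)
  }, numeric(1))
  out$level <- dichotomize(out$marker, out$score, config)
  out <- out[order(out$patient_id, out$marker), , drop = FALSE]
  rownames(out) <- NULL
  out
}
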