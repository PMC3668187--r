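# Programmatic fixtures built from the published cohort counts and
# cross-tabulation, used by the summary/crosstab tests. These encode
# only printed counts; which synthetic patient carries which label is
# arbitrary.

# Marker-call table reproducing the published availability structure:
# 512 patients; ANLN called for 479 (309 high), PBK for 292 (105 high),
# PDZK1 for 280 (43 high); exactly the first 252 patients have all
# three markers (extra PBK patients are a subset of the extra ANLN
# patients, extra PDZK1 patients are disjoint from both).
published_marker_calls <- function() {
  ids <- sprintf("P%04d", 1:512)
  ev <- list(ANLN = c(1:252, 253:479),
             PBK = c(1:252, 253:292),
             PDZK1 = c(1:252, 480:507))
  hi <- list(ANLN = 309, PBK = 105, PDZK1 = 43)
  do.call(rbind, lapply(names(ev), function(m) {
    level <- rep(NA_character_, 512)
    level[ev[[m]]] <- "low"
    level[ev[[m]][seq_len(hi[[m]])]] <- "high"
    score <- ifelse(is.na(level), NA_real_,
                    ifelse(level == "high", 3, 0))
    data.frame(patient_id = ids, marker = m, score = score,
               level = level, stringsAsFactors = FALSE)
  }))
}

# Expand published crosstab counts (rows = categories incl. optional
# "unknown", cols = panel scores 0..3) into per-patient vectors.
expand_crosstab <- function(counts) {
  score <- integer(0)
  category <- character(0)
  for (j in seq_len(ncol(counts))) {
    for (i in seq_len(nrow(counts))) {
      n <- counts[i, j]
      score <- c(score, rep(j - 1L, n))
      category <- c(category, rep(rownames(counts)[i], n))
    }
  }
  list(score = score, category = category)
}

published_ki67_counts <- function() {
  matrix(c(5, 3, 1,  48, 29, 0,  33, 68, 4,  7, 53, 1), nrow = 3,
         dimnames = list(c("0-10%", "11-100%", "unknown"), 0:3))
}

published_grade_counts <- function() {
  matrix(c(4, 5, 0,  25, 42, 9,  23, 38, 44,  4, 19, 38), nrow = 3,
         dimnames = list(c("I", "II", "III"), 0:3))
}

published_nodal_counts <- function() {
  matrix(c(4, 2,  45, 21,  49, 47,  41, 15), nrow = 2,
         dimnames = list(c("N0", "N1+"), 0:3))
}

# Small survival fixture with ties, censoring and four groups.
four_group_fixture <- function() {
  data.frame(
    time  = c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8, 9, 10),
    event = c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 1),
    group = rep(c("a", "b", "c", "d"), 3))
}
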