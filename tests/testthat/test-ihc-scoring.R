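test_that("core QC applies strict less-than rules at the published limits", {
  # below either limit the core is discarded; exact boundaries pass
  expect_false(qc_filter_core(29, 500))
  expect_true(qc_filter_core(30, 100))
  expect_false(qc_filter_core(90, 99))
  expect_equal(qc_filter_core(c(0, 30, 100), c(1000, 100, 0)),
               c(FALSE, TRUE, FALSE))
  expect_error(qc_filter_core(101, 100), "tissue_percent")
  expect_error(qc_filter_core(50, -1), "cell_count")
  # limits are configurable
  cfg <- scoring_config(qc_min_tissue_percent = 50, qc_min_cells = 200)
  expect_false(qc_filter_core(49, 500, cfg))
  expect_true(qc_filter_core(50, 200, cfg))
})

test_that("ANLN nuclear-percentage bins partition 0..100 and are monotone", {
  expect_equal(anln_category(c(0, 1)), c(0L, 0L))
  expect_equal(anln_category(c(2, 25)), c(1L, 1L))
  expect_equal(anln_category(c(26, 50, 75)), c(2L, 2L, 2L))
  expect_equal(anln_category(c(76, 100)), c(3L, 3L))
  cats <- anln_category(0:100)
  expect_true(all(diff(cats) >= 0))          # non-decreasing
  expect_equal(sort(unique(cats)), 0:3)      # preimages partition 0..100
  expect_error(anln_category(101), "percent_nuclear")
  expect_error(anln_category(12.5), "percent_nuclear")
})

test_that("PDZK1 intensity passes through with validation", {
  expect_equal(pdzk1_score(c(0, 3)), c(0L, 3L))
  expect_error(pdzk1_score(4), "intensity")
  expect_error(pdzk1_score(-1), "intensity")
})

test_that("PBK ID score is the intensity x percent product on 0-300", {
  expect_equal(pbk_id_score(2, 25), 50)
  expect_equal(pbk_id_score(0, 90), 0)
  expect_equal(pbk_id_score(3, 100), 300)
  grid <- expand.grid(i = 0:3, p = seq(0, 100, by = 5))
  s <- pbk_id_score(grid$i, grid$p)
  expect_true(all(s >= 0 & s <= 300))
  expect_equal(s == 0, grid$i == 0 | grid$p == 0)  # zero iff a factor is 0
  # monotone in each argument
  expect_true(all(diff(pbk_id_score(0:3, 50)) > 0))
  expect_true(all(diff(pbk_id_score(rep(2, 5), c(0, 10, 40, 70, 100))) > 0))
  expect_error(pbk_id_score(4, 10), "intensity")
})

test_that("consensus is the max over evaluable cores, NA when none", {
  expect_equal(consensus_score(c(1, 3), c(TRUE, TRUE)), 3)
  expect_equal(consensus_score(c(2, 3), c(TRUE, FALSE)), 2)
  expect_true(is.na(consensus_score(c(1, 3), c(FALSE, FALSE))))
  expect_error(consensus_score(numeric(0)), "empty")
  # idempotent on singletons, permutation-invariant
  expect_equal(consensus_score(2.5), 2.5)
  x <- c(0, 3, 1, 2); ev <- c(TRUE, TRUE, FALSE, TRUE)
  perm <- c(3, 1, 4, 2)
  expect_equal(consensus_score(x, ev), consensus_score(x[perm], ev[perm]))
  # mean alternative
  expect_equal(consensus_score(c(1, 3), method = "mean"), 2)
})

test_that("dichotomisation reproduces the published high sets exactly", {
  expect_equal(dichotomize("ANLN", 0:3),
               c("low", "low", "high", "high"))
  expect_equal(dichotomize("PDZK1", 0:3),
               c("low", "low", "low", "high"))
  pbk <- dichotomize("PBK", 0:300)
  expect_equal(which(pbk == "high") - 1L, 49:300)  # (48, 300] is high
  expect_true(is.na(dichotomize("ANLN", NA)))
  expect_error(dichotomize("TP53", 1), "unknown marker")
})

test_that("cohort scoring runs QC, per-marker scoring, consensus and calls", {
  cores <- data.frame(
    patient_id = c("p1", "p1", "p1", "p1", "p2", "p2", "p3", "p3"),
    core_index = c(1, 2, 1, 2, 1, 2, 1, 2),
    marker = c("ANLN", "ANLN", "PBK", "PBK", "PDZK1", "PDZK1",
               "ANLN", "ANLN"),
    tissue_percent = c(80, 90, 85, 25, 95, 80, 20, 10),
    cell_count = c(500, 400, 300, 500, 200, 99, 500, 400),
    intensity = c(2, 2, 3, 3, 2, 3, 1, 1),
    percent_stained = c(30, 80, 20, 90, 50, 60, 10, 90))
  calls <- score_ihc_cohort(cores)

  a1 <- calls[calls$patient_id == "p1" & calls$marker == "ANLN", ]
  expect_equal(a1$score, 3)  # max(cat(30)=2, cat(80)=3)
  expect_equal(a1$level, "high")
  b1 <- calls[calls$patient_id == "p1" & calls$marker == "PBK", ]
  expect_equal(b1$score, 60)  # second core fails QC; 3 x 20
  expect_equal(b1$level, "high")
  d2 <- calls[calls$patient_id == "p2" & calls$marker == "PDZK1", ]
  expect_equal(d2$score, 2)   # low-cell core dropped; intensity 2
  expect_equal(d2$level, "low")
  a3 <- calls[calls$patient_id == "p3" & calls$marker == "ANLN", ]
  expect_true(is.na(a3$score))      # both cores fail QC
  expect_true(is.na(a3$level))      # never a high/low call without tissue
  expect_error(score_ihc_cohort(cores[, -4]), "tissue_percent")
})

test_that("patients with zero evaluable cores never get a high/low call", {
  set.seed(42)
  n <- 40
  cores <- data.frame(
    patient_id = rep(sprintf("q%02d", 1:n), each = 2),
    core_index = rep(1:2, n),
    marker = "PBK",
    tissue_percent = sample(0:100, 2 * n, replace = TRUE),
    cell_count = sample(0:300, 2 * n, replace = TRUE),
    intensity = sample(0:3, 2 * n, replace = TRUE),
    percent_stained = sample(0:100, 2 * n, replace = TRUE))
  calls <- score_ihc_cohort(cores)
  ev <- qc_filter_core(cores$tissue_percent, cores$cell_count)
  any_ev <- tapply(ev, cores$patient_id, any)
  expect_equal(is.na(calls$level[match(names(any_ev), calls$patient_id)]),
               as.vector(!any_ev))
})
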