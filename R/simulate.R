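# Seeded simulators for (a) a TMA-style IHC cohort with duplicate cores,
# correlated core loss and proportional-hazards outcomes, and (b) a
# collection of heterogeneous expression datasets with platform effects,
# probe multiplicity and survival tied to the three panel genes.
#
# Core-loss model: a core of marker m for patient i is lost (physically
# absent or failing QC) with probability pnorm(a_m + b * f_i), where
# f_i ~ N(0,1) is a shared per-patient fragility factor. Marginal
# patient-level availability of marker m is 1 - E[p_m(f)^2] (both
# duplicate cores lost). The intercepts a_m are calibrated to the target
# marginal availabilities and the loading b to the target three-marker
# completeness; with b = 0 (independent loss) the product of the default
# availabilities would give only ~29% completeness, far below the ~49%
# a real TMA shows, because loss is block-correlated across markers.

# Expectation over f ~ N(0,1) on a fixed quadrature grid.
.f_grid <- seq(-6, 6, length.out = 601)
.f_w <- stats::dnorm(.f_grid) * diff(.f_grid[1:2])
.f_w <- .f_w / sum(.f_w)

.loss_unavail <- function(a, b) sum(stats::pnorm(a + b * .f_grid)^2 * .f_w)

.calibrate_loss <- function(availability, completeness_target) {
  if (completeness_target > min(availability)) {
    stop_ihc("infeasible config: completeness target exceeds the smallest ",
             "marker availability")
  }
  solve_a <- function(b) {
    vapply(availability, function(av) {
      if (av >= 1) return(-Inf)  # no loss at all
      stats::uniroot(function(a) .loss_unavail(a, b) - (1 - av),
                     c(-30, 10), tol = 1e-10)$root
    }, numeric(1))
  }
  completeness_at <- function(b) {
    a <- solve_a(b)
    keep <- rep(1, length(.f_grid))
    for (ai in a) keep <- keep * (1 - stats::pnorm(ai + b * .f_grid)^2)
    sum(keep * .f_w)
  }
  if (completeness_at(0) >= completeness_target) {
    return(list(a = solve_a(0), b = 0))
  }
  b <- stats::uniroot(function(b) completeness_at(b) - completeness_target,
                      c(0, 6), tol = 1e-8, extendInt = "upX")$root
  list(a = solve_a(b), b = b)
}

#' Configuration for the TMA cohort simulator
#'
#' Defaults emulate the structure of the consecutive breast-cancer
#' cohort the panel was validated on: 512 patients with duplicate cores,
#' block-correlated core loss calibrated to per-marker availabilities of
#' 93.6\% (ANLN), 57.0\% (PBK) and 54.7\% (PDZK1) and ~49.2\%
#' three-marker completeness, marker-high rates of 64.5\%/36.0\%/15.4\%,
#' covariate margins modelled on the published cross-tabulation, and
#' exponential proportional-hazards outcomes over a 17-year
#' administrative horizon.
#'
#' @param seed integer RNG seed; all randomness flows from it.
#' @param n_patients number of patients.
#' @param cores_per_patient duplicate cores per patient and marker.
#' @param availability named vector of target per-marker patient-level
#'   availability fractions (ANLN, PBK, PDZK1).
#' @param completeness_target target fraction of patients with all three
#'   markers evaluable; must not exceed \code{min(availability)}.
#' @param marker_high named vector of target marker-high fractions.
#' @param shared_loading loading of the ANLN and PBK latent propensities
#'   on a shared proliferation factor (PDZK1 stays independent), giving
#'   a positive ANLN-PBK correlation.
#' @param effect \code{"signature"}: the hazard depends on the true
#'   Signature-B indicator (panel score >= 2); \code{"markers"}: on the
#'   three marker states individually.
#' @param signature_log_hr named vector (rfs, bcss) of log hazard ratios
#'   for Signature B under \code{effect = "signature"}.
#' @param marker_log_hr list with elements \code{rfs} and \code{bcss},
#'   each a named vector of log-HRs for high ANLN, high PBK, high PDZK1.
#' @param baseline_hazard named vector (rfs, bcss) of exponential
#'   baseline hazards per year.
#' @param censor_rate rate of the independent exponential censoring.
#' @param horizon administrative censoring horizon in years.
#' @param covariate_targets named list of covariate margins (see
#'   defaults) used to generate the clinicopathological table.
#' @return object of class \code{cohort_sim_config}.
#' @export
cohort_sim_config <- function(seed = 1L,
                              n_patients = 512L,
                              cores_per_patient = 2L,
                              availability = c(ANLN = 0.936, PBK = 0.570,
                                               PDZK1 = 0.547),
                              completeness_target = 0.492,
                              marker_high = c(ANLN = 0.645, PBK = 0.360,
                                              PDZK1 = 0.154),
                              shared_loading = 0.55,
                              effect = c("signature", "markers"),
                              signature_log_hr = c(rfs = log(3.33),
                                                   bcss = log(16.36)),
                              marker_log_hr = list(
                                rfs = c(ANLN = log(2.41), PBK = log(1.64),
                                        PDZK1 = log(0.65)),
                                bcss = c(ANLN = log(3.91), PBK = log(2.33),
                                         PDZK1 = log(0.17))),
                              baseline_hazard = c(rfs = 0.020, bcss = 0.008),
                              censor_rate = 0.04,
                              horizon = 17,
                              covariate_targets = list(
                                age_mean = 65, age_sd = 14,
                                age_range = c(27, 96),
                                size_gt2cm = 0.36,
                                grade = c(I = 0.22, II = 0.42, III = 0.36),
                                nodal_pos = 0.38, er_neg = 0.16,
                                pr_neg = 0.37, her2_pos = 0.11,
                                ki67_high = 0.62,
                                histology = c(ductal = 0.69, lobular = 0.128,
                                              indeterminate = 0.08,
                                              tubular = 0.056,
                                              medullary = 0.023,
                                              mucinous = 0.023),
                                unknown = c(nodal = 0.11, ER = 0.028,
                                            PR = 0.19, Her2 = 0.055,
                                            Ki67 = 0.024))) {
  effect <- match.arg(effect)
  stopifnot(n_patients >= 1, cores_per_patient >= 1, horizon > 0,
            all(availability > 0 & availability <= 1),
            completeness_target > 0, completeness_target <= 1,
            all(marker_high > 0 & marker_high < 1),
            shared_loading >= 0, shared_loading < 1)
  availability <- availability[MARKERS]
  marker_high <- marker_high[MARKERS]
  loss <- .calibrate_loss(availability, completeness_target)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 cores_per_patient = as.integer(cores_per_patient),
                 availability = availability,
                 completeness_target = completeness_target,
                 marker_high = marker_high, shared_loading = shared_loading,
                 effect = effect, signature_log_hr = signature_log_hr,
                 marker_log_hr = marker_log_hr,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, horizon = horizon,
                 covariate_targets = covariate_targets,
                 loss_intercepts = loss$a, loss_loading = loss$b),
            class = "cohort_sim_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Integer draw from lo:hi, vectorised over n.
rint <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

# Per-core observed (intensity, percent) for one marker given the true
# patient-level high/low state. Observer noise is boundary-respecting:
# duplicate-core jitter never crosses the dichotomisation cut-off, so
# misclassification of an evaluable patient cannot occur (documented as
# a simplification in the methods vignette).
.sim_marker_cores <- function(marker, high, k) {
  n <- length(high)
  if (marker == "ANLN") {
    base <- ifelse(high, rint(n, 26, 100), rint(n, 0, 25))
    pct <- clamp(rep(base, each = k) + round(stats::rnorm(n * k, 0, 4)),
                 ifelse(rep(high, each = k), 26, 0),
                 ifelse(rep(high, each = k), 100, 25))
    data.frame(intensity = anln_category(pct), percent_stained = pct)
  } else if (marker == "PDZK1") {
    base <- ifelse(high, 3L,
                   sample(0:2, n, replace = TRUE,
                          prob = c(0.35, 0.40, 0.25)))
    jit <- sample(c(-1L, 0L, 1L), n * k, replace = TRUE,
                  prob = c(0.15, 0.7, 0.15))
    intens <- clamp(rep(base, each = k) + jit,
                    0L, ifelse(rep(high, each = k), 3L, 2L))
    intens[rep(high, each = k)] <- 3L
    pct <- ifelse(intens == 0, 0L, rint(n * k, 10, 100))
    data.frame(intensity = intens, percent_stained = pct)
  } else { # PBK: ID score = intensity * percent, high iff > 48
    intens <- integer(n); pct_lo <- integer(n); pct_hi <- integer(n)
    hi_i <- sample(1:3, n, replace = TRUE, prob = c(0.15, 0.40, 0.45))
    lo_i <- sample(0:3, n, replace = TRUE, prob = c(0.30, 0.35, 0.25, 0.10))
    intens <- ifelse(high, hi_i, lo_i)
    pct_lo <- ifelse(high, floor(48 / intens) + 1L, 0L)
    pct_hi <- ifelse(high, 100L, ifelse(intens == 0, 100L,
                                        pmin(100L, floor(48 / intens))))
    base <- rint(n, pct_lo, pct_hi)
    pct <- clamp(rep(base, each = k) + round(stats::rnorm(n * k, 0, 3)),
                 rep(pct_lo, each = k), rep(pct_hi, each = k))
    data.frame(intensity = rep(intens, each = k), percent_stained = pct)
  }
}

#' Simulate a TMA-style cohort
#'
#' Generates a per-core IHC observation table, a clinicopathological
#' covariate table and a survival table, together with a truth record of
#' every generating parameter and latent state, so that the scoring,
#' panel and survival pipeline can be exercised and parameter recovery
#' can be verified. All randomness flows from \code{config$seed}; two
#' runs with equal configs are identical.
#'
#' @param config a \code{\link{cohort_sim_config}}.
#' @return list of class \code{tma_simulation}: \code{cores} (one row
#'   per patient, marker and core, scoring-pipeline input format),
#'   \code{covariates}, \code{survival} (patient_id, rfs_time,
#'   rfs_event, bcss_time, bcss_event) and \code{truth}.
#' @export
simulate_tma_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  k <- config$cores_per_patient
  tg <- config$covariate_targets
  ids <- sprintf("P%04d", seq_len(n))

  # latent structure: shared proliferation factor g drives ANLN, PBK,
  # grade and Ki67; PDZK1 is independent; f is TMA-block fragility.
  g <- stats::rnorm(n)
  f <- stats::rnorm(n)
  lam <- config$shared_loading
  z <- cbind(ANLN = lam * g + sqrt(1 - lam^2) * stats::rnorm(n),
             PBK = lam * g + sqrt(1 - lam^2) * stats::rnorm(n),
             PDZK1 = stats::rnorm(n))
  high <- sweep(z, 2, stats::qnorm(1 - config$marker_high[colnames(z)]),
                ">")

  # per-core observations
  cores <- do.call(rbind, lapply(MARKERS, function(m) {
    obs <- .sim_marker_cores(m, high[, m], k)
    lost <- stats::runif(n * k) <
      stats::pnorm(config$loss_intercepts[[m]] +
                     config$loss_loading * rep(f, each = k))
    tissue <- rint(n * k, 30, 100)
    cells <- rint(n * k, 100, 900)
    # a lost core fails QC by low tissue, low cell count, or both
    mode_lost <- sample(1:3, n * k, replace = TRUE, prob = c(0.45, 0.45, 0.1))
    tissue[lost & mode_lost != 2] <- rint(sum(lost & mode_lost != 2), 0, 29)
    cells[lost & mode_lost != 1] <- rint(sum(lost & mode_lost != 1), 0, 99)
    data.frame(patient_id = rep(ids, each = k),
               core_index = rep(seq_len(k), n),
               marker = m, tissue_percent = tissue, cell_count = cells,
               intensity = obs$intensity,
               percent_stained = obs$percent_stained,
               stringsAsFactors = FALSE)
  }))
  rownames(cores) <- NULL

  # covariates
  unk <- function(x, p) {
    x[stats::runif(length(x)) < p] <- "unknown"
    x
  }
  latent_er <- 0.45 * (-g) + sqrt(1 - 0.45^2) * stats::rnorm(n)
  er_neg <- latent_er < stats::qnorm(tg$er_neg)
  latent_pr <- 0.6 * latent_er + 0.8 * stats::rnorm(n)
  covariates <- data.frame(
    patient_id = ids,
    age = clamp(round(stats::rnorm(n, tg$age_mean, tg$age_sd)),
                tg$age_range[1], tg$age_range[2]),
    size = ifelse(stats::runif(n) < tg$size_gt2cm, ">2cm", "<=2cm"),
    histological_type = sample(names(tg$histology), n, replace = TRUE,
                               prob = tg$histology),
    grade = c("I", "II", "III")[
      findInterval(stats::pnorm(0.8 * g + 0.6 * stats::rnorm(n)),
                   cumsum(tg$grade)[-3]) + 1L],
    nodal = unk(ifelse(stats::runif(n) < tg$nodal_pos, "N1+", "N0"),
                tg$unknown[["nodal"]]),
    ER = unk(ifelse(er_neg, "neg", "pos"), tg$unknown[["ER"]]),
    PR = unk(ifelse(latent_pr < stats::qnorm(tg$pr_neg), "neg", "pos"),
             tg$unknown[["PR"]]),
    Her2 = unk(ifelse(stats::runif(n) < tg$her2_pos, "3+", "0-2+"),
               tg$unknown[["Her2"]]),
    Ki67 = unk(ifelse(0.7 * g + sqrt(1 - 0.49) * stats::rnorm(n) >
                        stats::qnorm(1 - tg$ki67_high),
                      "11-100%", "0-10%"),
               tg$unknown[["Ki67"]]),
    stringsAsFactors = FALSE)

  # proportional-hazards outcomes from the TRUE marker states
  score_true <- high[, "ANLN"] + high[, "PBK"] + (1 - high[, "PDZK1"])
  eta <- list()
  for (ep in c("rfs", "bcss")) {
    eta[[ep]] <- if (config$effect == "signature") {
      config$signature_log_hr[[ep]] * (score_true >= 2)
    } else {
      b <- config$marker_log_hr[[ep]]
      b[["ANLN"]] * high[, "ANLN"] + b[["PBK"]] * high[, "PBK"] +
        b[["PDZK1"]] * high[, "PDZK1"]
    }
  }
  surv <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (ep in c("rfs", "bcss")) {
    t_ev <- stats::rexp(n, config$baseline_hazard[[ep]] * exp(eta[[ep]]))
    t_cn <- pmin(stats::rexp(n, config$censor_rate), config$horizon)
    surv[[paste0(ep, "_time")]] <- round(pmin(t_ev, t_cn), 4)
    surv[[paste0(ep, "_event")]] <- as.integer(t_ev <= t_cn)
  }

  structure(list(cores = cores, covariates = covariates, survival = surv,
                 truth = list(config = config, fragility = f,
                              proliferation = g, marker_high = high,
                              score_true = score_true,
                              signature_true = ifelse(score_true >= 2,
                                                      "B", "A"),
                              eta = eta)),
            class = "tma_simulation")
}

#' Configuration for the expression-dataset simulator
#'
#' Defaults emulate the structure of a ten-dataset, ~1,300-sample
#' cross-platform meta-analysis: per-dataset location/scale platform
#' effects, one to three probes per gene, survival tied to the strict
#' poor-signature group (high ANLN, high PBK, low PDZK1 at the
#' within-dataset median) and covariates with enough missingness that
#' the complete-case n drops to roughly half the pooled n.
#'
#' @param seed integer RNG seed.
#' @param n_datasets number of datasets (platforms).
#' @param n_samples samples per dataset (recycled to \code{n_datasets}).
#' @param n_genes genes per dataset, including ANLN/PBK/PDZK1 (>= 3).
#' @param probes_per_gene_probs probabilities of 1, 2, ... probes per gene.
#' @param platform_loc_sd SD of the per-dataset location shift.
#' @param platform_scale_range range of the per-dataset scale factor.
#' @param probe_noise_sd SD of probe-level noise around the gene value
#'   (on the pre-platform scale).
#' @param n_unmapped_probes extra probes per dataset absent from the
#'   probe map (exercises unmapped-probe dropping).
#' @param shared_loading latent correlation loading of ANLN and PBK.
#' @param log_hr true log hazard ratio of the poor-signature group.
#' @param baseline_hazard exponential baseline hazard per year.
#' @param censor_rate independent exponential censoring rate.
#' @param horizon administrative censoring horizon in years.
#' @param covariate_missing per-covariate missingness probability (the
#'   complete-case fraction is roughly \code{(1 - covariate_missing)^3}).
#' @return object of class \code{expr_sim_config}.
#' @export
expr_sim_config <- function(seed = 1L,
                            n_datasets = 10L,
                            n_samples = 130L,
                            n_genes = 60L,
                            probes_per_gene_probs = c(0.5, 0.3, 0.2),
                            platform_loc_sd = 1.5,
                            platform_scale_range = c(0.6, 1.8),
                            probe_noise_sd = 0.3,
                            n_unmapped_probes = 2L,
                            shared_loading = 0.55,
                            log_hr = log(1.49),
                            baseline_hazard = 0.08,
                            censor_rate = 0.2,
                            horizon = 15,
                            covariate_missing = 0.189) {
  stopifnot(n_datasets >= 1, all(n_samples >= 4), n_genes >= 3,
            all(probes_per_gene_probs >= 0), platform_loc_sd >= 0,
            all(platform_scale_range > 0), probe_noise_sd >= 0,
            horizon > 0, covariate_missing >= 0, covariate_missing < 1)
  structure(list(seed = as.integer(seed), n_datasets = as.integer(n_datasets),
                 n_samples = rep_len(as.integer(n_samples), n_datasets),
                 n_genes = as.integer(n_genes),
                 probes_per_gene_probs = probes_per_gene_probs /
                   sum(probes_per_gene_probs),
                 platform_loc_sd = platform_loc_sd,
                 platform_scale_range = platform_scale_range,
                 probe_noise_sd = probe_noise_sd,
                 n_unmapped_probes = as.integer(n_unmapped_probes),
                 shared_loading = shared_loading, log_hr = log_hr,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, horizon = horizon,
                 covariate_missing = covariate_missing),
            class = "expr_sim_config")
}

#' Simulate heterogeneous expression datasets
#'
#' Generates \code{n_datasets} probe-by-sample expression matrices with
#' platform-specific location/scale shifts, probe maps, RFS follow-up
#' generated from the strict poor-signature group at the configured log
#' hazard ratio, and covariates (node, grade, ER) with configurable
#' missingness. The per-sample poor indicator is recorded in the truth
#' record.
#'
#' @param config an \code{\link{expr_sim_config}}.
#' @return list of class \code{expr_simulation}: \code{datasets} (list
#'   of \code{\link{expression_dataset}}) and \code{truth}.
#' @export
simulate_expression_datasets <- function(config = expr_sim_config()) {
  stopifnot(inherits(config, "expr_sim_config"))
  set.seed(config$seed)
  genes <- c(PANEL_GENES,
             sprintf("GENE%03d", seq_len(config$n_genes - 3)))
  mu <- stats::rnorm(length(genes), 6, 2)  # shared gene-level baselines
  names(mu) <- genes
  lam <- config$shared_loading

  datasets <- vector("list", config$n_datasets)
  truth_groups <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    did <- sprintf("DS%02d", d)
    ns <- config$n_samples[d]
    sample_ids <- sprintf("%s_S%03d", did, seq_len(ns))
    loc <- stats::rnorm(1, 0, config$platform_loc_sd)
    scl <- stats::runif(1, config$platform_scale_range[1],
                        config$platform_scale_range[2])

    gshared <- stats::rnorm(ns)
    zmat <- matrix(stats::rnorm(length(genes) * ns), length(genes), ns,
                   dimnames = list(genes, sample_ids))
    zmat["ANLN", ] <- lam * gshared + sqrt(1 - lam^2) * zmat["ANLN", ]
    zmat["PBK", ] <- lam * gshared + sqrt(1 - lam^2) * zmat["PBK", ]
    gene_vals <- loc + scl * (mu[genes] + zmat)

    # strict poor group at the within-dataset median of the gene values
    lv <- apply(gene_vals[PANEL_GENES, , drop = FALSE], 1,
                median_dichotomize)
    poor <- lv[, "ANLN"] == "high" & lv[, "PBK"] == "high" &
      lv[, "PDZK1"] == "low"

    # probe layer
    npp <- sample(seq_along(config$probes_per_gene_probs),
                  length(genes), replace = TRUE,
                  prob = config$probes_per_gene_probs)
    probe_gene <- rep(genes, npp)
    probe_ids <- sprintf("%s_p%04d", did, seq_along(probe_gene))
    exprs <- gene_vals[probe_gene, , drop = FALSE] +
      matrix(stats::rnorm(length(probe_gene) * ns, 0,
                          config$probe_noise_sd * scl),
             length(probe_gene), ns)
    rownames(exprs) <- probe_ids
    probe_map <- data.frame(probe = probe_ids, gene = probe_gene,
                            stringsAsFactors = FALSE)
    if (config$n_unmapped_probes > 0L) {
      extra_ids <- sprintf("%s_x%03d", did,
                           seq_len(config$n_unmapped_probes))
      extra <- matrix(stats::rnorm(config$n_unmapped_probes * ns, loc, scl),
                      config$n_unmapped_probes, ns,
                      dimnames = list(extra_ids, sample_ids))
      exprs <- rbind(exprs, extra)
    }

    t_ev <- stats::rexp(ns, config$baseline_hazard * exp(config$log_hr * poor))
    t_cn <- pmin(stats::rexp(ns, config$censor_rate), config$horizon)
    followup <- data.frame(sample_id = sample_ids,
                           time = round(pmin(t_ev, t_cn), 4),
                           event = as.integer(t_ev <= t_cn),
                           stringsAsFactors = FALSE)

    miss <- function(x) {
      x[stats::runif(length(x)) < config$covariate_missing] <- NA
      x
    }
    covariates <- data.frame(
      sample_id = sample_ids,
      node = miss(ifelse(stats::runif(ns) < 0.4, "N1+", "N0")),
      grade = miss(sample(c("I", "II", "III"), ns, replace = TRUE,
                          prob = c(0.2, 0.45, 0.35))),
      er = miss(ifelse(stats::runif(ns) < 0.75, "pos", "neg")),
      stringsAsFactors = FALSE)

    datasets[[d]] <- expression_dataset(did, exprs, probe_map, followup,
                                        covariates)
    truth_groups[[d]] <- data.frame(dataset_id = did, sample_id = sample_ids,
                                    poor = poor, stringsAsFactors = FALSE)
  }
  structure(list(datasets = datasets,
                 truth = list(config = config,
                              groups = do.call(rbind, truth_groups))),
            class = "expr_simulation")
}
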