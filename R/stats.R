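# Association and survival statistics: Kaplan-Meier curves, log-rank
# tests, Cox proportional-hazards regression, chi-square, Fisher's exact
# test and Pearson correlation, with the validation and reporting
# conventions used throughout the panel analyses. Model fitting is
# delegated to survival:: and stats::; this layer standardises inputs,
# complete-case handling and the result containers.

check_surv_input <- function(time, event) {
  if (length(time) == 0L) stop_ihc("empty survival input")
  if (length(time) != length(event)) {
    stop_ihc("time and event must have the same length")
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop_ihc("survival times must be finite and non-negative")
  }
  if (!all(event %in% c(0, 1))) {
    stop_ihc("event must be 0 (censored) or 1 (event)")
  }
  invisible(NULL)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function, overall or per group.
#' Subjects censored at an event time are counted at risk at that time.
#'
#' @param time non-negative follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param group optional group labels; one curve per group.
#' @return data frame with columns \code{group}, \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{surv};
#'   suitable for export as a delimited coordinate table.
#' @export
km_estimate <- function(time, event, group = NULL) {
  check_surv_input(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  if (length(group) != length(time)) {
    stop_ihc("group must have the same length as time")
  }
  d <- data.frame(time = time, event = event, group = as.character(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  grp <- if (is.null(fit$strata)) {
    rep(unique(d$group), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv, stringsAsFactors = FALSE)
}

#' Survival probability at a time point from a KM curve
#'
#' Step-function lookup: S(t) is the estimate at the latest event time
#' <= \code{t} within the group, or 1 before the first step.
#'
#' @param km data frame from \code{\link{km_estimate}}.
#' @param t time point.
#' @param group group label (default the first group present).
#' @return survival probability in [0, 1].
#' @export
km_surv_at <- function(km, t, group = km$group[1]) {
  k <- km[km$group == group & km$time <= t, , drop = FALSE]
  if (nrow(k) == 0L) return(1)
  k$surv[which.max(k$time)]
}

#' Log-rank test
#'
#' Mantel-Cox log-rank test comparing the survival of two or more
#' groups, with the hypergeometric variance and groups - 1 degrees of
#' freedom. With zero events the statistic is 0 and p = 1.
#'
#' @inheritParams km_estimate
#' @param group group labels (>= 2 distinct values).
#' @return list of class \code{logrank_result}: \code{statistic},
#'   \code{df}, \code{p_value}, \code{n}.
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  group <- as.character(group)
  if (length(unique(group)) < 2L) {
    stop_ihc("log-rank test needs at least two groups")
  }
  df <- length(unique(group)) - 1L
  if (sum(event) == 0) {
    res <- list(statistic = 0, df = df, p_value = 1, n = length(time))
  } else {
    d <- data.frame(time = time, event = event, group = group)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    res <- list(statistic = unname(sd$chisq), df = df,
                p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                n = length(time))
  }
  structure(res, class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

# One-hot encode a covariate data frame against first-alphabetical (or
# configured) reference levels; numeric columns pass through.
encode_covariates <- function(covariates, reference = NULL) {
  stopifnot(is.data.frame(covariates))
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (!is.numeric(v)) {
      lev <- if (is.factor(v)) {
        intersect(levels(v), unique(as.character(v[!is.na(v)])))
      } else {
        sort(unique(as.character(v[!is.na(v)])))
      }
      ref <- if (!is.null(reference) && nm %in% names(reference)) {
        reference[[nm]]
      } else lev[1]
      if (!ref %in% lev) {
        stop_ihc(sprintf("reference level '%s' absent from covariate '%s'",
                         ref, nm))
      }
      covariates[[nm]] <- factor(as.character(v),
                                 levels = c(ref, setdiff(lev, ref)))
    }
  }
  covariates
}

#' Cox proportional-hazards regression
#'
#' Fits a Cox model by partial-likelihood maximisation (Newton-type,
#' convergence tolerance 1e-9, at most 50 iterations) on complete-case
#' rows, reporting per-term hazard ratios with 95\% Wald confidence
#' intervals exp(beta +/- 1.959964 se). Categorical covariates are
#' one-hot encoded against a reference level (first alphabetical unless
#' given in \code{reference}).
#'
#' @inheritParams km_estimate
#' @param covariates data frame of covariates (numeric or categorical);
#'   rows align with \code{time}.
#' @param ties tie handling, \code{"efron"} (default) or \code{"breslow"}.
#' @param reference named list of reference levels for categorical
#'   covariates.
#' @return list of class \code{cox_result}: \code{terms} (data frame
#'   with coef, se, hr, ci_lower, ci_upper, p_value), \code{loglik}
#'   (log partial likelihood at the optimum), \code{n_used},
#'   \code{n_supplied}, \code{n_events}, \code{ties}.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow"),
                    reference = NULL) {
  ties <- match.arg(ties)
  check_surv_input(time, event)
  if (!is.data.frame(covariates) || nrow(covariates) != length(time)) {
    stop_ihc("covariates must be a data frame with one row per subject")
  }
  n_supplied <- length(time)
  cc <- stats::complete.cases(covariates) & !is.na(time) & !is.na(event)
  d <- covariates[cc, , drop = FALSE]
  time <- time[cc]; event <- event[cc]
  if (sum(event) < 1) stop_ihc("no events among complete cases")
  d <- encode_covariates(d, reference)
  for (nm in names(d)) {
    if (length(unique(d[[nm]])) < 2L) {
      stop_ihc(sprintf("covariate '%s' is constant on complete cases; %s",
                       nm, "the model is not identifiable"))
    }
  }
  d$.time <- time; d$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", setdiff(names(d), c(".time", ".event"))),
          collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        stop_ihc("Cox fit did not converge (possible perfect separation): ",
                 conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit))) {
    stop_ihc("Cox fit produced non-identifiable coefficients")
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- 1.959964
  terms <- data.frame(term = names(beta), coef = unname(beta),
                      se = unname(se), hr = exp(unname(beta)),
                      ci_lower = exp(unname(beta) - z * unname(se)),
                      ci_upper = exp(unname(beta) + z * unname(se)),
                      p_value = 2 * stats::pnorm(-abs(unname(beta) /
                                                        unname(se))),
                      stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  structure(list(terms = terms, loglik = fit$loglik[2],
                 n_used = fit$n, n_supplied = n_supplied,
                 n_events = sum(event), ties = ties),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties), n = %d of %d supplied, %d events\n",
              x$ties, x$n_used, x$n_supplied, x$n_events))
  t <- x$terms
  t$hr_ci <- sprintf("%.2f (%.2f-%.2f)", t$hr, t$ci_lower, t$ci_upper)
  print(t[, c("term", "coef", "se", "hr_ci", "p_value")], row.names = FALSE)
  invisible(x)
}

as_count_matrix <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0L || sum(x) == 0) stop_ihc("empty contingency table")
  if (any(x < 0) || any(!is.finite(x))) {
    stop_ihc("contingency counts must be finite and non-negative")
  }
  x
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square statistic against independence with
#' (r-1)(c-1) degrees of freedom and no continuity correction. Rows or
#' columns with a zero margin are dropped with a warning before the
#' degrees of freedom are computed.
#'
#' @param counts matrix (or object coercible to one) of non-negative counts.
#' @return list of class \code{association_result}: \code{test},
#'   \code{statistic}, \code{df}, \code{p_value}, \code{n}.
#' @export
chi_square_test <- function(counts) {
  x <- as_count_matrix(counts)
  rz <- rowSums(x) == 0; cz <- colSums(x) == 0
  if (any(rz) || any(cz)) {
    warning("dropping zero-margin rows/columns from the contingency table",
            call. = FALSE)
    x <- x[!rz, !cz, drop = FALSE]
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop_ihc("chi-square test needs at least a 2x2 table after dropping ",
             "zero margins")
  }
  ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  structure(list(test = "chi-square", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = unname(ct$p.value),
                 n = sum(x)),
            class = "association_result")
}

#' Fisher's exact test on a contingency table
#'
#' For a 2x2 table, the exact two-sided p-value by hypergeometric
#' enumeration (summing tables whose conditional probability does not
#' exceed the observed one). For larger tables, a seeded Monte Carlo
#' permutation p-value with at least 1e5 draws.
#'
#' @param counts matrix of non-negative integer counts.
#' @param b Monte Carlo replicates for tables larger than 2x2.
#' @param simulate force the Monte Carlo path even on a 2x2 table
#'   (used for self-consistency checks against the exact p).
#' @return list of class \code{association_result}.
#' @export
fisher_exact <- function(counts, b = 1e5, simulate = FALSE) {
  x <- as_count_matrix(counts)
  assert_int_range(as.vector(x), 0, Inf, "contingency count")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    p <- 1
  } else if (nrow(x) == 2L && ncol(x) == 2L && !simulate) {
    p <- stats::fisher.test(x)$p.value
  } else {
    p <- stats::fisher.test(x, simulate.p.value = TRUE,
                            B = max(b, 1e5))$p.value
  }
  structure(list(test = "fisher", statistic = NA_real_, df = NA_real_,
                 p_value = min(p, 1), n = sum(x)),
            class = "association_result")
}

#' Pearson correlation with t-based p-value
#'
#' Pearson's r between two numeric vectors with the two-sided p-value
#' from the t transform on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return list of class \code{association_result} with additional
#'   element \code{r}.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_ihc("x and y must have the same length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_ihc("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ihc("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(test = "pearson", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = unname(ct$p.value),
                 r = unname(ct$estimate), n = length(x)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s test: ", x$test))
  if (!is.na(x$statistic)) cat(sprintf("statistic = %.4g, ", x$statistic))
  if (!is.null(x$r)) cat(sprintf("r = %.3f, ", x$r))
  if (!is.na(x$df)) cat(sprintf("df = %g, ", x$df))
  cat(sprintf("p = %.4g (n = %d)\n", x$p_value, x$n))
  invisible(x)
}
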