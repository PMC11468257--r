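# Cohort-level statistics: the battery applied to a feature + outcome table
# (rank tests, Spearman, ROC/Youden/DeLong, logistic, Cox, Kaplan-Meier).

#' Rank test of a feature across groups
#'
#' Two groups: Mann-Whitney U (exact when there are no ties and both groups
#' have fewer than 50 observations, otherwise the normal approximation with
#' tie correction and no continuity correction, so a mean-valued U yields
#' p = 1). More than two groups: Kruskal-Wallis.
#'
#' @param values numeric vector, one value per patient.
#' @param groups grouping vector (>= 2 nonempty groups).
#' @return list with `p_value`, `method`, `statistic`.
#' @export
rank_tests <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two nonempty groups", call. = FALSE)
  if (min(table(groups)) < 1L) stop("empty group", call. = FALSE)
  if (k == 2L) {
    x <- values[groups == levels(groups)[1]]
    y <- values[groups == levels(groups)[2]]
    use_exact <- !any(duplicated(values)) && length(x) < 50 && length(y) < 50
    ht <- stats::wilcox.test(x, y, exact = use_exact, correct = FALSE)
    list(p_value = unname(ht$p.value), method = "mann-whitney",
         statistic = unname(ht$statistic))
  } else {
    ht <- stats::kruskal.test(values, groups)
    list(p_value = unname(ht$p.value), method = "kruskal-wallis",
         statistic = unname(ht$statistic))
  }
}

#' Spearman rank correlation with t-approximation p-value
#'
#' @param x,y paired numeric vectors, n >= 3; constant input is an error
#'   (rho undefined).
#' @return list with `rho` and `p_value`.
#' @export
spearman_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("constant input: Spearman correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

# AUC by the Mann-Whitney identity, convention "higher score -> positive";
# ties count 1/2. Rank-based, O(n log n).
auc_mw <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# DeLong placement values: V10 (one per positive), V01 (one per negative).
delong_placements <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp), auc = mean(cmp),
       m = m, n = n)
}

check_labels <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) stop("labels must be 0/1 or logical", call. = FALSE)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

#' ROC analysis with Youden-index cutoff
#'
#' AUC via the Mann-Whitney identity (ties 1/2), 95% CI by the DeLong
#' variance, optimal cutoff maximizing J = sensitivity + specificity - 1 over
#' midpoints between adjacent distinct scores (smallest cutoff on ties). The
#' orientation is chosen so that AUC >= 0.5 and reported as `direction`:
#' `">"` means values above the cutoff predict the positive class, `"<"`
#' values below it.
#'
#' @param scores numeric marker values.
#' @param labels 0/1 or logical outcome (positive = 1).
#' @return list of class `roc_summary`: `auc`, `auc_ci95`, `cutoff`,
#'   `sensitivity_pct`, `specificity_pct`, `direction`, `j`.
#' @export
roc_youden <- function(scores, labels) {
  labels <- check_labels(labels)
  ok <- is.finite(scores)
  scores <- scores[ok]; labels <- labels[ok]
  raw_auc <- auc_mw(scores, labels)
  direction <- if (raw_auc >= 0.5) ">" else "<"
  oriented <- if (direction == ">") scores else -scores
  pl <- delong_placements(oriented, labels)
  se <- sqrt(stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n)
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * stats::qnorm(0.975) * se))

  s <- sort(unique(scores))
  if (length(s) < 2L) {
    cutoffs <- s
  } else {
    cutoffs <- (s[-1] + s[-length(s)]) / 2
  }
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- spec <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    if (direction == ">") {
      sens[i] <- mean(pos > cutoffs[i]); spec[i] <- mean(neg <= cutoffs[i])
    } else {
      sens[i] <- mean(pos < cutoffs[i]); spec[i] <- mean(neg >= cutoffs[i])
    }
  }
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.min(cutoffs[best])]
  structure(list(auc = pl$auc, auc_ci95 = ci, cutoff = cutoffs[best],
                 sensitivity_pct = 100 * sens[best],
                 specificity_pct = 100 * spec[best],
                 direction = direction, j = j[best]),
            class = "roc_summary")
}

#' Paired DeLong comparison of two AUCs
#'
#' Two-sided test of equal AUC for two markers measured on the same subjects.
#' Each marker is oriented so its AUC >= 0.5 before comparison (the usual
#' reporting convention).
#'
#' @param scores_a,scores_b paired marker values.
#' @param labels shared 0/1 outcome.
#' @return list with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- check_labels(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores and labels must be paired (equal length)", call. = FALSE)
  }
  orient <- function(s) if (auc_mw(s, labels) >= 0.5) s else -s
  pa <- delong_placements(orient(scores_a), labels)
  pb <- delong_placements(orient(scores_b), labels)
  var_d <- stats::var(pa$v10 - pb$v10) / pa$m + stats::var(pa$v01 - pb$v01) / pa$n
  d <- pa$auc - pb$auc
  if (var_d <= .Machine$double.eps) {
    if (abs(d) <= .Machine$double.eps^0.5) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p_value = 1))
    }
    stop("degenerate DeLong comparison: zero variance with unequal AUCs",
         call. = FALSE)
  }
  z <- d / sqrt(var_d)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

# Standard factor codings used in the report tables: Luminal A is the
# molecular-subtype reference; T and N stage are the binary groupings.
SUBTYPE_LEVELS <- c("Luminal A", "Luminal B", "HER2-enriched", "Triple negative")
T_LEVELS <- c("T1-T2", "T3-T4")
N_LEVELS <- c("N0", "N1-N3")

coerce_cohort <- function(cohort) {
  if ("molecular_subtype" %in% names(cohort)) {
    cohort$molecular_subtype <- factor(cohort$molecular_subtype,
                                       levels = SUBTYPE_LEVELS)
  }
  if ("clinical_t" %in% names(cohort)) {
    cohort$clinical_t <- factor(cohort$clinical_t, levels = T_LEVELS)
  }
  if ("clinical_n" %in% names(cohort)) {
    cohort$clinical_n <- factor(cohort$clinical_n, levels = N_LEVELS)
  }
  cohort
}

DEFAULT_COVARIATES <- c("age", "clinical_t", "clinical_n", "molecular_subtype")

model_formula <- function(outcome, parameter, covariates, adjusted) {
  rhs <- parameter
  if (adjusted) rhs <- c(parameter, covariates)
  stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
}

summarize_fit <- function(coefs, parameter, adjusted, covariates, converged, n,
                          effect_name) {
  row <- grep(paste0("^", parameter), rownames(coefs))[1]
  est <- coefs[row, 1]; se <- coefs[row, 2]
  p <- 2 * stats::pnorm(-abs(est / se))
  structure(list(parameter = parameter,
                 p_value = p,
                 effect = exp(est),
                 ci95 = exp(est + c(-1, 1) * stats::qnorm(0.975) * se),
                 log_effect = est, se = se,
                 adjusted = adjusted,
                 covariates = if (adjusted) covariates else character(0),
                 converged = converged, n = n,
                 effect_name = effect_name),
            class = "model_summary")
}

#' Logistic regression odds ratio for pathological complete response
#'
#' Fits `pcr ~ parameter` (univariate) or `pcr ~ parameter + age + T stage +
#' N stage + molecular subtype` (adjusted), with dummy coding as in the
#' report tables. The odds ratio is per 1.00 increase of the parameter.
#'
#' @param cohort data.frame with a logical/0-1 `pcr` column, the parameter
#'   column, and (if adjusted) the covariate columns.
#' @param parameter name of the feature column.
#' @param covariates covariate column names for the adjusted model.
#' @param adjusted fit the multivariate model (one PET parameter at a time
#'   plus the fixed clinical covariates — never several PET parameters
#'   jointly).
#' @return A `model_summary` list: `parameter`, `p_value`, `effect` (OR),
#'   `ci95`, `adjusted`, `covariates`, `converged`, `n`.
#' @export
logistic_or <- function(cohort, parameter, covariates = DEFAULT_COVARIATES,
                        adjusted = FALSE) {
  cohort <- coerce_cohort(cohort)
  y <- cohort$pcr
  if (is.null(y)) stop("cohort has no 'pcr' column", call. = FALSE)
  if (length(unique(stats::na.omit(y))) < 2L) {
    stop("outcome has no variation: logistic model not identifiable", call. = FALSE)
  }
  if (length(unique(stats::na.omit(cohort[[parameter]]))) < 2L) {
    stop("parameter '", parameter, "' is constant", call. = FALSE)
  }
  f <- model_formula("pcr", parameter, covariates, adjusted)
  fit <- stats::glm(f, data = cohort, family = stats::binomial())
  coefs <- summary(fit)$coefficients
  separated <- any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
    any(coefs[, 2] > 100)
  out <- summarize_fit(coefs, parameter, adjusted, covariates,
                       converged = fit$converged && !separated,
                       n = stats::nobs(fit), effect_name = "odds_ratio")
  if (!out$converged) {
    warning("logistic fit for '", parameter,
            "' did not converge cleanly (possible separation)", call. = FALSE)
  }
  out
}

#' Cox proportional-hazards ratio for progression-free survival
#'
#' Fits `Surv(pfs_months, event) ~ parameter` (plus the fixed clinical
#' covariates when adjusted) with Efron handling of tied event times. The
#' hazard ratio is per 1.00 increase of the parameter.
#'
#' @inheritParams logistic_or
#' @return A `model_summary` list with `effect` = hazard ratio.
#' @export
cox_hr <- function(cohort, parameter, covariates = DEFAULT_COVARIATES,
                   adjusted = FALSE) {
  cohort <- coerce_cohort(cohort)
  if (is.null(cohort$pfs_months) || is.null(cohort$event)) {
    stop("cohort needs 'pfs_months' and 'event' columns", call. = FALSE)
  }
  if (sum(cohort$event, na.rm = TRUE) == 0L) {
    stop("no events: Cox model not estimable", call. = FALSE)
  }
  if (length(unique(stats::na.omit(cohort[[parameter]]))) < 2L) {
    stop("parameter '", parameter, "' is constant", call. = FALSE)
  }
  f <- model_formula("survival::Surv(pfs_months, event)", parameter,
                     covariates, adjusted)
  fit <- survival::coxph(f, data = cohort, ties = "efron")
  coefs <- summary(fit)$coefficients[, c("coef", "se(coef)"), drop = FALSE]
  summarize_fit(coefs, parameter, adjusted, covariates,
                converged = TRUE, n = fit$n, effect_name = "hazard_ratio")
}

#' Kaplan-Meier curves and log-rank test at a cutoff
#'
#' Dichotomizes the cohort at `cutoff` (high = score > cutoff), estimates
#' product-limit curves per group, evaluates survival at a horizon by step
#' function, and compares the groups with the two-sided log-rank test. With
#' no events anywhere the log-rank statistic is degenerate and p is reported
#' as 1 with `degenerate = TRUE`.
#'
#' @param cohort data.frame with `pfs_months` and `event`.
#' @param score feature column name used for grouping.
#' @param cutoff dichotomization threshold (e.g. the Youden cutoff from
#'   [roc_youden()]).
#' @param horizon_months time at which per-group survival is reported
#'   (default 60, i.e. 5-year).
#' @return list of class `km_summary`: `group` (per patient), `curves`
#'   (data.frame: group, time, n_risk, n_event, survival), `logrank_p`,
#'   `survival_at_horizon` (named, per group), `degenerate`.
#' @export
km_logrank <- function(cohort, score, cutoff, horizon_months = 60) {
  x <- cohort[[score]]
  if (is.null(x)) stop("no column '", score, "' in cohort", call. = FALSE)
  grp <- factor(ifelse(x > cutoff, "high", "low"), levels = c("low", "high"))
  if (any(table(grp) == 0L)) {
    stop("cutoff does not split the cohort into two nonempty groups", call. = FALSE)
  }
  df <- data.frame(time = cohort$pfs_months, event = as.integer(cohort$event),
                   group = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, survival = fit$surv,
                       stringsAsFactors = FALSE)
  sv <- summary(fit, times = horizon_months, extend = TRUE)
  s_at <- stats::setNames(sv$surv, sub("^group=", "", as.character(sv$strata)))
  degenerate <- sum(df$event) == 0L
  if (degenerate) {
    p <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  }
  structure(list(group = grp, curves = curves, logrank_p = p,
                 survival_at_horizon = s_at, degenerate = degenerate,
                 cutoff = cutoff, horizon_months = horizon_months),
            class = "km_summary")
}
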