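#' Kaplan-Meier relapse-free survival by group
#'
#' RFS runs from diagnosis to the first of relapse or death; patients alive
#' in remission are censored at last follow-up. Product-limit curves are
#' computed per group and compared with the log-rank test; the step function
#' is evaluated at requested horizons (default 5 and 10 years).
#'
#' @param data Data frame with `time_years`, `event` (0/1) and the grouping
#'   column.
#' @param group Name of the grouping column.
#' @param horizons Times (years) at which to report RFS.
#' @return List with `fit` (a `survfit`), `rfs` (data frame group x horizon,
#'   percent), `logrank_p` (NA, flagged, if the comparison is degenerate),
#'   `degenerate`.
#' @export
km_rfs <- function(data, group = "group", horizons = c(5, 10)) {
  stopifnot(all(c("time_years", "event") %in% names(data)))
  if (any(data$time_years < 0)) stop("negative follow-up time")
  g <- factor(data[[group]])
  fit <- survival::survfit(
    survival::Surv(data$time_years, data$event) ~ g)
  sm <- summary(fit, times = horizons, extend = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(g)[1], length(sm$time)) else
    sub("^g=", "", as.character(sm$strata))
  rfs <- data.frame(group = strata, time = sm$time,
                    rfs_pct = 100 * sm$surv, stringsAsFactors = FALSE)
  degenerate <- nlevels(g) < 2 || sum(data$event) == 0
  logrank_p <- NA_real_
  if (!degenerate) {
    sd <- survival::survdiff(
      survival::Surv(data$time_years, data$event) ~ g)
    logrank_p <- stats::pchisq(sd$chisq, df = nlevels(g) - 1,
                               lower.tail = FALSE)
  }
  list(fit = fit, rfs = rfs, logrank_p = logrank_p, degenerate = degenerate)
}

#' Cox proportional-hazards models for relapse-free survival
#'
#' Univariate (one model per covariate) or multivariate (all covariates
#' jointly) partial-likelihood fits with Wald confidence intervals and Efron
#' tie handling. Age is entered per 5-year increase; treatment protocol, when
#' present, is a factor with "PETHEMA" as the reference level.
#'
#' @param data Data frame with `time_years`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param mode "univariate" or "multivariate".
#' @return Data frame of class `CoxResult`: one row per coefficient with
#'   `covariate`, `term`, `hr`, `ci_lower`, `ci_upper`, `p_value`, `mode`.
#' @export
cox_fit <- function(data, covariates, mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  if (sum(data$event) == 0) stop("no events; Cox model cannot be fitted")
  dat <- data
  if ("age" %in% covariates) dat$age <- dat$age / 5   # per 5-year increase
  if ("protocol" %in% covariates) {
    lv <- unique(dat$protocol)
    ref <- if ("PETHEMA" %in% lv) "PETHEMA" else lv[1]
    dat$protocol <- stats::relevel(factor(dat$protocol), ref = ref)
  }
  fit_one <- function(covs) {
    fml <- stats::as.formula(paste(
      "survival::Surv(time_years, event) ~", paste(covs, collapse = " + ")))
    fit <- survival::coxph(fml, data = dat, ties = "efron")
    if (any(is.na(stats::coef(fit))))
      stop("Cox fit failed (degenerate covariate or separation): ",
           paste(covs, collapse = ", "))
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               ci_lower = s$conf.int[, "lower .95"],
               ci_upper = s$conf.int[, "upper .95"],
               p_value = s$coefficients[, "Pr(>|z|)"],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (mode == "multivariate") {
    out <- fit_one(covariates)
    out$covariate <- out$term
  } else {
    out <- do.call(rbind, lapply(covariates, function(cv) {
      o <- fit_one(cv); o$covariate <- cv; o
    }))
  }
  out$mode <- mode
  class(out) <- c("CoxResult", "data.frame")
  out
}

#' Maximally selected log-rank cutpoint for a continuous marker
#'
#' Scans candidate cutpoints of a continuous marker (e.g. the percentage of
#' the major clone), restricted to the inner quantile range of its observed
#' values, and at each candidate computes the standardized log-rank
#' statistic for the two groups (marker <= c vs > c). The cutpoint with the
#' largest statistic dichotomizes the marker. When the maximum statistic is
#' small the cutpoint is unstable and flagged.
#'
#' @param marker Numeric marker values, one per patient.
#' @param data Data frame with `time_years` and `event`, aligned with
#'   `marker`.
#' @param quantiles Inner quantile restriction for candidates (default
#'   0.10-0.90), preventing boundary cutpoints.
#' @param grid Optional explicit candidate grid; defaults to the observed
#'   marker values within the quantile range.
#' @param min_stat Standardized statistic below which the cutpoint is
#'   flagged unstable (default 1.64).
#' @return List with `cutpoint`, `statistic`, `profile` (data frame
#'   `cutpoint`, `statistic` for plotting), `unstable`.
#' @export
max_rank_cutoff <- function(marker, data, quantiles = c(0.10, 0.90),
                            grid = NULL, min_stat = 1.64) {
  stopifnot(length(marker) == nrow(data))
  rng <- stats::quantile(marker, quantiles, names = FALSE)
  if (is.null(grid)) {
    grid <- sort(unique(marker[marker >= rng[1] & marker <= rng[2]]))
    grid <- grid[grid < max(marker)]   # both sides must be non-empty
  } else {
    if (any(grid < min(marker)) || any(grid > max(marker)))
      stop("candidate grid extends outside the observed marker range")
  }
  if (!length(grid)) stop("no candidate cutpoints inside the quantile range")
  stat <- vapply(grid, function(cc) {
    hi <- marker > cc
    if (!any(hi) || all(hi)) return(NA_real_)
    sd <- survival::survdiff(
      survival::Surv(data$time_years, data$event) ~ hi)
    sqrt(sd$chisq)
  }, numeric(1))
  ok <- !is.na(stat)
  best <- which.max(ifelse(ok, stat, -Inf))
  list(cutpoint = grid[best], statistic = stat[best],
       profile = data.frame(cutpoint = grid, statistic = stat),
       unstable = !ok[best] || stat[best] < min_stat)
}

#' Correlation between a heterogeneity marker and trisomy rates
#'
#' E.g. percentage of major clone against per-patient trisomy-18/-10 rates;
#' high aneuploidy rates go with low PMC (high clonal heterogeneity), so the
#' expected association is negative.
#'
#' @param marker Numeric per-patient marker (e.g. PMC).
#' @param feature Numeric per-patient feature (e.g. %+18).
#' @param method "spearman" (default; robust on the bounded percentage
#'   scale) or "pearson".
#' @return List with `estimate`, `p_value`, `method`.
#' @export
corr_marker_vs_feature <- function(marker, feature,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (stats::sd(marker) == 0 || stats::sd(feature) == 0)
    stop("constant input; correlation undefined")
  ct <- suppressWarnings(stats::cor.test(marker, feature, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, method = method)
}
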