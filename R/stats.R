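# Group statistics: mixed-effects tissue contrast, FDR adjustment, extent of
# resection, simple linear regression, Kaplan-Meier and log-rank.

#' Mixed-effects tissue contrast on channel-level HGp
#'
#' Fits, by REML, a linear mixed model with tissue (tumour vs non-tumour) as
#' a fixed effect and a random intercept per participant, and reports the
#' Wald F-test for the tissue effect (Satterthwaite denominator df).
#'
#' @param table data.frame with numeric `hgp`, factor-like `tissue_label`
#'   (`non_tumour` is the reference level) and `participant`.
#' @param pooling `"channel"` (one row per channel, default) or
#'   `"participant"` (average channels within participant x tissue first).
#' @return an `lme_result`: `fixed_effect_estimate`, `standard_error`,
#'   `F_stat`, `df_num`, `df_den`, `p_value`,
#'   `participant_random_intercept_sd`, `residual_sd`.
#' @export
fit_lme_tissue <- function(table, pooling = c("channel", "participant")) {
  pooling <- match.arg(pooling)
  assert_fields(table, c("hgp", "tissue_label", "participant"), "table")
  if (length(unique(table$tissue_label)) < 2) {
    stop("need both tissue labels present")
  }
  if (length(unique(table$participant)) < 2) {
    stop("need at least 2 participants")
  }
  if (pooling == "participant") {
    table <- aggregate(hgp ~ tissue_label + participant, table, mean)
  }
  table$tissue_label <- stats::relevel(factor(table$tissue_label),
                                       ref = "non_tumour")
  fit <- lmerTest::lmer(hgp ~ tissue_label + (1 | participant), data = table,
                        REML = TRUE)
  sm <- summary(fit)
  an <- anova(fit)  # Satterthwaite F test for the fixed effect
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fixed_effect_estimate = unname(sm$coefficients[2, "Estimate"]),
    standard_error = unname(sm$coefficients[2, "Std. Error"]),
    F_stat = an[1, "F value"],
    df_num = an[1, "NumDF"],
    df_den = an[1, "DenDF"],
    p_value = an[1, "Pr(>F)"],
    participant_random_intercept_sd = vc$sdcor[vc$grp == "participant"],
    residual_sd = vc$sdcor[vc$grp == "Residual"]
  ), class = "lme_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; order-preserving and bounded by 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Volumetric extent of resection
#'
#' `(pre - post) / pre x 100` percent; resections cannot add volume, so
#' `post > pre` is an error.
#'
#' @param pre_volume pre-operative tumour volume, cm^3, `> 0`.
#' @param post_volume post-operative tumour volume, cm^3.
#' @return percentage in `[0, 100]`.
#' @export
extent_of_resection <- function(pre_volume, post_volume) {
  if (any(pre_volume <= 0)) stop("pre-operative volume must be positive")
  if (any(post_volume < 0) || any(post_volume > pre_volume)) {
    stop("post-operative volume must lie in [0, pre_volume]")
  }
  (pre_volume - post_volume) / pre_volume * 100
}

#' Ordinary least squares with a two-sided slope test
#'
#' @param x predictor (non-constant).
#' @param y response.
#' @return a `regression_result`: `slope`, `intercept`, `r_squared`,
#'   `p_value` (two-sided slope test), `n`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0) stop("constant predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(x)),
            class = "regression_result")
}

#' Kaplan-Meier curves with a two-tailed log-rank test
#'
#' Product-limit estimator per group; the median is the earliest time at
#' which survival drops to 0.5 or below (`NA` = not reached). The log-rank
#' chi-square and two-tailed p-value compare the groups; with
#' `reverse_km = TRUE` the median follow-up (reverse Kaplan-Meier, censoring
#' as the event) is also reported.
#'
#' @param cohort data.frame with `time_weeks`, `event` (1 = death) and a
#'   group column.
#' @param group name of the group column, default `"group"`.
#' @param reverse_km also estimate median follow-up.
#' @return a `km_result`: per-group step functions (`time`, `surv`),
#'   `median`, `logrank_chisq`, `logrank_df`, `p_value`,
#'   `median_followup` (when requested).
#' @export
km_logrank <- function(cohort, group = "group", reverse_km = FALSE) {
  assert_fields(cohort, c("time_weeks", "event", group), "cohort")
  if (any(cohort$time_weeks <= 0)) stop("survival times must be positive")
  g <- factor(cohort[[group]])
  if (any(table(g) == 0)) stop("empty group")
  sf <- survival::survfit(survival::Surv(time_weeks, event) ~ g, data = cohort)
  strata <- if (is.null(sf$strata)) {
    setNames(list(seq_along(sf$time)), levels(g)[1])
  } else {
    idx <- split(seq_along(sf$time),
                 rep(seq_along(sf$strata), sf$strata))
    names(idx) <- sub("^g=", "", names(sf$strata))
    idx
  }
  curves <- lapply(strata, function(i) {
    data.frame(time = sf$time[i], surv = sf$surv[i],
               n_risk = sf$n.risk[i], n_event = sf$n.event[i])
  })
  medians <- vapply(curves, function(cv) {
    hit <- which(cv$surv <= 0.5)
    if (length(hit)) cv$time[min(hit)] else NA_real_
  }, numeric(1))

  p <- NA_real_; chisq <- NA_real_; df <- NA_integer_
  if (nlevels(g) >= 2) {
    if (sum(cohort$event) < 1) stop("log-rank needs at least one event")
    sd_ <- survival::survdiff(survival::Surv(time_weeks, event) ~ g,
                              data = cohort)
    chisq <- sd_$chisq
    df <- length(sd_$n) - 1L
    p <- pchisq(chisq, df, lower.tail = FALSE)
  }
  out <- list(curves = curves, median = medians, logrank_chisq = chisq,
              logrank_df = df, p_value = p)
  if (reverse_km) {
    rev <- cohort
    rev$event <- 1 - rev$event
    rf <- survival::survfit(survival::Surv(time_weeks, event) ~ 1, data = rev)
    hit <- which(rf$surv <= 0.5)
    out$median_followup <- if (length(hit)) rf$time[min(hit)] else NA_real_
  }
  structure(out, class = "km_result")
}
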