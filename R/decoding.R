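# Leave-one-participant-out (LOPO) decoding of word-frequency condition from
# high-gamma features, with exact binomial and normal-approximation
# significance tests.

#' Build a decoding feature matrix from ERSP epochs
#'
#' Flattens the per-trial z-scored high-gamma envelope inside a window around
#' speech onset into one row per trial (channels x time bins).
#'
#' @param ersp an `ersp_set` from [compute_ersp()].
#' @param participant participant id to attach to every trial.
#' @param window_s feature window relative to onset, s (default
#'   `c(-0.5, 0.5)`).
#' @return data.frame with `group`, `label` and numeric feature columns.
#' @export
ersp_features <- function(ersp, participant, window_s = c(-0.5, 0.5)) {
  stopifnot(inherits(ersp, "ersp_set"))
  n_t <- dim(ersp$values)[3]
  onset <- n_t / 2
  idx <- seq(floor(onset + window_s[1] * ersp$fs) + 1,
             min(n_t, ceiling(onset + window_s[2] * ersp$fs)))
  feats <- t(apply(ersp$values[, , idx, drop = FALSE], 1, as.vector))
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  cbind(data.frame(group = participant, label = ersp$trials$condition),
        as.data.frame(feats))
}

#' Leave-one-participant-out decoding with l2-regularised logistic regression
#'
#' For each participant, trains an l2-penalised (ridge) logistic regression
#' classifier (inverse regularisation strength `cost`, i.e. C = 1 by default)
#' on all other participants' trials and scores the held-out participant.
#' Features are standardised per fold using training-fold statistics only.
#'
#' @param features data.frame with `group` (participant id), `label`
#'   (two classes) and numeric feature columns.
#' @param cost inverse regularisation strength, default 1.
#' @return a `decode_result`: `per_fold_accuracy`, `mean_accuracy`,
#'   `n_test_trials`, `n_correct`, `p_value` (exact binomial, primary),
#'   `p_value_z` (normal approximation), `single_class_folds`.
#' @export
decode_lopo <- function(features, cost = 1) {
  assert_fields(features, c("group", "label"), "features")
  feat_cols <- setdiff(names(features), c("group", "label"))
  X <- as.matrix(features[, feat_cols, drop = FALSE])
  if (anyNA(X)) stop("features contain missing values")
  y <- factor(features$label)
  if (nlevels(y) != 2) stop("need exactly 2 classes")
  groups <- unique(features$group)
  if (length(groups) < 2) stop("need at least 2 participants for LOPO")

  per_fold <- numeric(length(groups))
  n_correct <- 0L
  n_total <- 0L
  flagged <- character(0)
  for (g in seq_along(groups)) {
    test <- features$group == groups[g]
    if (length(unique(y[!test])) < 2) {
      stop("training folds must contain both classes")
    }
    mu <- colMeans(X[!test, , drop = FALSE])
    sdev <- apply(X[!test, , drop = FALSE], 2, sd)
    sdev[sdev == 0] <- 1
    Xtr <- sweep(sweep(X[!test, , drop = FALSE], 2, mu), 2, sdev, "/")
    Xte <- sweep(sweep(X[test, , drop = FALSE], 2, mu), 2, sdev, "/")
    # ridge logistic regression; glmnet's lambda = 1 / (n_train * cost)
    # matches the "cost of 1" (C) parameterisation of the l2 penalty
    fit <- glmnet::glmnet(Xtr, y[!test], family = "binomial", alpha = 0,
                          lambda = 1 / (nrow(Xtr) * cost),
                          standardize = FALSE, thresh = 1e-8)
    pred <- predict(fit, Xte, type = "class")
    correct <- pred == as.character(y[test])
    per_fold[g] <- mean(correct)
    n_correct <- n_correct + sum(correct)
    n_total <- n_total + length(correct)
    if (length(unique(y[test])) < 2) flagged <- c(flagged, as.character(groups[g]))
  }
  sig <- accuracy_significance(n_correct, n_total)
  structure(list(per_fold_accuracy = setNames(per_fold, groups),
                 mean_accuracy = mean(per_fold),
                 n_test_trials = n_total, n_correct = n_correct,
                 p_value = sig$p_exact, p_value_z = sig$p_normal,
                 single_class_folds = flagged),
            class = "decode_result")
}

#' Significance of a classification accuracy against chance
#'
#' Tests `n_correct` successes out of `n_total` against a binomial
#' distribution at the chance rate. Returns both the exact upper-tail
#' binomial probability `P(X >= n_correct)` (primary) and the one-sided
#' normal-approximation Z-test.
#'
#' @param n_correct,n_total counts.
#' @param chance chance accuracy, default 0.5.
#' @return list with `p_exact` (primary), `p_normal`, `z`, and `primary`
#'   naming the exact test.
#' @export
accuracy_significance <- function(n_correct, n_total, chance = 0.5) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_correct < 0 || n_correct > n_total) stop("need 0 <= n_correct <= n_total")
  p_exact <- pbinom(n_correct - 1, n_total, chance, lower.tail = FALSE)
  z <- (n_correct / n_total - chance) / sqrt(chance * (1 - chance) / n_total)
  list(p_exact = p_exact, p_normal = pnorm(z, lower.tail = FALSE), z = z,
       primary = "exact_binomial")
}
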