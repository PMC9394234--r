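#' Random-forest Gini importance under leave-one-out cross-validation
#'
#' For each held-out sample a forest is trained on the remaining samples and
#' per-chromosome Gini importances (mean decrease in node impurity) are
#' collected; chromosomes are ranked by their median importance across
#' folds. This ranks which chromosome-gain rates are most informative for
#' separating favorable from unfavorable outcome.
#'
#' @param features Numeric matrix, rows = samples, columns = chromosome gain
#'   percentages (column names = chromosome labels).
#' @param labels Outcome factor with two levels (e.g. CR/REL), one per
#'   sample.
#' @param ntree Trees per forest (default 500).
#' @param seed Integer seed; each fold uses `seed + fold`.
#' @return List with `importance` (folds x features matrix), `median`
#'   (named, per feature), `ranking` (feature names, most important first).
#' @export
gini_importance_loocv <- function(features, labels, ntree = 500, seed = 1) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need samples from both outcome classes")
  n <- nrow(features)
  imp <- matrix(NA_real_, n, ncol(features),
                dimnames = list(NULL, colnames(features)))
  for (i in seq_len(n)) {
    if (nlevels(droplevels(labels[-i])) < 2)
      stop("a fold lost one outcome class entirely; need >= 2 per class")
    set.seed(seed + i)
    fit <- randomForest::randomForest(features[-i, , drop = FALSE],
                                      droplevels(labels[-i]), ntree = ntree,
                                      importance = FALSE)
    imp[i, ] <- fit$importance[, "MeanDecreaseGini"]
  }
  med <- apply(imp, 2, stats::median)
  list(importance = imp, median = med,
       ranking = names(sort(med, decreasing = TRUE)))
}

#' Fit a two-threshold (depth-2) pair rule
#'
#' The rule family is the one used for outcome prediction from trisomy
#' rates: a sample is called favorable iff its first feature exceeds a
#' threshold AND its second feature exceeds a second threshold; otherwise
#' unfavorable. Thresholds are fitted by exhaustive search over a grid,
#' maximizing training accuracy; among ties the componentwise median of the
#' maximizing grid cells is taken, so the fitted thresholds sit centrally in
#' the optimal plateau.
#'
#' @param f1,f2 Numeric feature vectors (percent scale).
#' @param y Labels; `positive` names the favorable level.
#' @param grid Candidate thresholds (default 0 to 100 by 2.5).
#' @param positive Label value called when both features exceed their
#'   thresholds.
#' @return List with `t1`, `t2`, `accuracy` (training), `positive`.
#' @export
fit_pair_rule <- function(f1, f2, y, grid = c(0, seq(2.5, 97.5, 2.5), 100),
                          positive = "CR") {
  pos <- y == positive
  acc <- pair_rule_accuracy(f1, f2, pos, grid)
  best <- which(acc == max(acc), arr.ind = TRUE)
  t1 <- grid[round(stats::median(best[, 1]))]
  i1 <- round(stats::median(best[, 1]))
  sub <- best[best[, 1] == i1, , drop = FALSE]
  if (!nrow(sub)) sub <- best
  t2 <- grid[round(stats::median(sub[, 2]))]
  list(t1 = t1, t2 = t2, accuracy = max(acc) / length(f1),
       positive = positive)
}

# count of correct calls for every (t1, t2) grid cell; rule: positive iff
# f1 > t1 & f2 > t2
pair_rule_accuracy <- function(f1, f2, pos, grid) {
  U <- outer(f1, grid, ">")          # n x G
  V <- outer(f2, grid, ">")
  both_pos <- crossprod(U[pos, , drop = FALSE], V[pos, , drop = FALSE])
  both_neg <- crossprod(U[!pos, , drop = FALSE], V[!pos, , drop = FALSE])
  both_pos + (sum(!pos) - both_neg)
}

#' Evaluate candidate chromosome pairs by leave-one-out accuracy
#'
#' For each candidate pair a two-threshold rule is fitted on each
#' leave-one-out training set and scored on the held-out sample.
#'
#' @param features Samples x chromosomes matrix of gain percentages.
#' @param labels Outcome labels.
#' @param pairs List of length-2 character vectors of column names (default:
#'   the three pairs carried forward in the discovery analysis).
#' @param grid Candidate thresholds.
#' @param positive Favorable label.
#' @return Data frame per pair: `f1`, `f2`, `t1`, `t2` (full-data fit),
#'   `train_accuracy`, `loocv_accuracy`; ordered by decreasing LOOCV
#'   accuracy.
#' @export
evaluate_pair_rules <- function(features, labels,
                                pairs = list(c("21", "14"), c("21", "10"),
                                             c("18", "10")),
                                grid = c(0, seq(2.5, 97.5, 2.5), 100),
                                positive = "CR") {
  features <- as.matrix(features)
  n <- nrow(features)
  res <- lapply(pairs, function(pr) {
    f1 <- features[, pr[1]]; f2 <- features[, pr[2]]
    full <- fit_pair_rule(f1, f2, labels, grid, positive)
    correct <- logical(n)
    for (i in seq_len(n)) {
      fit_i <- fit_pair_rule(f1[-i], f2[-i], labels[-i], grid, positive)
      call_i <- if (f1[i] > fit_i$t1 && f2[i] > fit_i$t2) positive else
        setdiff(unique(labels), positive)[1]
      correct[i] <- call_i == labels[i]
    }
    data.frame(f1 = pr[1], f2 = pr[2], t1 = full$t1, t2 = full$t2,
               train_accuracy = full$accuracy, loocv_accuracy = mean(correct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-out$loocv_accuracy), ]
}

#' The chromosome-18 / chromosome-10 two-step risk rule
#'
#' Samples are first classified by their percentage of chromosome-18 gains
#' against a 40% threshold: below it, the call is unfavorable. Samples above
#' are refined by the percentage of chromosome-10 gains against a second 40%
#' threshold: below it unfavorable, above it favorable. "Above" is strictly
#' greater by default (a sample exactly at a threshold is unfavorable).
#'
#' @param profile A `TrisomyProfile`, or a named numeric vector containing
#'   elements "18" and "10" (gain percentages).
#' @param threshold18,threshold10 Rule thresholds in (0, 100).
#' @return List of class `RiskCall`: `label` ("favorable"/"unfavorable"),
#'   `trace` (which step decided), `features`.
#' @examples
#' chr18_chr10_rule(c("18" = 80, "10" = 80))$label   # favorable
#' chr18_chr10_rule(c("18" = 30, "10" = 90))$trace   # decided at step 1
#' @export
chr18_chr10_rule <- function(profile, threshold18 = 40, threshold10 = 40) {
  stopifnot(threshold18 > 0, threshold18 < 100,
            threshold10 > 0, threshold10 < 100)
  if (inherits(profile, "TrisomyProfile")) {
    r <- profile$rates
    feats <- c("18" = r$gain_pct[r$chromosome == "18"],
               "10" = r$gain_pct[r$chromosome == "10"])
  } else {
    feats <- profile[c("18", "10")]
  }
  if (anyNA(feats) || length(feats) != 2)
    stop("profile must provide gain percentages for chromosomes 18 and 10")
  if (feats[["18"]] <= threshold18) {
    call <- list(label = "unfavorable",
                 trace = "chr18 gain % at or below threshold (step 1)")
  } else if (feats[["10"]] <= threshold10) {
    call <- list(label = "unfavorable",
                 trace = "chr10 gain % at or below threshold (step 2)")
  } else {
    call <- list(label = "favorable",
                 trace = "both gain percentages above thresholds")
  }
  structure(c(call, list(features = feats)), class = "RiskCall")
}

#' @export
print.RiskCall <- function(x, ...) {
  cat("RiskCall:", x$label, "-", x$trace, "\n")
  invisible(x)
}

#' Confusion counts and accuracies of risk calls against outcomes
#'
#' @param calls Character vector of "favorable"/"unfavorable" calls.
#' @param outcomes True outcomes, "CR" (favorable) / "REL" (unfavorable), or
#'   already on the favorable/unfavorable scale.
#' @return List with `confusion` (2x2 table), `overall`, `favorable`,
#'   `unfavorable` accuracies (fractions).
#' @export
classification_report <- function(calls, outcomes) {
  if (length(calls) != length(outcomes))
    stop("calls and outcomes differ in length")
  truth <- ifelse(outcomes %in% c("CR", "favorable"), "favorable",
                  "unfavorable")
  lv <- c("favorable", "unfavorable")
  conf <- table(call = factor(calls, lv), truth = factor(truth, lv))
  list(confusion = conf,
       overall = sum(diag(conf)) / sum(conf),
       favorable = if (sum(conf[, 1])) conf[1, 1] / sum(conf[, 1]) else NA,
       unfavorable = if (sum(conf[, 2])) conf[2, 2] / sum(conf[, 2]) else NA)
}

#' Noise-injection stress test of a threshold classifier
#'
#' For every noise level L in the grid, uniform deviates u ~ U(0, L) with
#' independent random signs are added to every feature of every sample, the
#' perturbed cohort is reclassified, and this is repeated `reps` times. The
#' output reports, per level, the mean number of correctly and incorrectly
#' classified samples across repetitions. Perturbed percentages are clipped
#' to [0, 100]. Level 0 reproduces the noiseless confusion exactly.
#'
#' @param features Samples x features matrix (percent scale). Must contain
#'   the columns the classifier reads.
#' @param labels True outcomes ("CR"/"REL" or favorable/unfavorable).
#' @param classify Function(feature_row) -> "favorable"/"unfavorable";
#'   default the chr18-chr10 rule.
#' @param levels Noise-level grid (default 0 to 30 by 5).
#' @param reps Repetitions per level (default 100).
#' @param seed Integer seed; results are exactly reproducible given
#'   (seed, levels, reps).
#' @return Object of class `StressTestResult`: data frame per level with
#'   `level`, `mean_correct`, `mean_misclassified`, `sd_correct`; attributes
#'   `reps`, `seed`, `n`.
#' @export
stress_test <- function(features, labels,
                        classify = function(row) chr18_chr10_rule(row)$label,
                        levels = seq(0, 30, by = 5), reps = 100, seed = 1) {
  if (any(levels < 0)) stop("noise levels must be non-negative")
  features <- as.matrix(features)
  n <- nrow(features)
  truth <- ifelse(labels %in% c("CR", "favorable"), "favorable",
                  "unfavorable")
  set.seed(seed)
  out <- lapply(levels, function(L) {
    ncorrect <- numeric(reps)
    for (r in seq_len(reps)) {
      u <- matrix(stats::runif(length(features), 0, L), n)
      s <- matrix(sample(c(-1, 1), length(features), replace = TRUE), n)
      pert <- pmin(pmax(features + s * u, 0), 100)
      colnames(pert) <- colnames(features)
      calls <- apply(pert, 1, classify)
      ncorrect[r] <- sum(calls == truth)
    }
    data.frame(level = L, mean_correct = mean(ncorrect),
               mean_misclassified = n - mean(ncorrect),
               sd_correct = stats::sd(ncorrect))
  })
  res <- do.call(rbind, out)
  structure(res, reps = reps, seed = seed, n = n,
            class = c("StressTestResult", "data.frame"))
}
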