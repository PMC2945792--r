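#' Spearman rank correlation between predictions and observations
#'
#' Rank correlation with average ranks for ties.  A constant vector has no
#' ranking, so the correlation is undefined and returned as \code{NA} with
#' a warning.
#'
#' @param pred,obs paired numeric vectors (length >= 2).
#' @return rho in [-1, 1], or \code{NA}.
#' @export
spearman_rho <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 2)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(pred, obs, method = "spearman")
}

#' Quantile-labeled ROC curve and AUC
#'
#' Labels the most downregulated fraction of observations as true
#' positives and the least downregulated fraction as true negatives
#' (middle discarded), then sweeps score thresholds treating more-negative
#' scores as stronger positive predictions.  AUC by the trapezoid rule.
#' Alternatively labels can be fixed by a Z-score threshold
#' (\code{labels} argument) or passed directly.
#'
#' @param scores prediction scores (more negative = stronger prediction of
#'   downregulation).
#' @param obs observed log expression changes (used for quantile labeling),
#'   or ignored when \code{labels} is given.
#' @param top_frac fraction labeled positive (most negative \code{obs}) and
#'   negative (most positive \code{obs}).
#' @param labels optional logical/0-1 vector of true labels overriding the
#'   quantile rule.
#' @return list with \code{curve} (data.frame \code{fpr}, \code{tpr}),
#'   \code{auc}, and the label vector used.
#' @export
quantile_roc <- function(scores, obs = NULL, top_frac = 0.2, labels = NULL) {
  if (is.null(labels)) {
    stopifnot(!is.null(obs), length(scores) == length(obs))
    lo <- stats::quantile(obs, top_frac)
    hi <- stats::quantile(obs, 1 - top_frac)
    keep <- obs <= lo | obs >= hi
    labels <- obs[keep] <= lo
    scores <- scores[keep]
  } else {
    labels <- as.logical(labels)
  }
  if (!any(labels) || all(labels)) stop("one label class is empty")
  # more negative score = stronger prediction: rank by -score descending
  s <- -scores
  ord <- order(s, decreasing = TRUE)
  lab <- labels[ord]
  sv <- s[ord]
  # pool tied thresholds
  grp <- cumsum(!duplicated(sv))
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(lab))
  fpr <- c(0, fp[last] / sum(!lab))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc, labels = labels)
}

#' Detection-rate curves under conservation filtering
#'
#' Defines the set of truly downregulated genes as the most downregulated
#' quantile of the observations, then, for each conservation threshold,
#' ranks the genes whose site passes the threshold by prediction score and
#' accumulates how many downregulated genes are detected as predictions
#' are admitted one by one.  Curves are scaled by the plateau of the
#' unfiltered curve, so a filter that discards effective but unconserved
#' sites plateaus below 1.
#'
#' @param scores per-gene prediction scores (more negative = stronger).
#' @param obs per-gene observed log expression changes.
#' @param conservation per-gene site conservation values in [0, 1].
#' @param thresholds conservation thresholds (0 = no filter).
#' @param top_frac fraction of genes labeled downregulated (default top 5%).
#' @return list of data.frames keyed by threshold, each with
#'   \code{n_predictions} and \code{detection_rate}; attribute
#'   \code{"max_detected"} carries the unfiltered plateau count.
#' @export
detection_rate_curve <- function(scores, obs, conservation,
                                 thresholds = c(0, 0.5, 0.8),
                                 top_frac = 0.05) {
  stopifnot(length(scores) == length(obs),
            length(scores) == length(conservation))
  down <- obs <= stats::quantile(obs, top_frac)
  max_detected <- sum(down)
  out <- list()
  for (th in thresholds) {
    pass <- conservation >= th
    if (!any(pass)) {
      warning(sprintf("threshold %g removes all sites", th), call. = FALSE)
      out[[as.character(th)]] <-
        data.frame(n_predictions = 0L, detection_rate = 0)
      next
    }
    ord <- order(scores[pass])
    hits <- cumsum(down[pass][ord])
    out[[as.character(th)]] <- data.frame(
      n_predictions = seq_along(hits),
      detection_rate = hits / max_detected)
  }
  attr(out, "max_detected") <- max_detected
  out
}

#' One-sided CDF-shift test between true and false site scores
#'
#' One-sided two-sample Kolmogorov-Smirnov test of whether the true-site
#' score distribution is shifted toward more negative values than the
#' false-site distribution (true sites predicted to drive stronger
#' downregulation).
#'
#' @param scores_true,scores_false score samples.
#' @return list with \code{statistic} (D) and \code{p.value}.
#' @export
cdf_shift_test <- function(scores_true, scores_false) {
  stopifnot(length(scores_true) > 0, length(scores_false) > 0)
  # shifted to more negative values <=> CDF of true lies above CDF of false
  k <- suppressWarnings(
    stats::ks.test(scores_true, scores_false, alternative = "greater"))
  list(statistic = unname(k$statistic), p.value = unname(k$p.value))
}

#' Precision and sensitivity at a score cutoff, with permutation p-value
#'
#' Sites with score at or below the cutoff are called positive predictions;
#' precision = TP/(TP+FP), sensitivity = TP/(TP+FN).  The permutation
#' p-value shuffles the labels and counts how often permuted precision
#' reaches the observed one.
#'
#' @param scores site scores (more negative = stronger prediction).
#' @param labels logical/0-1 true-site labels.
#' @param cutoff score cutoff (default -0.1).
#' @param n_perm number of label permutations (0 skips the test).
#' @return list with \code{precision}, \code{sensitivity},
#'   \code{n_called}, and \code{p_perm}.
#' @export
precision_sensitivity_at <- function(scores, labels, cutoff = -0.1,
                                     n_perm = 10000) {
  labels <- as.logical(labels)
  called <- scores <= cutoff
  if (!any(called)) {
    warning("no site at or below cutoff; precision undefined", call. = FALSE)
    return(list(precision = NA_real_, sensitivity = 0,
                n_called = 0L, p_perm = NA_real_))
  }
  prec <- mean(labels[called])
  sens <- sum(labels & called) / sum(labels)
  p <- NA_real_
  if (n_perm > 0) {
    perm <- replicate(n_perm, mean(sample(labels)[called]))
    p <- (1 + sum(perm >= prec)) / (n_perm + 1)
  }
  list(precision = prec, sensitivity = sens,
       n_called = sum(called), p_perm = p)
}

#' Seed-class composition across score bins
#'
#' Splits sites into equal-count score bins (most negative first) and
#' tabulates the proportion of each seed class per bin; rows sum to 1.
#'
#' @param scores site scores.
#' @param seed_classes character vector of classes per site.
#' @param n_bins number of equal-count bins (must not exceed the number of
#'   sites).
#' @return matrix of proportions, bins x classes.
#' @export
seed_class_distribution <- function(scores, seed_classes, n_bins = 5) {
  stopifnot(length(scores) == length(seed_classes))
  if (n_bins > length(scores)) stop("more bins than sites")
  bin <- cut(rank(scores, ties.method = "first"), n_bins, labels = FALSE)
  tab <- table(bin, seed_classes)
  prop.table(tab, margin = 1)
}

#' Paired comparison of two methods across experiments
#'
#' Wilcoxon signed-rank test on paired per-experiment metrics (for example
#' per-experiment Spearman correlations of two scoring methods).
#'
#' @param metric_a,metric_b paired per-experiment metrics.
#' @param alternative passed to \code{wilcox.test} (default: method A
#'   yields greater metrics).
#' @return list with \code{p.value}, \code{n} and \code{wins} (experiments
#'   where A beats B).
#' @export
compare_methods <- function(metric_a, metric_b, alternative = "greater") {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 6)
  w <- stats::wilcox.test(metric_a, metric_b, paired = TRUE,
                          alternative = alternative, exact = TRUE)
  list(p.value = w$p.value, n = length(metric_a),
       wins = sum(metric_a > metric_b))
}

#' Per-experiment evaluation report
#'
#' Convenience wrapper computing the rank correlation and the
#' quantile-labeled ROC for each experiment in a long table of paired
#' predictions and observations.  For inhibition experiments (expression
#' rises when the microRNA is blocked) the observed changes are
#' sign-flipped before ranking so that all experiments share the
#' "more negative = more regulated" convention.
#'
#' @param scores,obs paired vectors.
#' @param experiment_id experiment label per pair.
#' @param inhibition logical per pair (or per experiment); observations are
#'   negated where TRUE.
#' @param top_frac quantile fraction for ROC labeling.
#' @return data.frame with one row per experiment: \code{experiment_id},
#'   \code{n}, \code{rho}, \code{auc}.
#' @export
evaluation_report <- function(scores, obs, experiment_id,
                              inhibition = FALSE, top_frac = 0.2) {
  if (length(inhibition) == 1) inhibition <- rep(inhibition, length(obs))
  obs <- ifelse(inhibition, -obs, obs)
  ids <- unique(experiment_id)
  rows <- lapply(ids, function(ex) {
    i <- experiment_id == ex
    roc <- tryCatch(quantile_roc(scores[i], obs[i], top_frac),
                    error = function(e) list(auc = NA_real_))
    data.frame(experiment_id = ex, n = sum(i),
               rho = spearman_rho(scores[i], obs[i]), auc = roc$auc)
  })
  do.call(rbind, rows)
}
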