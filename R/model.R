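#' Sigmoid transfer function for score calibration
#'
#' \code{t(x) = -c / (1 + exp(a * (-x) + b))}: a strictly monotone map of
#' raw regression scores into the interval \code{(-c, 0)}, so that
#' calibrated site scores can be interpreted on a common downregulation
#' scale and added across sites of a gene.
#'
#' @param x raw scores.
#' @param a,b,c sigmoid parameters (\code{c > 0}).
#' @return transformed scores in \code{(-c, 0)}.
#' @export
sigmoid_transform <- function(x, a, b, c) {
  -c / (1 + exp(a * (-x) + b))
}

#' Fit the sigmoid calibration to raw scores
#'
#' Nonlinear least squares of \code{\link{sigmoid_transform}} against the
#' observed (Z-transformed) log expression changes.  Three documented
#' starting points are tried — \code{(a, b, c) = (1, 0, r)},
#' \code{(-1, 0, r)} and \code{(0.25, 0, 2r)} with \code{r} the range of
#' \code{y} — covering both monotonicity branches, and the converged fit
#' with the smallest residual sum of squares is kept; if none converges an
#' error is raised.
#'
#' @param scores raw (uncalibrated) prediction scores, typically assembled
#'   out-of-fold from cross-validation.
#' @param y observed responses.
#' @param tol convergence tolerance passed to the optimizer.
#' @return object of class \code{"sigmoid_calibration"}: list with
#'   \code{a}, \code{b}, \code{c}.
#' @export
fit_sigmoid <- function(scores, y, tol = 1e-8) {
  r <- max(diff(range(y)), 1e-6)
  starts <- list(c(a = 1, b = 0, c = r),
                 c(a = -1, b = 0, c = r),
                 c(a = 0.25, b = 0, c = 2 * r),
                 c(a = -0.25, b = 0, c = 2 * r))
  dat <- data.frame(x = scores, y = y)
  # the transform is increasing iff a < 0; when the response truly rises
  # with the score the increasing branch is the meaningful calibration, so
  # near-ties in residual error are broken toward the observed association
  assoc <- sign(stats::cor(scores, y, method = "spearman"))
  cands <- list()
  for (s in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(y ~ -cc / (1 + exp(a * (-x) + b)), data = dat,
                        start = list(a = s[["a"]], b = s[["b"]], cc = s[["c"]]),
                        control = minpack.lm::nls.lm.control(
                          ftol = tol, ptol = tol, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(cand)) next
    p <- stats::coef(cand)
    if (p[["cc"]] <= 0) next                    # outputs must lie in (-c, 0)
    cands[[length(cands) + 1]] <- list(
      p = p, rss = sum(stats::residuals(cand)^2),
      concordant = (assoc == 0) || (sign(-p[["a"]]) == assoc))
  }
  if (!length(cands) || !any(vapply(cands, `[[`, logical(1), "concordant"))) {
    # deterministic coarse grid fallback: slopes on the score scale, centres
    # at score quantiles, amplitude solved in closed form; the best grid
    # point is polished by the optimizer when possible
    sx <- max(stats::sd(scores), 1e-8)
    grid_best <- NULL
    grid_rss <- Inf
    for (a0 in c(-8, -4, -2, -1, -0.5, 0.5, 1, 2, 4, 8) / sx) {
      for (x0 in stats::quantile(scores, seq(0.1, 0.9, by = 0.2))) {
        g <- 1 / (1 + exp(a0 * (-scores) + a0 * x0))
        cc0 <- -sum(g * y) / sum(g * g)
        if (!is.finite(cc0) || cc0 <= 0) next
        rss <- sum((y + cc0 * g)^2)
        if (rss < grid_rss) {
          grid_rss <- rss
          grid_best <- c(a = a0, b = a0 * x0, cc = cc0)
        }
      }
    }
    if (!is.null(grid_best)) {
      polish <- tryCatch(
        minpack.lm::nlsLM(y ~ -cc / (1 + exp(a * (-x) + b)), data = dat,
                          start = as.list(grid_best),
                          control = minpack.lm::nls.lm.control(
                            ftol = tol, ptol = tol, maxiter = 500)),
        error = function(e) NULL)
      p <- if (!is.null(polish)) stats::coef(polish) else grid_best
      if (p[["cc"]] > 0)
        cands[[length(cands) + 1]] <- list(
          p = p,
          rss = sum((y - sigmoid_transform(scores, p[["a"]], p[["b"]],
                                           p[["cc"]]))^2),
          concordant = (assoc == 0) || (sign(-p[["a"]]) == assoc))
    }
  }
  if (!length(cands))
    stop("sigmoid calibration failed to converge from all starting points")
  conc <- Filter(function(cd) cd$concordant, cands)
  pool <- if (length(conc)) conc else cands
  best <- pool[[which.min(vapply(pool, `[[`, numeric(1), "rss"))]]
  p <- best$p
  structure(list(a = unname(p["a"]), b = unname(p["b"]),
                 c = unname(p["cc"])), class = "sigmoid_calibration")
}

#' @export
print.sigmoid_calibration <- function(x, ...) {
  cat(sprintf("sigmoid calibration t(x) = -c/(1+exp(a(-x)+b)): a=%.4g b=%.4g c=%.4g\n",
              x$a, x$b, x$c))
  invisible(x)
}

# deterministic polynomial hash -> cross-validation fold per gene id
.fold_hash <- function(ids, folds, seed) {
  vapply(as.character(ids), function(g) {
    h <- seed %% 2147483647
    for (ch in utf8ToInt(g)) h <- (h * 31 + ch) %% 2147483647
    as.integer(h %% folds) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Train a linear nu-SVR on standardized features
#'
#' Thin wrapper around libsvm (via \pkg{e1071}) configured as in the
#' deployed scorer: nu support-vector regression with a linear kernel,
#' epsilon-insensitive loss with the tube width set by the nu mechanism,
#' \code{C = 0.1} and \code{nu = 0.5}.
#'
#' @param X standardized feature matrix.
#' @param y responses (Z-transformed log expression changes).
#' @param C,nu libsvm cost and nu parameters.
#' @return list with weight vector \code{w} (named by feature), bias
#'   \code{b}, hyperparameters, and support-vector diagnostics
#'   (\code{n_sv}, \code{n_bounded}).
#' @export
train_svr <- function(X, y, C = 0.1, nu = 0.5) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("NA in features or response")
  if (nrow(X) < ncol(X))
    warning("fewer examples than features; SVR weights may be unstable",
            call. = FALSE)
  if (stats::sd(y) == 0) {
    # degenerate no-signal case: libsvm returns an empty model
    w <- stats::setNames(rep(0, ncol(X)), colnames(X))
    return(list(w = w, b = y[1], C = C, nu = nu, n_sv = 0L, n_bounded = 0L))
  }
  fit <- e1071::svm(X, y, type = "nu-regression", kernel = "linear",
                    cost = C, nu = nu, scale = FALSE, fitted = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  names(w) <- colnames(X)
  list(w = w, b = -fit$rho, C = C, nu = nu,
       n_sv = fit$tot.nSV,
       n_bounded = sum(abs(fit$coefs) >= C - 1e-8))
}

#' Fit the mirSVR downregulation model
#'
#' The central fitting routine: Z-standardizes the site feature matrix,
#' trains a linear nu-SVR of the (per-experiment Z-transformed) log
#' expression change on the features, and calibrates the raw scores with a
#' sigmoid transfer function fitted by nonlinear regression on scores
#' assembled from k-fold cross-validation (each score predicted by a model
#' that never saw the gene).  The final SVR is retrained on all data and
#' deployed together with the scaler and the calibration.
#'
#' @param x numeric feature matrix, one row per single-site training gene,
#'   columns as in \code{\link{feature_names}} (any fixed feature set
#'   works; the order is frozen into the model).
#' @param y observed log expression changes, Z-transformed per experiment
#'   (see \code{\link{prepare_training_set}}).
#' @param C,nu libsvm hyperparameters (defaults 0.1 and 0.5).
#' @param calibrate fit the sigmoid transfer function (TRUE) or return an
#'   uncalibrated model.
#' @param folds number of cross-validation folds for calibration.
#' @param gene_id per-row gene identifiers; folds are assigned by a
#'   deterministic hash of the id so repeated runs use identical folds.
#' @param cv_seed integer mixed into the fold hash.
#' @param standardize fit a Z-score scaler on \code{x} (TRUE) or use
#'   \code{x} as-is.
#' @return object of class \code{"mirsvr"} with components \code{w},
#'   \code{b}, \code{scaler}, \code{calibration}, \code{fitted_raw},
#'   \code{fitted_cal}, \code{oof_raw} (out-of-fold raw scores) and
#'   metadata.
#' @seealso \code{\link{predict.mirsvr}}, \code{\link{score_sites}},
#'   \code{\link{write_mirsvr}}
#' @export
mirsvr <- function(x, y, C = 0.1, nu = 0.5, calibrate = TRUE, folds = 5,
                   gene_id = rownames(x), cv_seed = 1L, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (length(y) != nrow(x)) stop("length(y) must match nrow(x)")
  if (anyNA(x) || anyNA(y)) stop("NA in features or response")
  scaler <- NULL
  xs <- x
  if (standardize) {
    scaler <- fit_scaler(x)
    xs <- apply_scaler(scaler, x)
  }
  if (is.null(gene_id)) gene_id <- as.character(seq_len(nrow(xs)))

  calibration <- NULL
  oof <- NULL
  fold <- NULL
  if (calibrate) {
    if (nrow(xs) < folds * 2)
      stop("too few examples for ", folds, "-fold calibration")
    fold <- .fold_hash(gene_id, folds, cv_seed)
    oof <- numeric(nrow(xs))
    for (k in sort(unique(fold))) {
      part <- train_svr(xs[fold != k, , drop = FALSE], y[fold != k], C, nu)
      oof[fold == k] <- drop(xs[fold == k, , drop = FALSE] %*% part$w) + part$b
    }
    calibration <- fit_sigmoid(oof, y)
  }
  final <- train_svr(xs, y, C, nu)
  raw <- drop(xs %*% final$w) + final$b
  obj <- structure(list(
    w = final$w, b = final$b, C = C, nu = nu,
    n_sv = final$n_sv, n_bounded = final$n_bounded,
    scaler = scaler, calibration = calibration,
    features = colnames(xs), n = nrow(xs),
    fitted_raw = raw,
    fitted_cal = if (!is.null(calibration))
      sigmoid_transform(raw, calibration$a, calibration$b, calibration$c),
    residuals = y - raw, y = y,
    oof_raw = oof, fold = fold,
    call = match.call()), class = "mirsvr")
  obj
}

#' Predict downregulation scores for new sites
#'
#' @param object a fitted \code{"mirsvr"} model.
#' @param newdata feature matrix on the original (unstandardized) scale,
#'   containing at least the model's feature columns.
#' @param type \code{"calibrated"} for sigmoid-transformed scores (more
#'   negative = stronger predicted downregulation) or \code{"raw"} for the
#'   linear SVR output.
#' @param ... unused.
#' @return numeric vector of scores.
#' @export
predict.mirsvr <- function(object, newdata,
                           type = c("calibrated", "raw"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (is.null(colnames(X)) && ncol(X) == length(object$features))
    colnames(X) <- object$features
  miss <- setdiff(object$features, colnames(X))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  Xs <- if (is.null(object$scaler)) X[, object$features, drop = FALSE]
        else apply_scaler(object$scaler, X)
  raw <- drop(Xs %*% object$w) + object$b
  if (type == "raw") return(raw)
  if (is.null(object$calibration))
    stop("model has no sigmoid calibration; use type = \"raw\"")
  cal <- object$calibration
  sigmoid_transform(raw, cal$a, cal$b, cal$c)
}

#' @export
print.mirsvr <- function(x, ...) {
  cat(sprintf("mirSVR model: linear nu-SVR (C=%g, nu=%g) on %d features, n=%d\n",
              x$C, x$nu, length(x$w), x$n))
  if (!is.null(x$calibration))
    print(x$calibration)
  else cat("  (uncalibrated: raw scores only)\n")
  invisible(x)
}

#' @export
summary.mirsvr <- function(object, ...) {
  w <- sort(object$w)
  cat(sprintf("mirSVR model over %d features (n = %d training sites)\n",
              length(w), object$n))
  cat(sprintf("  support vectors: %d (%d at bound)\n",
              object$n_sv, object$n_bounded))
  cat(sprintf("  training residual sd: %.3f\n",
              sqrt(mean(object$residuals^2))))
  if (!is.null(object$calibration)) print(object$calibration)
  cat("strongest weights (most predictive of downregulation when negative):\n")
  show <- c(utils::head(w, 5), utils::tail(w, 5))
  print(round(show, 4))
  invisible(object)
}

#' @export
coef.mirsvr <- function(object, ...) {
  c(bias = object$b, object$w)
}

#' @export
fitted.mirsvr <- function(object, ...) {
  if (!is.null(object$fitted_cal)) object$fitted_cal else object$fitted_raw
}

#' @export
residuals.mirsvr <- function(object, ...) object$residuals

#' Simulate responses from a fitted mirSVR model
#'
#' Draws Gaussian responses around the model's raw fitted values with the
#' training residual standard deviation.
#'
#' @param object a fitted \code{"mirsvr"}.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with \code{nsim} columns.
#' @export
simulate.mirsvr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(mean(object$residuals^2))
  out <- as.data.frame(replicate(nsim,
    object$fitted_raw + stats::rnorm(object$n, 0, s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Calibration plot of a fitted mirSVR model
#'
#' Left: the fitted sigmoid transfer over the out-of-fold raw scores.
#' Right: binned mean observed expression change against binned mean
#' calibrated score (equal-count bins) — for a well-calibrated model the
#' points fall on a line.
#'
#' @param x a fitted \code{"mirsvr"} with calibration.
#' @param bins number of equal-count bins.
#' @param ... passed to \code{plot}.
#' @export
plot.mirsvr <- function(x, bins = 10, ...) {
  if (is.null(x$calibration)) stop("model has no calibration to plot")
  cal <- x$calibration
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ord <- order(x$oof_raw)
  graphics::plot(x$oof_raw[ord], x$y[ord], pch = 16, cex = 0.4,
                 col = "grey60", xlab = "raw SVR score",
                 ylab = "observed log expression change (Z)", ...)
  graphics::lines(x$oof_raw[ord],
                  sigmoid_transform(x$oof_raw[ord], cal$a, cal$b, cal$c),
                  col = "firebrick", lwd = 2)
  cal_scores <- sigmoid_transform(x$oof_raw, cal$a, cal$b, cal$c)
  q <- cut(rank(cal_scores, ties.method = "first"), bins, labels = FALSE)
  mx <- tapply(cal_scores, q, mean)
  my <- tapply(x$y, q, mean)
  graphics::plot(mx, my, pch = 16, xlab = "mean mirSVR score (bin)",
                 ylab = "mean observed change (bin)")
  graphics::abline(stats::lm(my ~ mx), col = "firebrick", lwd = 2)
  invisible(x)
}

# --- training-set assembly ---------------------------------------------------

#' Assemble the single-site training set from expression tables and sites
#'
#' Mirrors the transfection training design: per experiment, keep genes
#' whose control-transfection signal intensity is above the experiment
#' median (genes must be expressed for silencing to be observable), then
#' keep genes carrying exactly one target site for the transfected microRNA
#' under the chosen seed mode; positive log expression changes are kept.
#' Responses are Z-transformed within each experiment (population sd).
#'
#' @param expression data.frame with columns \code{gene_id},
#'   \code{experiment_id}, \code{mirna_id} (the transfected microRNA),
#'   \code{log_change} and either \code{control_intensity} or a logical
#'   \code{above_median}.
#' @param sites list of \code{"target_site"} objects for all
#'   microRNA/gene pairs.
#' @param mode \code{"canonical_only"} (sites with zero seed violations) or
#'   \code{"all_sites"} (at most one violation).
#' @param min_genes experiments retaining fewer genes trigger a warning.
#' @return data.frame with one row per training example: \code{gene_id},
#'   \code{experiment_id}, \code{mirna_id}, \code{y} (Z-transformed log
#'   change) and \code{site} (index into \code{sites}).
#' @export
prepare_training_set <- function(expression, sites,
                                 mode = c("canonical_only", "all_sites"),
                                 min_genes = 50) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene_id", "experiment_id", "mirna_id", "log_change")
                %in% names(expression)))
  max_viol <- if (mode == "canonical_only") 0L else 1L
  st <- sites_table(sites)
  st$idx <- seq_len(nrow(st))
  st <- st[st$seed_violations <= max_viol, , drop = FALSE]
  out <- NULL
  for (ex in unique(expression$experiment_id)) {
    tab <- expression[expression$experiment_id == ex, , drop = FALSE]
    if ("above_median" %in% names(tab)) {
      tab <- tab[tab$above_median, , drop = FALSE]
    } else if ("control_intensity" %in% names(tab)) {
      tab <- tab[tab$control_intensity > stats::median(tab$control_intensity),
                 , drop = FALSE]
    } else stop("expression table needs control_intensity or above_median")
    mir <- tab$mirna_id[1]
    ssub <- st[st$mirna_id == mir, , drop = FALSE]
    counts <- table(ssub$gene_id)
    single <- names(counts)[counts == 1]
    tab <- tab[tab$gene_id %in% single, , drop = FALSE]
    if (nrow(tab) < min_genes)
      warning(sprintf("experiment %s: only %d genes survive filtering",
                      ex, nrow(tab)), call. = FALSE)
    if (!nrow(tab)) next
    mu <- mean(tab$log_change)
    sd_pop <- sqrt(mean((tab$log_change - mu)^2))
    if (sd_pop == 0) sd_pop <- 1
    tab$y <- (tab$log_change - mu) / sd_pop
    tab$site <- ssub$idx[match(tab$gene_id, ssub$gene_id)]
    out <- rbind(out, tab[, c("gene_id", "experiment_id", "mirna_id",
                              "y", "site")])
  }
  if (is.null(out))
    out <- data.frame(gene_id = character(), experiment_id = character(),
                      mirna_id = character(), y = numeric(), site = integer())
  rownames(out) <- NULL
  out
}

# --- scoring -----------------------------------------------------------------

#' Score target sites with a fitted model
#'
#' @param object a fitted \code{"mirsvr"}.
#' @param features feature matrix (unstandardized), one row per site.
#' @param sites optional list of \code{"target_site"} objects (same order)
#'   whose coordinates are included in the output.
#' @return data.frame with columns from \code{\link{sites_table}} (when
#'   sites are given), \code{raw_score} and \code{mirsvr_score}.
#' @export
score_sites <- function(object, features, sites = NULL) {
  raw <- predict(object, features, type = "raw")
  cal <- if (!is.null(object$calibration))
    predict(object, features, type = "calibrated") else rep(NA_real_, length(raw))
  out <- data.frame(raw_score = raw, mirsvr_score = cal)
  if (!is.null(sites)) out <- cbind(sites_table(sites), out)
  out
}

#' Aggregate calibrated site scores into gene scores
#'
#' Calibrated site scores are additive: the score of a gene is the exact
#' sum of the scores of its sites (order-independent).
#'
#' @param site_scores numeric vector of calibrated site scores.
#' @param gene_id gene identifier per site.
#' @param mirna_id optional microRNA identifier per site.
#' @return data.frame with \code{gene_id}, \code{n_sites}, \code{total},
#'   and \code{mirna_ids} (comma-joined) when given.
#' @export
score_gene <- function(site_scores, gene_id, mirna_id = NULL) {
  tot <- tapply(site_scores, gene_id, sum)
  n <- tapply(site_scores, gene_id, length)
  out <- data.frame(gene_id = names(tot), n_sites = as.integer(n),
                    total = as.numeric(tot), stringsAsFactors = FALSE)
  if (!is.null(mirna_id)) {
    ids <- tapply(mirna_id, gene_id,
                  function(m) paste(sort(unique(m)), collapse = ","))
    out$mirna_ids <- as.character(ids[out$gene_id])
  }
  rownames(out) <- NULL
  out
}

#' Empirical probability of downregulation given a score cutoff
#'
#' For each downregulation level \code{a} and score threshold \code{S},
#' estimates \code{P(y <= a | score <= S)} by direct counting on a test
#' set, together with the fraction of predictions at or below \code{S}.
#' Thresholds with an empty conditioning set yield \code{NA}.
#'
#' @param scores calibrated prediction scores (more negative = stronger
#'   predicted downregulation).
#' @param y observed log expression changes on the same genes.
#' @param a_levels downregulation levels.
#' @param S_grid score thresholds; defaults to deciles of \code{scores}.
#' @return data.frame with columns \code{a}, \code{S}, \code{p},
#'   \code{n_cond} and \code{frac_le_S}.
#' @export
empirical_downreg_probability <- function(scores, y,
                                          a_levels = c(-0.1, -0.5, -1.0, -1.5),
                                          S_grid = NULL) {
  stopifnot(length(scores) == length(y))
  if (is.null(S_grid))
    S_grid <- unname(stats::quantile(scores, seq(0.05, 1, by = 0.05)))
  grid <- expand.grid(a = a_levels, S = S_grid)
  grid$p <- grid$n_cond <- grid$frac_le_S <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cond <- scores <= grid$S[i]
    grid$n_cond[i] <- sum(cond)
    grid$frac_le_S[i] <- mean(cond)
    if (any(cond)) grid$p[i] <- mean(y[cond] <= grid$a[i])
  }
  grid[, c("a", "S", "p", "n_cond", "frac_le_S")]
}

# --- serialization -----------------------------------------------------------

.num17 <- function(x) sprintf("%.17g", x)

#' Serialize a fitted mirSVR model to a JSON artifact
#'
#' Writes feature order, scaler statistics, weights, bias, hyperparameters
#' and sigmoid calibration as a single JSON document.  Numbers are stored
#' at full precision so that a reloaded model rescoring the same sites is
#' bit-identical.
#'
#' @param object a fitted \code{"mirsvr"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_mirsvr <- function(object, path) {
  doc <- list(
    format = "mirsvr-model", version = 1L,
    features = object$features,
    w = .num17(unname(object$w)), b = .num17(object$b),
    C = .num17(object$C), nu = .num17(object$nu),
    scaler = if (!is.null(object$scaler)) list(
      features = object$scaler$features,
      center = .num17(unname(object$scaler$center)),
      scale = .num17(unname(object$scaler$scale))),
    calibration = if (!is.null(object$calibration)) list(
      a = .num17(object$calibration$a), b = .num17(object$calibration$b),
      c = .num17(object$calibration$c)),
    n_train = object$n)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Load a serialized mirSVR model
#'
#' @param path JSON file written by \code{\link{write_mirsvr}}.
#' @return object of class \code{"mirsvr"} (scoring components only).
#' @export
read_mirsvr <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "mirsvr-model"))
    stop("not a mirsvr model artifact: ", path)
  scaler <- NULL
  if (!is.null(doc$scaler))
    scaler <- structure(list(
      center = stats::setNames(as.numeric(doc$scaler$center), doc$scaler$features),
      scale = stats::setNames(as.numeric(doc$scaler$scale), doc$scaler$features),
      features = doc$scaler$features), class = "feature_scaler")
  calibration <- NULL
  if (!is.null(doc$calibration))
    calibration <- structure(list(a = as.numeric(doc$calibration$a),
                                  b = as.numeric(doc$calibration$b),
                                  c = as.numeric(doc$calibration$c)),
                             class = "sigmoid_calibration")
  structure(list(
    w = stats::setNames(as.numeric(doc$w), doc$features),
    b = as.numeric(doc$b), C = as.numeric(doc$C), nu = as.numeric(doc$nu),
    scaler = scaler, calibration = calibration,
    features = doc$features, n = doc$n_train), class = "mirsvr")
}
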