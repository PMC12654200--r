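#' Evaluation configuration for donor-level LOOCV
#'
#' @param model `"svm"` (RBF or linear kernel, C = 1 by default, kernel
#'   width from the "scale" heuristic `1/(n_features * var)`) or
#'   `"naive_bayes"` (Gaussian class-conditionals with a relative variance
#'   floor of 1e-9).
#' @param fs_mode `"per_fold"` (FCBF re-run inside every training fold;
#'   leakage-safe default), `"global"` (one selection on the full donor set,
#'   reproducing the single band list per pipeline that a global-selection
#'   workflow reports — optimistic), or `"none"`.
#' @param positive_class Class scored as positive (default `"DCD"`).
#' @param alpha Complement of the confidence level for the accuracy CI.
#' @param svm_cost SVM penalty C.
#' @param svm_kernel `"rbf"` or `"linear"`.
#' @param fcbf An [fcbf_config()] used when feature selection is active.
#' @param seed Integer recorded with the result (the evaluation itself is
#'   deterministic: fixed hyperparameters, no random restarts).
#' @return An `eval_config` list.
#' @export
eval_config <- function(model = c("svm", "naive_bayes"),
                        fs_mode = c("per_fold", "global", "none"),
                        positive_class = "DCD", alpha = 0.05,
                        svm_cost = 1, svm_kernel = c("rbf", "linear"),
                        fcbf = fcbf_config(), seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, svm_cost > 0)
  structure(list(model = match.arg(model), fs_mode = match.arg(fs_mode),
                 positive_class = positive_class, alpha = alpha,
                 svm_cost = svm_cost, svm_kernel = match.arg(svm_kernel),
                 fcbf = fcbf, seed = as.integer(seed)),
            class = "eval_config")
}

#' Rank-based AUC
#'
#' Mann-Whitney statistic of positive-class scores over negative-class
#' scores (ties 0.5) divided by `n_pos * n_neg`: the probability a random
#' positive score exceeds a random negative one. Reported exactly as
#' computed — never flipped — so an inverted score orientation shows up as
#' AUC < 0.5 rather than being silently corrected.
#'
#' @param scores Numeric scores.
#' @param labels Class labels.
#' @param positive_class Which label counts as positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels, positive_class = "DCD") {
  pos <- scores[labels == positive_class]
  neg <- scores[labels != positive_class]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present", call. = FALSE)
  mann_whitney_u(pos, neg) / (length(pos) * length(neg))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' `lo = qbeta(alpha/2, k, n-k+1)` (0 when k = 0) and
#' `hi = qbeta(1-alpha/2, k+1, n-k)` (1 when k = n).
#'
#' @param k Successes, `0 <= k <= n`.
#' @param n Trials, >= 1.
#' @param alpha Two-sided error level (default 0.05 for a 95% CI).
#' @return Numeric `c(lo, hi)`.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("need integers 0 <= k <= n, n >= 1", call. = FALSE)
  c(lo = if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1),
    hi = if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k))
}

# z-score columns by training mean/sd (sd 0 -> 1 to keep constants harmless)
standardizer <- function(train) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(apply = function(m) sweep(sweep(m, 2L, mu), 2L, sdv, `/`))
}

fit_score_svm <- function(xtr, ytr, xte, positive, cost, kernel) {
  gam <- 1 / (ncol(xtr) * max(stats::var(as.vector(xtr)), .Machine$double.eps))
  fit <- e1071::svm(xtr, factor(ytr), scale = FALSE, cost = cost,
                    kernel = if (kernel == "rbf") "radial" else "linear",
                    gamma = gam)
  pr <- stats::predict(fit, xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1L], "/")[[1L]][1L]
  if (first == positive) drop(dv) else -drop(dv)
}

# Gaussian naive Bayes with relative variance floor; returns P(positive | x)
fit_score_gnb <- function(xtr, ytr, xte, positive) {
  classes <- unique(ytr)
  pooled <- apply(xtr, 2L, stats::var)
  stats_by_class <- lapply(classes, function(cl) {
    xi <- xtr[ytr == cl, , drop = FALSE]
    v <- apply(xi, 2L, stats::var)
    v <- pmax(v, 1e-9 * pooled, .Machine$double.xmin)
    list(mu = colMeans(xi), v = v, logprior = log(nrow(xi) / nrow(xtr)))
  })
  names(stats_by_class) <- classes
  loglik <- vapply(classes, function(cl) {
    s <- stats_by_class[[cl]]
    apply(xte, 1L, function(x)
      sum(stats::dnorm(x, s$mu, sqrt(s$v), log = TRUE)) + s$logprior)
  }, numeric(nrow(xte)))
  loglik <- matrix(loglik, nrow = nrow(xte),
                   dimnames = list(NULL, classes))
  post <- exp(loglik - apply(loglik, 1L, max))
  post <- post / rowSums(post)
  post[, positive]
}

#' Donor-level leave-one-out cross-validation
#'
#' Each donor is held out in turn; FCBF (when the pipeline requests it and
#' `fs_mode = "per_fold"`) runs on the remaining donors only, features are
#' z-scored with training-fold mean/SD, the model is fitted and the held-out
#' donor scored (SVM: signed decision value; naive Bayes: posterior
#' probability of the positive class). The out-of-fold scores yield the
#' rank-based AUC; thresholding them (SVM at 0, NB at 0.5) yields the
#' confusion matrix, accuracy with Clopper-Pearson CI, sensitivity
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)`.
#'
#' @param set A donor-level, preprocessed [spectra_set()] (n >= 4, both
#'   classes present, no `UNKNOWN` labels).
#' @param pipeline The [pipeline_spec()] that produced `set` (its `fcbf`
#'   flag gates feature selection); `NULL` disables selection.
#' @param config An [eval_config()].
#' @return A `loocv_eval` list: `auc`, `accuracy`, `accuracy_ci`,
#'   `sensitivity`, `specificity`, `confusion` (tp/fp/tn/fn),
#'   `fold_scores` (named per donor), `fold_features` (per-fold selected
#'   wavenumbers, when selection ran), `config`, `pipeline_label`.
#' @export
loocv_evaluate <- function(set, pipeline = NULL, config = eval_config()) {
  y <- set$meta$group
  if (any(y == "UNKNOWN"))
    stop("supervised evaluation requires DCD/DBD labels only", call. = FALSE)
  n <- nrow(set$matrix)
  if (n < 4L) stop("need at least 4 donors", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  pos <- config$positive_class
  do_fs <- !is.null(pipeline) && isTRUE(pipeline$fcbf) && config$fs_mode != "none"

  x <- set$matrix
  colnames(x) <- formatC(set$grid, format = "fg", digits = 6)

  global_sel <- NULL
  if (do_fs && config$fs_mode == "global") {
    global_sel <- fcbf_select(x, y, config$fcbf)
    if (nrow(global_sel) == 0L)
      stop("global FCBF selected no features", call. = FALSE)
  }

  scores <- numeric(n)
  fold_features <- vector("list", n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L)
      stop(sprintf("fold %d: training labels collapse to one class", i),
           call. = FALSE)
    xtr <- x[-i, , drop = FALSE]
    xte <- x[i, , drop = FALSE]
    if (do_fs) {
      sel <- if (config$fs_mode == "per_fold")
        fcbf_select(xtr, ytr, config$fcbf) else global_sel
      if (nrow(sel) == 0L)
        stop(sprintf("fold %d (held-out donor '%s'): FCBF selected no features",
                     i, set$meta$donor_id[i]), call. = FALSE)
      keep <- match(formatC(sel$wavenumber, format = "fg", digits = 6),
                    colnames(x))
      xtr <- xtr[, keep, drop = FALSE]
      xte <- xte[, keep, drop = FALSE]
      fold_features[[i]] <- sel$wavenumber
    }
    std <- standardizer(xtr)
    xtr <- std$apply(xtr); xte <- std$apply(xte)
    scores[i] <- if (config$model == "svm")
      fit_score_svm(xtr, ytr, xte, pos, config$svm_cost, config$svm_kernel)
    else fit_score_gnb(xtr, ytr, xte, pos)
  }
  names(scores) <- set$meta$donor_id

  thr <- if (config$model == "svm") 0 else 0.5
  pred_pos <- scores > thr
  is_pos <- y == pos
  tp <- sum(pred_pos & is_pos); fn <- sum(!pred_pos & is_pos)
  tn <- sum(!pred_pos & !is_pos); fp <- sum(pred_pos & !is_pos)
  k <- tp + tn
  structure(list(
    auc = auc_rank(scores, y, pos),
    accuracy = k / n,
    accuracy_ci = clopper_pearson(k, n, config$alpha),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    fold_scores = scores,
    fold_features = fold_features,
    config = config,
    pipeline_label = if (is.null(pipeline)) NA_character_ else pipeline$label),
    class = "loocv_eval")
}

#' @export
print.loocv_eval <- function(x, ...) {
  cat(sprintf("<loocv_eval> %s | AUC %.2f | accuracy %.2f (%.2f-%.2f) | sens %.2f | spec %.2f\n",
              ifelse(is.na(x$pipeline_label), "", x$pipeline_label),
              x$auc, x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2],
              x$sensitivity, x$specificity))
  invisible(x)
}
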