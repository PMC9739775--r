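# The experiment driver: stratified k-fold cross-validation repeated
# n_repeats times, per-fold z-scoring from training statistics only,
# accuracy / kappa / macro one-vs-rest AUROC and AUPRC, and the window
# sweep over 1-24 s.

#' Cross-validation configuration
#'
#' @param n_folds number of folds (default 10).
#' @param n_repeats number of repeats of the whole CV (study default
#'   30; desk-scale runs typically use 3).
#' @param seed master integer seed.
#' @param stratified stratify folds by class (default TRUE).
#' @param grouping `"epoch"` (default) assigns folds at the epoch
#'   level, matching the study protocol; `"recording"` keeps all epochs
#'   of a recording in one fold, which avoids the leakage that
#'   overlapping epochs otherwise cause.
#' @return a `cv_config` list.
#' @export
cv_config <- function(n_folds = 10L, n_repeats = 30L, seed = 1L,
                      stratified = TRUE,
                      grouping = c("epoch", "recording")) {
  grouping <- match.arg(grouping)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  structure(list(n_folds = n_folds, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), stratified = isTRUE(stratified),
                 grouping = grouping),
            class = "cv_config")
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals its members across
#' folds, sending remainders to the currently least-loaded folds, so
#' per-class counts per fold differ by at most 1 and total fold sizes
#' differ by at most 1. Deterministic given the seed.
#'
#' @param labels class labels.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:n_folds`.
#' @export
stratified_kfold <- function(labels, n_folds, seed = NULL) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (n < n_folds) stop("fewer observations than folds")
  with_seed_or_not(seed, {
    fold <- integer(n)
    load <- integer(n_folds)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (!length(idx)) next
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% n_folds
      rem <- length(idx) %% n_folds
      counts <- rep.int(base, n_folds)
      if (rem > 0L) {
        # break load ties randomly so no fold is systematically favoured
        recipients <- order(load, sample.int(n_folds))[seq_len(rem)]
        counts[recipients] <- counts[recipients] + 1L
      }
      fold[idx] <- rep.int(seq_len(n_folds), counts)
      load <- load + counts
    }
    fold
  })
}

#' Classification accuracy
#'
#' Number of correctly classified instances divided by the total number
#' of instances.
#'
#' @param predictions predicted labels.
#' @param truths true labels of the same length.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) == 0L) {
    stop("predictions and truths must be non-empty and of equal length")
  }
  mean(as.character(predictions) == as.character(truths))
}

#' Cohen's kappa from a confusion matrix
#'
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and chance
#' agreement `p_e` from the row/column marginals. Returns `NaN` when
#' `p_e = 1` (degenerate marginals).
#'
#' @param cm square confusion matrix (rows: truth, columns: predicted,
#'   or vice versa; kappa is symmetric in that choice).
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  n <- sum(cm)
  if (n == 0) stop("confusion matrix is empty")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  (po - pe) / (1 - pe)
}

# Binary ROC AUC by trapezoidal integration over the (FPR, TPR) curve,
# grouping tied scores.
roc_auc_binary <- function(scores, positive) {
  P <- sum(positive); Ng <- sum(!positive)
  if (P == 0L || Ng == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  cut_end <- which(diff(s) != 0)
  cut_end <- c(cut_end, length(s))
  tp <- cumsum(y)[cut_end]
  fp <- cumsum(!y)[cut_end]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / Ng)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Binary precision-recall AUC, trapezoid over recall with the curve
# anchored at (recall 0, precision of the top-scoring group).
pr_auc_binary <- function(scores, positive) {
  P <- sum(positive)
  if (P == 0L || all(positive)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- positive[ord]; s <- scores[ord]
  cut_end <- which(diff(s) != 0)
  cut_end <- c(cut_end, length(s))
  tp <- cumsum(y)[cut_end]
  n_pred <- cut_end
  precision <- tp / n_pred
  recall <- tp / P
  recall <- c(0, recall)
  precision <- c(precision[1L], precision)
  sum(diff(recall) * (utils::head(precision, -1) + utils::tail(precision, -1)) / 2)
}

#' Macro one-vs-rest AUROC and AUPRC
#'
#' One curve per class (that class's score column against
#' class-vs-rest truth), areas by trapezoidal integration, averaged
#' over the classes present in `truths`; absent classes are skipped
#' with a warning.
#'
#' @param scores matrix of per-instance class scores (columns named by
#'   class).
#' @param truths true labels.
#' @return named vector `c(auroc, auprc)`.
#' @export
macro_ovr_curves <- function(scores, truths) {
  truths <- as.factor(truths)
  classes <- colnames(scores)
  if (is.null(classes)) stop("scores must have class-named columns")
  present <- classes[classes %in% unique(as.character(truths))]
  absent <- setdiff(classes, present)
  if (length(absent) > 0L) {
    warning("class(es) absent from truths skipped: ", paste(absent, collapse = ", "))
  }
  aurocs <- auprcs <- numeric(0)
  for (cl in present) {
    pos <- as.character(truths) == cl
    aurocs <- c(aurocs, roc_auc_binary(scores[, cl], pos))
    auprcs <- c(auprcs, pr_auc_binary(scores[, cl], pos))
  }
  c(auroc = mean(aurocs, na.rm = TRUE), auprc = mean(auprcs, na.rm = TRUE))
}

# Column-wise z-scoring with training-fold statistics only; constant
# columns get unit scale.
standardize_fold <- function(train, test) {
  center <- colMeans(train)
  scale <- apply(train, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(
    train = sweep(sweep(train, 2L, center), 2L, scale, "/"),
    test = sweep(sweep(test, 2L, center), 2L, scale, "/"),
    center = center, scale = scale
  )
}

# Default per-method settings; user-supplied config entries override.
method_defaults <- function(method) {
  # Armijo with a conservative initial step for network training: the
  # sigmoid sum-of-squares surface has saturated plateaus that a full
  # first step can jump onto irrecoverably.
  nn_armijo <- armijo_params(s = 0.1)
  switch(method,
         knn = list(k = 2L),
         bfgs = list(n_hidden = 10L, max_iter = 300L, grad_tol = 1e-6,
                     init_scale = 0.2, armijo = nn_armijo),
         multistart = list(n_hidden = 10L, n_starts = 25L, bound = 10,
                           init_bound = NULL, max_iter = 200L,
                           grad_tol = 1e-6, armijo = nn_armijo),
         ga = list(n_hidden = 10L, bound = 10, ga = ga_config()),
         stop("unknown method: ", method))
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

# Train one classifier on a (standardized) training fold. Returns
# predict/scores closures over the fitted model.
fit_method <- function(method, X, y, config = list(), seed = NULL) {
  if (is.list(method)) {       # custom classifier: list(train, predict[, scores])
    model <- method$train(X, y)
    return(list(
      predict = function(newX) method$predict(model, newX),
      scores = if (!is.null(method$scores)) function(newX) method$scores(model, newX)
    ))
  }
  cfg <- merge_config(method_defaults(method), config)
  if (method == "knn") {
    model <- knn_model(X, y, k = cfg$k)
    return(list(predict = function(newX) knn_predict(model, newX),
                scores = function(newX) knn_scores(model, newX)))
  }
  problem <- slnn_problem(X, y, n_hidden = cfg$n_hidden)
  w <- switch(method,
    bfgs = {
      x0 <- with_seed_or_not(seed, stats::runif(problem$d, -cfg$init_scale, cfg$init_scale))
      bfgs_minimize(problem$f, problem$g, x0, grad_tol = cfg$grad_tol,
                    max_iter = cfg$max_iter, armijo = cfg$armijo)$x
    },
    multistart = {
      ib <- cfg$init_bound %||% cfg$bound
      multistart_minimize(
        problem$f, problem$g, lower = rep(-cfg$bound, problem$d),
        upper = rep(cfg$bound, problem$d), n_starts = cfg$n_starts,
        seed = seed, grad_tol = cfg$grad_tol, max_iter = cfg$max_iter,
        armijo = cfg$armijo, keep_unconverged = TRUE,
        sample_lower = rep(-ib, problem$d),
        sample_upper = rep(ib, problem$d))$best$x
    },
    ga = ga_minimize(problem$f, lower = rep(-cfg$bound, problem$d),
                     upper = rep(cfg$bound, problem$d), config = cfg$ga,
                     seed = seed, g = problem$g)$x
  )
  list(predict = function(newX) {
    slnn_predict(w, as.matrix(newX), problem$shape, problem$levels)
  }, scores = NULL)
}

#' Cross-validated evaluation of one classifier
#'
#' For each repeat a fresh seeded fold split is drawn; within each
#' fold, features are z-scored with training-fold statistics, the
#' classifier is trained on the training rows and evaluated on the test
#' rows. The reported accuracy is the mean over folds, then over
#' repeats. Cohen's kappa is computed on the confusion matrix pooled
#' over folds within a repeat and averaged over repeats; when the
#' classifier provides graded scores (K-NN), macro one-vs-rest AUROC
#' and AUPRC are pooled and averaged the same way.
#'
#' @param method `"bfgs"`, `"multistart"`, `"ga"`, `"knn"`, or a list
#'   with `train(X, y)` and `predict(model, X)` (and optionally
#'   `scores(model, X)`) entries.
#' @param table feature table from [build_feature_table()].
#' @param cv a [cv_config()].
#' @param method_config named list overriding the method's defaults.
#' @return a `cv_result` list with `mean_accuracy`, `sd_accuracy`,
#'   `repeat_accuracy`, `mean_kappa`, `mean_auroc`, `mean_auprc`,
#'   `method` and `n`.
#' @export
evaluate_classifier <- function(method, table, cv = cv_config(),
                                method_config = list()) {
  feat_cols <- setdiff(names(table), c("label", "source_id", "window_s"))
  X <- as.matrix(table[, feat_cols, drop = FALSE])
  y <- as_class_factor(table$label)
  counts <- table(y)
  small <- names(counts)[counts > 0 & counts < cv$n_folds]
  if (length(small) > 0L) {
    stop("class(es) with fewer rows than folds: ", paste(small, collapse = ", "))
  }
  groups <- if (cv$grouping == "recording") table$source_id else NULL
  repeat_seeds <- derive_seeds(cv$seed, cv$n_repeats * 2L)
  repeat_acc <- repeat_kappa <- repeat_auroc <- repeat_auprc <- numeric(cv$n_repeats)
  lev <- levels(y)
  for (r in seq_len(cv$n_repeats)) {
    fold <- assign_folds(y, groups, cv, repeat_seeds[2L * r - 1L])
    fit_seeds <- derive_seeds(repeat_seeds[2L * r], cv$n_folds)
    fold_acc <- numeric(cv$n_folds)
    cm <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
    all_scores <- NULL; score_truths <- NULL
    for (k in seq_len(cv$n_folds)) {
      test_idx <- which(fold == k)
      train_idx <- which(fold != k)
      if (!length(test_idx)) stop("fold ", k, " is empty")
      std <- standardize_fold(X[train_idx, , drop = FALSE],
                              X[test_idx, , drop = FALSE])
      fitted <- fit_method(method, std$train, y[train_idx],
                           config = method_config, seed = fit_seeds[k])
      pred <- fitted$predict(std$test)
      truth <- y[test_idx]
      fold_acc[k] <- accuracy(pred, truth)
      cm <- cm + as.matrix(table(factor(truth, levels = lev),
                                 factor(pred, levels = lev)))
      if (!is.null(fitted$scores)) {
        sc <- fitted$scores(std$test)
        all_scores <- rbind(all_scores, sc)
        score_truths <- c(score_truths, as.character(truth))
      }
    }
    repeat_acc[r] <- mean(fold_acc)
    repeat_kappa[r] <- cohen_kappa(cm)
    if (!is.null(all_scores)) {
      curves <- macro_ovr_curves(all_scores, factor(score_truths, levels = lev))
      repeat_auroc[r] <- curves[["auroc"]]
      repeat_auprc[r] <- curves[["auprc"]]
    } else {
      repeat_auroc[r] <- NA_real_
      repeat_auprc[r] <- NA_real_
    }
  }
  structure(list(
    method = if (is.list(method)) "custom" else method,
    mean_accuracy = mean(repeat_acc),
    sd_accuracy = stats::sd(repeat_acc),
    repeat_accuracy = repeat_acc,
    mean_kappa = mean(repeat_kappa),
    mean_auroc = mean(repeat_auroc),
    mean_auprc = mean(repeat_auprc),
    n = nrow(X)
  ), class = "cv_result")
}

# Fold assignment honouring the grouping mode: recording-level grouping
# stratifies recordings by their label and maps folds down to epochs.
assign_folds <- function(y, groups, cv, seed) {
  if (is.null(groups)) {
    if (cv$stratified) {
      stratified_kfold(y, cv$n_folds, seed)
    } else {
      with_seed_or_not(seed, sample(rep_len(seq_len(cv$n_folds), length(y))))
    }
  } else {
    ug <- unique(groups)
    glab <- y[match(ug, groups)]
    gfold <- stratified_kfold(glab, cv$n_folds, seed)
    gfold[match(groups, ug)]
  }
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s> mean accuracy %.4f (sd %.4f over %d repeats), kappa %.4f\n",
              x$method, x$mean_accuracy, x$sd_accuracy,
              length(x$repeat_accuracy), x$mean_kappa))
  if (!is.na(x$mean_auroc)) {
    cat(sprintf("  macro OVR AUROC %.4f, AUPRC %.4f\n", x$mean_auroc, x$mean_auprc))
  }
  invisible(x)
}

#' Run the window-length sweep
#'
#' For each window length: filter, epoch, extract features, and
#' cross-validate every requested method. Windows that yield no epochs
#' are marked unavailable; per-cell failures are recorded and the sweep
#' continues.
#'
#' @param set an `eeg_recording_set`.
#' @param windows window lengths in seconds (study default `1:24`).
#' @param methods subset of `c("bfgs", "multistart", "ga", "knn")`.
#' @param cv a [cv_config()].
#' @param overlap epoch overlap fraction (default 0.5).
#' @param cutoff_hz,n_taps FIR design parameters.
#' @param bands,summary feature extraction settings.
#' @param method_config named list of per-method config overrides,
#'   e.g. `list(ga = list(ga = ga_config(N = 50)))`.
#' @return a `sweep_result` with data frames `accuracy`
#'   (window_s, method, mean_accuracy, sd_accuracy, kappa, n_epochs,
#'   available, note), `knn_metrics` (window_s, auroc, auprc, kappa)
#'   and `best_windows` (method, window_s, mean_accuracy).
#' @export
run_window_sweep <- function(set, windows = 1:24,
                             methods = c("bfgs", "multistart", "ga", "knn"),
                             cv = cv_config(), overlap = 0.5,
                             cutoff_hz = 40, n_taps = 101L,
                             bands = eeg_bands(), summary = "mean",
                             method_config = list()) {
  recs <- if (inherits(set, "eeg_recording_set")) set$recordings else set
  fs <- recs[[1L]]$fs
  fir <- design_lowpass_fir(fs, cutoff_hz = cutoff_hz, n_taps = n_taps)
  rows <- list()
  knn_rows <- list()
  for (w in windows) {
    tab <- tryCatch(
      build_feature_table(set, w, overlap = overlap, filter_spec = fir,
                          bands = bands, summary = summary),
      error = function(e) e
    )
    for (m in methods) {
      if (inherits(tab, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          window_s = w, method = m, mean_accuracy = NA_real_,
          sd_accuracy = NA_real_, kappa = NA_real_, n_epochs = 0L,
          available = FALSE, note = conditionMessage(tab),
          stringsAsFactors = FALSE)
        next
      }
      res <- tryCatch(
        evaluate_classifier(m, tab, cv = cv,
                            method_config = method_config[[m]] %||% list()),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          window_s = w, method = m, mean_accuracy = NA_real_,
          sd_accuracy = NA_real_, kappa = NA_real_, n_epochs = nrow(tab),
          available = FALSE, note = conditionMessage(res),
          stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        window_s = w, method = m, mean_accuracy = res$mean_accuracy,
        sd_accuracy = res$sd_accuracy, kappa = res$mean_kappa,
        n_epochs = res$n, available = TRUE, note = "",
        stringsAsFactors = FALSE)
      if (identical(m, "knn")) {
        knn_rows[[length(knn_rows) + 1L]] <- data.frame(
          window_s = w, auroc = res$mean_auroc, auprc = res$mean_auprc,
          kappa = res$mean_kappa, stringsAsFactors = FALSE)
      }
    }
  }
  acc <- do.call(rbind, rows)
  rownames(acc) <- NULL
  best <- do.call(rbind, lapply(unique(acc$method), function(m) {
    sub <- acc[acc$method == m & acc$available, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    top <- sub[which.max(sub$mean_accuracy), , drop = FALSE]
    data.frame(method = m, window_s = top$window_s,
               mean_accuracy = top$mean_accuracy, stringsAsFactors = FALSE)
  }))
  structure(list(
    accuracy = acc,
    knn_metrics = if (length(knn_rows)) do.call(rbind, knn_rows) else NULL,
    best_windows = best,
    windows = windows, methods = methods, cv = cv
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  wide <- stats::reshape(
    x$accuracy[, c("window_s", "method", "mean_accuracy")],
    idvar = "window_s", timevar = "method", direction = "wide")
  names(wide) <- sub("^mean_accuracy\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  if (!is.null(x$best_windows)) {
    cat("best window per method:\n")
    print(x$best_windows, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write sweep outputs to a directory
#'
#' Emits `accuracy.csv`, `knn_metrics.csv` (when K-NN was run) and a
#' `manifest.json` capturing the resolved configuration and seed.
#'
#' @param sweep a `sweep_result`.
#' @param out_dir destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_sweep_result <- function(sweep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sweep$accuracy, file.path(out_dir, "accuracy.csv"),
                   row.names = FALSE)
  if (!is.null(sweep$knn_metrics)) {
    utils::write.csv(sweep$knn_metrics, file.path(out_dir, "knn_metrics.csv"),
                     row.names = FALSE)
  }
  manifest <- list(windows = sweep$windows, methods = sweep$methods,
                   n_folds = sweep$cv$n_folds, n_repeats = sweep$cv$n_repeats,
                   seed = sweep$cv$seed, grouping = sweep$cv$grouping)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
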