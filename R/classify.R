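#' Classifier specification
#'
#' The two classifiers of the pipeline: a Gaussian-kernel (RBF) support
#' vector machine with box constraint 1 and a kernel scale set by the
#' median-pairwise-distance heuristic, and linear discriminant analysis
#' with singular-value-decomposition semantics (rank-reduced, suitable for
#' many more features than examples).
#'
#' Both classifiers train under equal class priors (balanced SVM class
#' weights, uniform LDA priors): the paradigm delivers target and
#' distractor stimuli with equal probability, and leave-one-out training
#' folds are imbalanced by exactly one example, which would otherwise bias
#' a prior-sensitive classifier against the held-out class.
#'
#' @param kind "svm" or "lda".
#' @param kernel_scale "heuristic" or a positive number (SVM only); the
#'   kernel is exp(-||u - v||^2 / scale^2).
#' @param box_constraint SVM cost parameter.
#' @param balanced logical; equal-prior training (see above).
#' @param subsample maximum number of training points entering the
#'   kernel-scale heuristic.
#' @param seed seed for the heuristic's subsampling.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "lda"),
                            kernel_scale = "heuristic",
                            box_constraint = 1,
                            balanced = TRUE,
                            subsample = 1000L,
                            seed = 1L) {
  kind <- match.arg(kind)
  if (is.numeric(kernel_scale) && kernel_scale <= 0)
    stop("classifier_spec: kernel_scale must be > 0")
  structure(list(kind = kind, kernel_scale = kernel_scale,
                 box_constraint = box_constraint, balanced = balanced,
                 subsample = as.integer(subsample), seed = seed),
            class = "classifier_spec")
}

#' Median-distance kernel scale heuristic
#'
#' Median Euclidean distance between all pairs of a seeded subsample of the
#' training examples (the full set when it is no larger than `subsample`).
#'
#' @param X numeric matrix of training examples (rows).
#' @param subsample maximum subsample size.
#' @param seed seed for the subsample draw.
#' @return positive scalar; errors when the median distance is 0
#'   (degenerate data).
#' @export
kernel_scale_heuristic <- function(X, subsample = 1000L, seed = 1L) {
  n <- nrow(X)
  if (n < 2) stop("kernel_scale_heuristic: need >= 2 training examples")
  idx <- if (n <= subsample) seq_len(n)
         else with_seed(seed, sample(n, subsample))
  md <- median(stats::dist(X[idx, , drop = FALSE]))
  if (!is.finite(md) || md <= 0)
    stop("kernel_scale_heuristic: degenerate data (median pairwise distance 0)")
  md
}

#' Train an SVM or LDA classifier
#'
#' @param spec a [classifier_spec()].
#' @param X numeric feature matrix (rows = examples).
#' @param y factor or character labels with both classes present.
#' @return object of class `serp_model`.
#' @export
train_classifier <- function(spec, X, y) {
  y <- factor(y, levels = c("AD", "AV"))
  if (nlevels(droplevels(y)) < 2)
    stop("train_classifier: both classes must be present in the training set")
  if (!all(is.finite(X))) stop("train_classifier: non-finite features")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("s", seq_len(ncol(X)))
  fit <- if (spec$kind == "svm") {
    scale_val <- if (identical(spec$kernel_scale, "heuristic"))
      kernel_scale_heuristic(X, spec$subsample, spec$seed)
    else spec$kernel_scale
    cw <- if (isTRUE(spec$balanced)) {
      tb <- table(y)
      setNames(as.numeric(sum(tb) / (length(tb) * tb)), names(tb))
    }
    e1071::svm(X, y, kernel = "radial", gamma = 1 / scale_val^2,
               cost = spec$box_constraint, scale = FALSE,
               class.weights = cw)
  } else {
    # rank-reduced LDA; muffle the expected collinearity warning when p > n
    prior <- if (isTRUE(spec$balanced)) c(0.5, 0.5)
             else as.numeric(table(y) / length(y))
    withCallingHandlers(
      MASS::lda(X, grouping = y, prior = prior),
      warning = function(w) {
        if (grepl("collinear|constant", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  structure(list(spec = spec, fit = fit, p = ncol(X),
                 features = colnames(X)),
            class = "serp_model")
}

#' @export
predict.serp_model <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = object$p,
                    dimnames = list(NULL, object$features))
  if (object$spec$kind == "svm") {
    pr <- predict(object$fit, newdata, decision.values = TRUE)
    out <- as.character(pr)
    dv <- as.numeric(attr(pr, "decision.values"))
    out[dv == 0] <- "AD"   # fixed tie rule
    out
  } else {
    as.character(predict(object$fit, newdata)$class)
  }
}

# selection columns of the full F1/F2 matrix for a 1..60 index set
selection_cols <- function(method, indexes, p_half) {
  if (method %in% c("F1", "FS1")) c(indexes, p_half + indexes) else indexes
}

# LOO accuracy of spec on (X, y); used as the inner criterion of the
# threshold search
inner_loo_accuracy <- function(spec, X, y) {
  n <- nrow(X)
  correct <- 0L
  for (j in seq_len(n)) {
    yt <- droplevels(y[-j])
    if (nlevels(yt) < 2) next
    m <- train_classifier(spec, X[-j, , drop = FALSE], y[-j])
    if (predict(m, X[j, , drop = FALSE]) == as.character(y[j]))
      correct <- correct + 1L
  }
  correct / n
}

# choose the FS threshold/index set from training-fold rows only:
# ADAV from training class means, sweep thresholds, pick the smallest
# threshold attaining maximal inner-LOO accuracy (ties -> more features)
choose_selection <- function(spec, F2X, FbaseX, y, rows, method,
                             fs_threshold, fs_increment) {
  ad <- rows[y[rows] == "AD"]; av <- rows[y[rows] == "AV"]
  adav <- colMeans(F2X[ad, , drop = FALSE]) -
          colMeans(F2X[av, , drop = FALSE])
  p_half <- ncol(F2X)
  if (is.numeric(fs_threshold)) {
    idx <- select_indexes(adav, fs_threshold)
    if (length(idx) == 0) idx <- select_indexes(adav, 0)  # fallback
    return(list(threshold = fs_threshold, indexes = idx))
  }
  sweep <- sweep_selection(adav, fs_increment)
  best_acc <- -1; best <- NULL
  for (k in seq_along(sweep$thresholds)) {
    idx <- sweep$index_sets[[k]]
    cols <- selection_cols(method, idx, p_half)
    acc <- inner_loo_accuracy(spec, FbaseX[rows, cols, drop = FALSE], y[rows])
    if (acc > best_acc) {   # strict: smallest threshold wins ties
      best_acc <- acc
      best <- list(threshold = sweep$thresholds[k], indexes = idx)
    }
  }
  best
}

#' Leave-one-out cross-validation of one channel/method/classifier
#'
#' Each averaged-group example (one F1 pair or one F2 difference wave) is
#' held out in turn; everything data-dependent — the diffsERP(ADAV)
#' selection wave, the threshold choice for FS methods, and the SVM kernel
#' scale — is recomputed from the training fold only (default
#' `fs_mode = "train"`), so each fold is leakage-free and the procedure is
#' replayable online. `fs_mode = "pooled"` computes the selection once from
#' all examples (a deliberately leaky sensitivity mode).
#'
#' @param serps a [cluster_serps()] result.
#' @param method "F1", "F2", "FS1" or "FS2".
#' @param spec a [classifier_spec()].
#' @param fs_mode selection scope for FS methods: "train" or "pooled".
#' @param fs_threshold "auto" (inner leave-one-out choice of the smallest
#'   threshold with maximal training accuracy) or a fixed non-negative
#'   number; an empty fixed-threshold selection falls back to threshold 0.
#' @param fs_increment threshold grid step, microvolts.
#' @param detail logical; record per-fold thresholds/index sets.
#' @param keep_models logical; retain each fold's trained model (for
#'   leakage audits).
#' @return object of class `cv_result` with per-fold predictions and
#'   truths, `accuracy_pct`, and `confusion_pct` (TP_D, FP_D, FP_V, TP_V as
#'   percentages of all folds).
#' @export
loo_crossval <- function(serps, method = c("F1", "F2", "FS1", "FS2"),
                         spec = classifier_spec("svm"),
                         fs_mode = c("train", "pooled"),
                         fs_threshold = "auto", fs_increment = 0.1,
                         detail = FALSE, keep_models = FALSE) {
  method <- match.arg(method)
  fs_mode <- match.arg(fs_mode)
  is_fs <- method %in% c("FS1", "FS2")
  base <- if (method %in% c("F1", "FS1")) "F1" else "F2"

  Fbase <- feature_matrix(serps, base)
  F2X <- if (base == "F2") Fbase$X else feature_matrix(serps, "F2")$X
  y <- Fbase$y
  n <- length(y)
  if (min(table(y)) < 2)
    stop("loo_crossval: need >= 2 examples per class")
  p_half <- ncol(F2X)

  pooled_sel <- if (is_fs && fs_mode == "pooled")
    choose_selection(spec, F2X, Fbase$X, y, seq_len(n), method,
                     fs_threshold, fs_increment)

  pred <- character(n)
  fold_details <- if (detail) vector("list", n)
  models <- if (keep_models) vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    if (is_fs) {
      sel <- if (fs_mode == "pooled") pooled_sel
             else choose_selection(spec, F2X, Fbase$X, y, train, method,
                                   fs_threshold, fs_increment)
      cols <- selection_cols(method, sel$indexes, p_half)
    } else {
      sel <- NULL
      cols <- seq_len(ncol(Fbase$X))
    }
    model <- train_classifier(spec, Fbase$X[train, cols, drop = FALSE],
                              y[train])
    pred[i] <- predict(model, Fbase$X[i, cols, drop = FALSE])
    if (detail)
      fold_details[[i]] <- list(threshold = sel$threshold,
                                indexes = sel$indexes,
                                n_features = length(cols))
    if (keep_models) models[[i]] <- model
  }

  truth <- as.character(y)
  conf <- c(TP_D = 100 * mean(truth == "AD" & pred == "AD"),
            FP_D = 100 * mean(truth == "AD" & pred == "AV"),
            FP_V = 100 * mean(truth == "AV" & pred == "AD"),
            TP_V = 100 * mean(truth == "AV" & pred == "AV"))
  structure(list(pred = pred, truth = truth,
                 accuracy_pct = 100 * mean(pred == truth),
                 confusion_pct = conf, n_folds = n,
                 channel = serps$channel, method = method,
                 n_avg = serps$n_avg, classifier = spec$kind,
                 fs_mode = if (is_fs) fs_mode else NA_character_,
                 details = if (detail) fold_details,
                 models = if (keep_models) models),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s | %s | SEP%d | %s: accuracy %.1f%% (%d folds)\n",
              x$channel, x$method, x$n_avg, toupper(x$classifier),
              x$accuracy_pct, x$n_folds))
  invisible(x)
}

#' Confusion matrix in percent of all folds
#'
#' 2 x 2 table in the reporting layout: rows = true target (D = attended D,
#' V = attended V), columns = predicted; entries are percentages of all
#' folds and sum to 100. The trace equals the accuracy.
#'
#' @param result a `cv_result`.
#' @return 2 x 2 numeric matrix.
#' @export
confusion_table <- function(result) {
  if (result$n_folds < 1) stop("confusion_table: empty result")
  m <- matrix(result$confusion_pct[c("TP_D", "FP_D", "FP_V", "TP_V")],
              nrow = 2, byrow = TRUE,
              dimnames = list(truth = c("D", "V"),
                              predicted = c("D", "V")))
  m
}
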