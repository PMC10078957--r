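#' F1 feature vector: concatenated sERP pair
#'
#' Joins the i-th consecutive pair of averaged, downsampled sERP waveforms
#' of one class: [sERP(ADSD_i) || sERP(ADSV_i)] for class AD, and
#' [sERP(AVSD_i) || sERP(AVSV_i)] for class AV. The first 60 samples are
#' always the D-stimulation response.
#'
#' @param serps a [cluster_serps()] result.
#' @param i group index (1..m).
#' @param class "AD" or "AV".
#' @return list with `values` (length 120 at defaults) and `label`.
#' @export
extract_f1 <- function(serps, i, class = c("AD", "AV")) {
  class <- match.arg(class)
  if (i < 1 || i > serps$m) stop("extract_f1: group index out of range")
  values <- if (class == "AD") c(serps$ADSD[i, ], serps$ADSV[i, ])
            else c(serps$AVSD[i, ], serps$AVSV[i, ])
  list(values = unname(values), label = class)
}

#' F2 feature vector: within-condition difference wave
#'
#' The i-th difference wave of one class: diffsERP(AD_i) = sERP(ADSD_i) -
#' sERP(ADSV_i) for class AD, analogously for AV.
#'
#' @inheritParams extract_f1
#' @return list with `values` (length 60 at defaults) and `label`.
#' @export
extract_f2 <- function(serps, i, class = c("AD", "AV")) {
  class <- match.arg(class)
  if (i < 1 || i > serps$m) stop("extract_f2: group index out of range")
  values <- if (class == "AD") diff_serp(serps$ADSD[i, ], serps$ADSV[i, ])
            else diff_serp(serps$AVSD[i, ], serps$AVSV[i, ])
  list(values = unname(values), label = class)
}

#' Select sample indexes by amplitude threshold
#'
#' Returns the (ascending, 1-based) indexes of samples whose rectified
#' diffsERP(ADAV) amplitude equals or exceeds the threshold.
#'
#' @param adav the between-condition grand difference wave.
#' @param threshold_uV non-negative amplitude threshold, microvolts.
#' @return integer vector (possibly empty).
#' @export
select_indexes <- function(adav, threshold_uV) {
  if (threshold_uV < 0) stop("select_indexes: threshold must be >= 0")
  which(abs(adav) >= threshold_uV)
}

#' Sweep the amplitude-threshold selection
#'
#' Iterates thresholds 0, increment, 2*increment, ... applied to the
#' rectified diffsERP(ADAV), recording the selected index set at each step,
#' and stops before the first threshold that selects nothing. Index sets
#' are nested and non-increasing in size.
#'
#' @param adav the grand difference wave.
#' @param increment threshold step in microvolts.
#' @return object of class `selection_sweep`: list with `thresholds` and
#'   `index_sets` (parallel lists).
#' @export
sweep_selection <- function(adav, increment = 0.1) {
  if (increment <= 0) stop("sweep_selection: increment must be > 0")
  thresholds <- numeric(0)
  index_sets <- list()
  k <- 0
  repeat {
    thr <- k * increment
    idx <- select_indexes(adav, thr)
    if (length(idx) == 0) break
    thresholds <- c(thresholds, thr)
    index_sets[[length(index_sets) + 1]] <- idx
    k <- k + 1
  }
  structure(list(thresholds = thresholds, index_sets = index_sets),
            class = "selection_sweep")
}

#' Apply a selected index set to form an FS feature vector
#'
#' FS1 takes the selected samples of both sERPs of the pair and joins them
#' (D-stimulation samples first, length 2 * |indexes|); FS2 takes the
#' selected samples of the difference wave (length |indexes|).
#'
#' @param method "FS1" or "FS2".
#' @param serps a [cluster_serps()] result.
#' @param i group index.
#' @param class "AD" or "AV".
#' @param indexes non-empty integer index set from [select_indexes()].
#' @return list with `values`, `label`, `indexes`.
#' @export
apply_selection <- function(method = c("FS1", "FS2"), serps, i,
                            class = c("AD", "AV"), indexes) {
  method <- match.arg(method)
  class <- match.arg(class)
  if (length(indexes) == 0)
    stop("apply_selection: empty index set (caller must fall back to threshold 0)")
  values <- if (method == "FS1") {
    f <- extract_f1(serps, i, class)
    p <- length(f$values) / 2
    c(f$values[seq_len(p)][indexes], f$values[p + seq_len(p)][indexes])
  } else {
    extract_f2(serps, i, class)$values[indexes]
  }
  list(values = unname(values), label = class, indexes = indexes)
}

#' Full feature matrix for a serp_set
#'
#' Stacks the per-group feature vectors of both classes into a matrix with
#' the AD examples first. With `indexes` given, F1/F2 become their selected
#' FS1/FS2 counterparts.
#'
#' @param serps a [cluster_serps()] result.
#' @param method "F1" or "F2".
#' @param indexes optional index set (selection applied when non-NULL).
#' @return list with `X` (2m x p matrix) and `y` (factor, levels AD/AV).
#' @export
feature_matrix <- function(serps, method = c("F1", "F2"), indexes = NULL) {
  method <- match.arg(method)
  one <- function(i, cl) {
    if (is.null(indexes)) {
      if (method == "F1") extract_f1(serps, i, cl)$values
      else extract_f2(serps, i, cl)$values
    } else {
      fsm <- if (method == "F1") "FS1" else "FS2"
      apply_selection(fsm, serps, i, cl, indexes)$values
    }
  }
  X <- rbind(do.call(rbind, lapply(seq_len(serps$m), one, cl = "AD")),
             do.call(rbind, lapply(seq_len(serps$m), one, cl = "AV")))
  colnames(X) <- paste0("s", seq_len(ncol(X)))
  y <- factor(rep(c("AD", "AV"), each = serps$m), levels = c("AD", "AV"))
  list(X = X, y = y)
}
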