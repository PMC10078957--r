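#' Assign kept epochs to the four attention-by-location clusters
#'
#' Partitions the artifact-free epochs by (attended location, stimulated
#' location) into the clusters ADSD, ADSV, AVSD, AVSV, preserving
#' acquisition order within each cluster (required for consecutive-trial
#' averaging).
#'
#' @param epochs an `epoch_set` (after rejection; only kept epochs enter).
#' @return object of class `cluster_set`: list with `epochs`, `clusters`
#'   (named list of epoch indices) and `counts`.
#' @export
assign_clusters <- function(epochs) {
  keep <- which(epochs$kept)
  key <- paste0("A", epochs$events$attended_location[keep],
                "S", epochs$events$location[keep])
  keys <- c("ADSD", "ADSV", "AVSD", "AVSV")
  clusters <- lapply(keys, function(k) keep[key == k])
  names(clusters) <- keys
  structure(list(epochs = epochs, clusters = clusters,
                 counts = vapply(clusters, length, integer(1))),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set>", paste(names(x$counts), x$counts, sep = "=",
                             collapse = " "), "\n")
  invisible(x)
}

#' Balance clusters and form consecutive averaging groups
#'
#' Computes the common number of averages m = min over clusters of
#' floor(size / n_avg), truncates every cluster to its first m * n_avg
#' trials (i.e. the last trials of larger clusters are discarded), and
#' partitions each cluster into m consecutive non-overlapping groups of
#' n_avg trials in acquisition order.
#'
#' @param cluster_set a [assign_clusters()] result.
#' @param n_avg trials per average (3, 5 or 10 in the standard pipeline).
#' @param max_groups optional cap on m (keeps the first `max_groups`
#'   consecutive groups per cluster), for fixed-size analysis designs.
#' @return object of class `grouped_clusters`: list with `groups` (per
#'   cluster, a list of m index vectors), `m`, `n_avg`, `epochs`.
#' @export
balance_and_group <- function(cluster_set, n_avg, max_groups = NULL) {
  sizes <- cluster_set$counts
  too_small <- names(sizes)[sizes < n_avg]
  if (length(too_small))
    stop("balance_and_group: insufficient trials in cluster ",
         paste(too_small, collapse = ", "),
         sprintf(" (need >= %d)", n_avg))
  m <- min(sizes %/% n_avg)
  if (!is.null(max_groups)) m <- min(m, as.integer(max_groups))
  groups <- lapply(cluster_set$clusters, function(idx) {
    idx <- idx[seq_len(m * n_avg)]
    split(idx, rep(seq_len(m), each = n_avg))
  })
  structure(list(groups = groups, m = m, n_avg = as.integer(n_avg),
                 epochs = cluster_set$epochs),
            class = "grouped_clusters")
}

#' Average a group of single-trial SEPs on one channel
#'
#' Pointwise arithmetic mean of the 400 ms post-stimulus windows of the
#' given epochs on the given channel.
#'
#' @param epochs an `epoch_set`.
#' @param idx epoch indices forming the group.
#' @param channel channel label.
#' @return numeric sERP waveform of `post` samples (480 at defaults).
#' @export
average_group <- function(epochs, idx, channel) {
  post_idx <- (epochs$pre + 1):(epochs$pre + epochs$post)
  block <- epochs$data[channel, post_idx, idx, drop = FALSE]
  rowMeans(matrix(block, nrow = epochs$post))
}

#' Downsample a sERP waveform
#'
#' Default is plain decimation (every `factor`-th sample starting at the
#' first post-stimulus sample), taking 480 samples to 60 (150 Hz
#' equivalent); the 25 Hz low-pass of the preprocessing leaves negligible
#' energy above the new Nyquist. Block-averaging is available as an
#' alternative.
#'
#' @param w numeric waveform whose length is divisible by `factor`.
#' @param factor downsampling factor.
#' @param method "decimate" or "blockmean".
#' @return downsampled waveform; the equivalent rate is attached as the
#'   `rate_hz` attribute when the input carries one.
#' @export
downsample_wave <- function(w, factor = 8, method = c("decimate", "blockmean")) {
  method <- match.arg(method)
  if (length(w) %% factor != 0)
    stop("downsample_wave: waveform length not divisible by the factor")
  out <- switch(method,
                decimate = w[seq(1, length(w), by = factor)],
                blockmean = colMeans(matrix(w, nrow = factor)))
  out
}

#' Within-condition difference wave
#'
#' Subtracts the V-stimulation sERP from the D-stimulation sERP of the same
#' condition: diffsERP(AD) = sERP(ADSD) - sERP(ADSV) and diffsERP(AV) =
#' sERP(AVSD) - sERP(AVSV).
#'
#' @param w_d,w_v equal-length sERP waveforms (D-stim and V-stim).
#' @return the pointwise difference.
#' @export
diff_serp <- function(w_d, w_v) {
  if (length(w_d) != length(w_v))
    stop("diff_serp: waveform lengths differ")
  w_d - w_v
}

#' Between-condition grand difference wave
#'
#' diffsERP(ADAV) = mean of the AD difference waves minus mean of the AV
#' difference waves, pointwise; the selection signal for FS1/FS2.
#'
#' @param diffs_AD,diffs_AV matrices (rows = examples) or lists of
#'   equal-length difference waves.
#' @return numeric waveform.
#' @export
grand_diff <- function(diffs_AD, diffs_AV) {
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  a <- as_mat(diffs_AD); v <- as_mat(diffs_AV)
  if (is.null(a) || is.null(v) || nrow(a) == 0 || nrow(v) == 0)
    stop("grand_diff: empty difference-wave list")
  colMeans(a) - colMeans(v)
}

#' Averaged, downsampled sERPs for all clusters on one channel
#'
#' Convenience driver: runs [average_group()] and [downsample_wave()] over
#' every consecutive group of every cluster, producing the per-group sERP
#' matrices that feed feature extraction.
#'
#' @param grouped a [balance_and_group()] result.
#' @param channel channel label.
#' @param ds_factor downsampling factor (8: 480 -> 60 samples).
#' @param ds_method passed to [downsample_wave()].
#' @return object of class `serp_set`: list of m x 60 matrices ADSD, ADSV,
#'   AVSD, AVSV plus metadata (`m`, `n_avg`, `channel`).
#' @export
cluster_serps <- function(grouped, channel, ds_factor = 8,
                          ds_method = "decimate") {
  stopifnot(inherits(grouped, "grouped_clusters"))
  mats <- lapply(grouped$groups, function(gl) {
    do.call(rbind, lapply(gl, function(idx)
      downsample_wave(average_group(grouped$epochs, idx, channel),
                      ds_factor, ds_method)))
  })
  structure(c(mats, list(m = grouped$m, n_avg = grouped$n_avg,
                         channel = channel)),
            class = "serp_set")
}
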