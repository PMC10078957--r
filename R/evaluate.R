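#' Decision time of the averaging scheme
#'
#' One BCI decision needs `n_avg` averaged trials per stimulation location;
#' with sequential delivery at the inter-stimulus interval this takes
#' n_avg * isi_s * n_locations seconds (4.2 / 7 / 14 s for 3 / 5 / 10
#' averaged trials at 0.7 s ISI and 2 locations).
#'
#' @param n_avg averaged trials per location.
#' @param isi_s inter-stimulus interval, seconds.
#' @param n_locations stimulation locations.
#' @return decision time in seconds.
#' @export
decision_time <- function(n_avg, isi_s = 0.7, n_locations = 2) {
  if (any(c(n_avg, isi_s, n_locations) <= 0))
    stop("decision_time: all arguments must be positive")
  n_avg * isi_s * n_locations
}

#' Information transfer rate in bits per minute
#'
#' Wolpaw-style bits per decision
#' B = log2(N) + P log2(P) + (1 - P) log2((1 - P)/(N - 1)),
#' with the 0 * log(0) limits handled, scaled to bits per minute by the
#' decision time: ITR = B * 60 / T.
#'
#' @param accuracy classification accuracy P in 0..1.
#' @param decision_time_s decision duration T, seconds.
#' @param n_targets number of selectable targets N (>= 2).
#' @return bits per minute.
#' @export
itr_bpm <- function(accuracy, decision_time_s, n_targets = 2) {
  if (any(accuracy < 0 | accuracy > 1))
    stop("itr_bpm: accuracy must lie in [0, 1]")
  if (any(decision_time_s <= 0)) stop("itr_bpm: decision_time_s must be > 0")
  if (n_targets < 2) stop("itr_bpm: n_targets must be >= 2")
  xlx <- function(p) ifelse(p > 0, p * log2(p), 0)
  bits <- log2(n_targets) + xlx(accuracy) +
    ifelse(accuracy < 1,
           (1 - accuracy) * log2((1 - accuracy) / (n_targets - 1)), 0)
  bits * 60 / decision_time_s
}

#' Repeated-measures ANOVA on an accuracy panel
#'
#' One- or two-way within-subject ANOVA with sums-of-squares partitioning,
#' plus Greenhouse-Geisser sphericity correction (epsilon-scaled degrees of
#' freedom and corrected p) for effects with more than one degree of
#' freedom. Effects with zero between-condition variance are reported as
#' F = 0, p = 1.
#'
#' @param panel long-format data.frame with one row per subject x cell.
#' @param dv name of the accuracy column.
#' @param subject name of the subject column.
#' @param within character vector (length 1 or 2) of within-subject factor
#'   columns.
#' @return data.frame with effect, ss, df, error_ss, df_error, f, p,
#'   gg_epsilon, df_gg, df_error_gg, p_gg.
#' @export
rm_anova <- function(panel, dv = "accuracy_pct", subject = "subject",
                     within = c("classifier", "n_avg")) {
  stopifnot(length(within) %in% 1:2,
            all(c(dv, subject, within) %in% names(panel)))
  panel[[subject]] <- factor(panel[[subject]])
  for (w in within) panel[[w]] <- factor(panel[[w]])

  cells <- do.call(interaction, c(panel[within], list(drop = FALSE, sep = ".")))
  tab <- table(panel[[subject]], cells)
  if (any(tab != 1))
    stop("rm_anova: design must be complete and balanced (one value per subject x cell)")

  idata <- unique(panel[within])
  idata <- idata[do.call(order, unname(as.list(idata))), , drop = FALSE]
  rownames(idata) <- NULL
  cell_names <- do.call(paste, c(idata, list(sep = ".")))
  subjects <- levels(panel[[subject]])
  wide <- matrix(NA_real_, length(subjects), nrow(idata),
                 dimnames = list(subjects, cell_names))
  key <- do.call(paste, c(panel[within], list(sep = ".")))
  wide[cbind(as.character(panel[[subject]]), key)] <- panel[[dv]]

  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  mlm <- stats::lm(wide ~ 1)
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  res <- data.frame(effect = effects,
                    ss = ut[effects, "Sum Sq"],
                    df = ut[effects, "num Df"],
                    error_ss = ut[effects, "Error SS"],
                    df_error = ut[effects, "den Df"],
                    f = ut[effects, "F value"],
                    p = ut[effects, "Pr(>F)"],
                    gg_epsilon = NA_real_, df_gg = NA_real_,
                    df_error_gg = NA_real_, p_gg = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  pa <- s$pval.adjustments
  if (!is.null(pa) && nrow(pa) > 0) {
    for (e in intersect(rownames(pa), effects)) {
      k <- match(e, res$effect)
      eps <- pa[e, "GG eps"]
      res$gg_epsilon[k] <- eps
      res$df_gg[k] <- eps * res$df[k]
      res$df_error_gg[k] <- eps * res$df_error[k]
      res$p_gg[k] <- pa[e, "Pr(>F[GG])"]
    }
  }
  # degenerate cells: no between-condition variance
  zero <- res$ss < .Machine$double.eps^0.75
  res$f[zero] <- 0
  res$p[zero] <- 1
  res$p_gg[zero & !is.na(res$p_gg)] <- 1
  res
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Paired two-sided signed-rank test. With no zero differences and no ties
#' the exact null distribution is used (via the signed-rank distribution);
#' otherwise a normal approximation with the Pratt treatment of zeros
#' (zeros are ranked but their ranks are discarded from the statistic) and
#' tie correction. Also reports the standardized z statistic.
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (V, sum of positive ranks), `z`, `p`,
#'   `n_zero`, `all_zero`.
#' @export
signed_rank_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d)]
  n <- length(d)
  n0 <- sum(d == 0)
  if (n0 == n)
    return(list(statistic = 0, z = 0, p = 1, n_zero = n0, all_zero = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d[d != 0]))) || n0 > 0
  if (n0 == 0 && !ties && n <= 50) {
    nz <- n
    v_nz <- v
    p <- if (v_nz > nz * (nz + 1) / 4)
      2 * (1 - psignrank(v_nz - 1, nz)) else 2 * psignrank(v_nz, nz)
    p <- min(1, p)
    mu <- nz * (nz + 1) / 4
    sg <- sqrt(nz * (nz + 1) * (2 * nz + 1) / 24)
    z <- (v_nz - mu) / sg
    return(list(statistic = v_nz, z = z, p = p, n_zero = 0,
                all_zero = FALSE))
  }
  # Pratt: zeros share the lowest ranks but contribute nothing to V
  mu <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
  tie_tab <- table(r[d != 0])
  sg2 <- n * (n + 1) * (2 * n + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sg2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = v, z = z, p = p, n_zero = n0, all_zero = FALSE)
}

#' Pairwise Wilcoxon post-hoc comparisons with Bonferroni correction
#'
#' Runs [signed_rank_test()] on every pair of the supplied paired samples
#' and compares each p-value against alpha / m, where m is the number of
#' comparisons (e.g. 0.05/3 = 0.017 for the three averaging options,
#' 0.05/6 = 0.0083 for the six feature-method pairs).
#'
#' @param samples named list of equal-length paired numeric vectors.
#' @param alpha family-wise significance level.
#' @param comparisons optional 2-column matrix/data.frame of names to
#'   compare; default all pairs.
#' @return data.frame with pair, statistic, z, p, threshold, significant,
#'   all_zero.
#' @export
wilcoxon_posthoc <- function(samples, alpha = 0.05, comparisons = NULL) {
  stopifnot(is.list(samples), length(samples) >= 2,
            !is.null(names(samples)))
  if (is.null(comparisons)) {
    comparisons <- t(utils::combn(names(samples), 2))
  }
  comparisons <- as.matrix(comparisons)
  m <- nrow(comparisons)
  thr <- alpha / m
  rows <- lapply(seq_len(m), function(i) {
    a <- comparisons[i, 1]; b <- comparisons[i, 2]
    tst <- signed_rank_test(samples[[a]], samples[[b]])
    data.frame(pair = paste(a, "vs", b),
               statistic = tst$statistic, z = tst$z, p = tst$p,
               threshold = thr,
               significant = !tst$all_zero && tst$p < thr,
               all_zero = tst$all_zero,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
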