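# brute-force within-subject sums of squares for a two-factor design
brute_rm_ss <- function(panel) {
  wide_mean <- function(f) tapply(panel$acc, panel[[f]], mean)
  grand <- mean(panel$acc)
  n_s <- length(unique(panel$subject))
  a_lev <- sort(unique(panel$A)); b_lev <- sort(unique(panel$B))
  m_a <- tapply(panel$acc, panel$A, mean)
  m_b <- tapply(panel$acc, panel$B, mean)
  m_ab <- tapply(panel$acc, list(panel$A, panel$B), mean)
  m_s <- tapply(panel$acc, panel$subject, mean)
  m_sa <- tapply(panel$acc, list(panel$subject, panel$A), mean)
  m_sb <- tapply(panel$acc, list(panel$subject, panel$B), mean)
  ss_a <- n_s * length(b_lev) * sum((m_a - grand)^2)
  ss_b <- n_s * length(a_lev) * sum((m_b - grand)^2)
  ss_ab <- n_s * sum((m_ab - outer(m_a - grand, m_b - grand, "+") - grand)^2)
  err_a <- length(b_lev) *
    sum((m_sa - outer(m_s - grand, m_a - grand, "+") - grand)^2)
  err_b <- length(a_lev) *
    sum((m_sb - outer(m_s - grand, m_b - grand, "+") - grand)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab,
       err_a = err_a, err_b = err_b)
}

test_that("decision time scales with trials, ISI and locations", {
  expect_equal(decision_time(3), 4.2)
  expect_equal(decision_time(5), 7)
  expect_equal(decision_time(10), 14)
  expect_equal(decision_time(1, 1, 1), 1)
  expect_error(decision_time(0), "positive")
})

test_that("ITR reproduces the two-target perfect-accuracy rates", {
  expect_equal(round(itr_bpm(1, decision_time(3)), 2), 14.29)
  expect_equal(round(itr_bpm(1, decision_time(5)), 2), 8.57)
  expect_equal(round(itr_bpm(1, decision_time(10)), 2), 4.29)
  expect_equal(itr_bpm(0.5, 7), 0)          # chance carries no information
  expect_equal(itr_bpm(1, 60), 1)           # one bit per minute
})

test_that("ITR is monotone in accuracy and inverse in decision time", {
  p <- seq(0.5, 1, by = 0.05)
  expect_true(all(diff(itr_bpm(p, 7)) > 0))
  expect_equal(itr_bpm(0.9, 14), itr_bpm(0.9, 7) / 2)
})

test_that("two-way repeated-measures ANOVA matches brute-force sums of squares", {
  set.seed(11)
  panel <- expand.grid(subject = paste0("s", 1:6),
                       A = c("lda", "svm"), B = c("n3", "n5", "n10"),
                       stringsAsFactors = FALSE)
  panel$acc <- 70 + 3 * (panel$A == "svm") + 2 * (panel$B == "n10") +
    rep(rnorm(6, 0, 4), 6) + rnorm(36, 0, 2)
  res <- rm_anova(panel, dv = "acc", subject = "subject",
                  within = c("A", "B"))
  oracle <- brute_rm_ss(panel)
  expect_equal(res$ss[res$effect == "A"], oracle$ss_a)
  expect_equal(res$ss[res$effect == "B"], oracle$ss_b)
  expect_equal(res$ss[res$effect == "A:B"], oracle$ss_ab)
  expect_equal(res$error_ss[res$effect == "A"], oracle$err_a)
  expect_equal(res$error_ss[res$effect == "B"], oracle$err_b)
  # F from the SS partition
  f_a <- (oracle$ss_a / 1) / (oracle$err_a / 5)
  expect_equal(res$f[res$effect == "A"], f_a)
  expect_equal(res$df[res$effect == "B"], 2)
  expect_equal(res$df_error[res$effect == "B"], 10)
  # GG correction reported for the 3-level factor only
  expect_false(is.na(res$p_gg[res$effect == "B"]))
  expect_true(is.na(res$p_gg[res$effect == "A"]))
  expect_true(res$df_gg[res$effect == "B"] <= 2)
})

test_that("ANOVA degenerate and invariance properties hold", {
  panel <- expand.grid(subject = paste0("s", 1:5),
                       A = c("x", "y"), B = c("p", "q"),
                       stringsAsFactors = FALSE)
  panel$acc <- 75                                   # all cells identical
  res <- rm_anova(panel, dv = "acc", subject = "subject",
                  within = c("A", "B"))
  expect_equal(res$f, rep(0, 3))
  expect_equal(res$p, rep(1, 3))

  # per-subject offsets only: within-subject F unchanged by the offsets
  set.seed(21)
  panel$acc <- 70 + rnorm(20, 0, 3)
  res0 <- rm_anova(panel, dv = "acc", subject = "subject",
                   within = c("A", "B"))
  panel2 <- panel
  panel2$acc <- panel$acc + rep(c(5, -8, 12, 0, -3), 4)
  res1 <- rm_anova(panel2, dv = "acc", subject = "subject",
                   within = c("A", "B"))
  expect_equal(res1$f, res0$f, tolerance = 1e-8)

  # missing cell -> error
  expect_error(rm_anova(panel[-1, ], dv = "acc", subject = "subject",
                        within = c("A", "B")), "balanced")
})

test_that("one-way repeated-measures ANOVA runs with a single factor", {
  set.seed(31)
  panel <- expand.grid(subject = paste0("s", 1:8),
                       method = c("F1", "F2", "FS1", "FS2"),
                       stringsAsFactors = FALSE)
  panel$acc <- 72 + 4 * (panel$method %in% c("FS1", "FS2")) + rnorm(32, 0, 3)
  res <- rm_anova(panel, dv = "acc", subject = "subject", within = "method")
  expect_equal(nrow(res), 1)
  expect_equal(res$df, 3)
  expect_equal(res$df_error, 21)
  expect_false(is.na(res$gg_epsilon))
})

test_that("null accuracy panels rarely reject (type-I calibration)", {
  rejections <- 0L
  n_sim <- 120
  set.seed(41)
  for (i in seq_len(n_sim)) {
    panel <- expand.grid(subject = paste0("s", 1:8),
                         A = c("x", "y"), B = c("p", "q", "r"),
                         stringsAsFactors = FALSE)
    panel$acc <- 70 + rep(rnorm(8, 0, 4), 6) + rnorm(48, 0, 2)
    res <- rm_anova(panel, dv = "acc", subject = "subject",
                    within = c("A", "B"))
    if (res$p[res$effect == "A"] < 0.05) rejections <- rejections + 1L
  }
  # 95% binomial band around 0.05 for 120 simulations
  expect_gte(rejections, 1)
  expect_lte(rejections, 13)
})

test_that("signed-rank test: exact agreement, zero handling, thresholds", {
  x <- c(1.1, 2.3, 0.7, 3.1, 2.0, 1.4, 0.2, 2.8)
  y <- c(0.8, 2.9, 0.3, 2.0, 2.5, 0.7, 0.4, 1.9)  # distinct |differences|
  ours <- signed_rank_test(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p, ref$p.value)
  expect_equal(ours$statistic, unname(ref$statistic))

  # identical samples: all-zero differences, flagged and non-significant
  z <- signed_rank_test(x, x)
  expect_true(z$all_zero)
  expect_equal(z$p, 1)

  # Pratt handling keeps zeros in the ranking
  a <- c(0, 0, 1, 2, 3, 4, 5, 6)
  b <- numeric(8)
  pr <- signed_rank_test(a, b)
  expect_false(pr$all_zero)
  expect_lt(pr$p, 0.05)
})

test_that("post-hoc Bonferroni thresholds match the comparison count", {
  set.seed(51)
  s <- list(SEP3 = rnorm(10, 60, 5), SEP5 = rnorm(10, 66, 5),
            SEP10 = rnorm(10, 75, 5))
  res3 <- wilcoxon_posthoc(s)
  expect_equal(nrow(res3), 3)
  expect_equal(round(unique(res3$threshold), 3), 0.017)

  s4 <- c(s, list(SEP20 = rnorm(10, 78, 5)))
  res6 <- wilcoxon_posthoc(s4)
  expect_equal(nrow(res6), 6)
  expect_equal(round(unique(res6$threshold), 4), 0.0083)

  # self-comparison is never significant
  same <- wilcoxon_posthoc(list(a = s$SEP3, b = s$SEP3))
  expect_false(same$significant)
})
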