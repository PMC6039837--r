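#' @title Group statistics for graph measures
#'
#' @description
#' Responder vs non-responder differences are tested per feature with a
#' non-parametric two-way ANOVA (factors: responding to VNS, sedation
#' status) whose null distribution is built by bootstrap resampling of
#' reduced-model residuals (10,000 resamples by default); raw p-values are
#' corrected across the nine features with the Benjamini-Hochberg false
#' discovery rate at the 0.05 level. Controls are compared to each patient
#' group with a two-sided rank test.
#' @name groupstats
NULL

# residual sum of squares of y projected on the column space of Q (thin Q of
# a QR decomposition), vectorized over columns of y
rss_after <- function(Q, Y) colSums(Y^2) - colSums(crossprod(Q, Y)^2)

#' Bootstrap non-parametric two-way ANOVA
#'
#' Fits the main-effects model `y ~ a + b` (interaction omitted; the
#' unbalanced design has near-empty interaction cells) and computes the
#' observed Type-II F statistic for each factor. The null distribution of a
#' factor's F is built by resampling, with replacement, the residuals of the
#' reduced model (that factor removed), adding them to the reduced-model
#' fitted values, and re-fitting; p = (1 + #\{F_boot >= F_obs\}) /
#' (n_boot + 1).
#'
#' @param y numeric response.
#' @param factor_a,factor_b two-level factors (e.g. responding, sedation).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @return list with `p` (named p-values for `a` and `b`), `f_obs`,
#'   `n_boot`.
#' @export
bootstrap_two_way_anova <- function(y, factor_a, factor_b, n_boot = 10000L,
                                    seed = 1L) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(y) == length(a), length(y) == length(b))
  if (nlevels(a) < 2 || nlevels(b) < 2 ||
      any(table(a) < 2) || any(table(b) < 2))
    stop("each factor needs at least 2 levels with at least 2 observations")
  if (stats::var(y) == 0) stop("response is constant: F undefined")
  n <- length(y)
  X_full <- stats::model.matrix(~ a + b)
  X_a <- stats::model.matrix(~ b)   # reduced: factor a removed
  X_b <- stats::model.matrix(~ a)
  Qf <- qr.Q(qr(X_full)); Qa <- qr.Q(qr(X_a)); Qb <- qr.Q(qr(X_b))
  df_res <- n - ncol(X_full)
  df_a <- ncol(X_full) - ncol(X_a)
  df_b <- ncol(X_full) - ncol(X_b)

  f_stat <- function(Y, Qred, df_num) {
    r_full <- rss_after(Qf, Y)
    r_red <- rss_after(Qred, Y)
    ((r_red - r_full) / df_num) / (r_full / df_res)
  }
  ym <- matrix(y, ncol = 1L)
  f_obs <- c(a = f_stat(ym, Qa, df_a), b = f_stat(ym, Qb, df_b))

  boot_p <- function(Qred, df_num, f0, k) {
    fit_red <- Qred %*% crossprod(Qred, ym)
    res_red <- drop(ym - fit_red)
    idx <- with_seed(child_seed(seed, k),
                     matrix(sample.int(n, n * n_boot, replace = TRUE),
                            nrow = n))
    Yb <- matrix(res_red[idx], nrow = n) + drop(fit_red)
    fb <- f_stat(Yb, Qred, df_num)
    (1 + sum(fb >= f0)) / (n_boot + 1)
  }
  p <- c(a = boot_p(Qa, df_a, f_obs[["a"]], 1L),
         b = boot_p(Qb, df_b, f_obs[["b"]], 2L))
  list(p = p, f_obs = f_obs, n_boot = n_boot)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; significance is
#' declared at adjusted p < 0.05.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values.
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) < 1L) stop("need at least one p-value")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' BH critical values (i/m) * q
#'
#' The step-up critical value for the i-th smallest of m p-values at FDR
#' level q, reported for transparency next to the adjusted p-values.
#'
#' @param m number of tests.
#' @param q FDR level (default 0.05).
#' @return numeric vector of length `m`.
#' @export
bh_critical <- function(m, q = 0.05) seq_len(m) / m * q

#' Rank test of controls against a patient group
#'
#' Two-sided rank-based location test. The default is the unpaired rank-sum
#' (Mann-Whitney) form, exact for small untied samples, normal approximation
#' with tie correction otherwise. A paired signed-rank mode is available but
#' requires equal sample sizes.
#'
#' @param x_controls,y_group the two samples (each n >= 2).
#' @param paired use the paired signed-rank form (errors on unequal n).
#' @return the two-sided p-value.
#' @export
controls_vs_group_test <- function(x_controls, y_group, paired = FALSE) {
  stopifnot(length(x_controls) >= 2, length(y_group) >= 2)
  if (paired && length(x_controls) != length(y_group))
    stop("paired test requires equal sample sizes")
  pooled <- c(x_controls, y_group)
  if (diff(range(pooled)) == 0) stop("all values tied across both samples")
  suppressWarnings(
    stats::wilcox.test(x_controls, y_group, paired = paired,
                       alternative = "two.sided")$p.value)
}

#' Group-difference table for all nine features
#'
#' Mirrors the group-comparison layout: per measure x band, group
#' mean +/- SD, the bootstrap two-way ANOVA p-values for responding and
#' sedation (responding corrected across the nine features by FDR, with the
#' BH critical value column), and FDR-corrected rank tests of controls vs
#' each patient group.
#'
#' @param averaged run-averaged feature table from [cohort_features()].
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return data.frame, one row per measure x band.
#' @export
group_stats_table <- function(averaged, n_boot = 10000L, seed = 1L) {
  measures <- c("cpl", "transitivity", "modularity")
  bands <- intersect(c("theta", "alpha", "beta"), unique(averaged$band))
  rows <- list()
  idx <- 0L
  for (meas in measures) for (b in bands) {
    idx <- idx + 1L
    sub <- averaged[averaged$band == b, ]
    pat <- sub[sub$group != "control", ]
    bt <- bootstrap_two_way_anova(pat[[meas]],
                                  factor_a = pat$group == "responder",
                                  factor_b = pat$sedation,
                                  n_boot = n_boot,
                                  seed = child_seed(seed, idx))
    gm <- function(g) sub[[meas]][sub$group == g]
    fmt <- function(v) c(mean = mean(v), sd = stats::sd(v))
    rows[[idx]] <- data.frame(
      measure = meas, band = b,
      controls_mean = fmt(gm("control"))[["mean"]],
      controls_sd = fmt(gm("control"))[["sd"]],
      responders_mean = fmt(gm("responder"))[["mean"]],
      responders_sd = fmt(gm("responder"))[["sd"]],
      nonresponders_mean = fmt(gm("non_responder"))[["mean"]],
      nonresponders_sd = fmt(gm("non_responder"))[["sd"]],
      p_vns = bt$p[["a"]], p_sedation = bt$p[["b"]],
      p_ctrl_vs_resp = controls_vs_group_test(gm("control"), gm("responder")),
      p_ctrl_vs_nonresp = controls_vs_group_test(gm("control"),
                                                 gm("non_responder")))
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$bh_critical <- bh_critical(m)[rank(out$p_vns, ties.method = "first")]
  out$p_vns_fdr <- fdr_adjust(out$p_vns)
  out$p_ctrl_vs_resp_fdr <- fdr_adjust(out$p_ctrl_vs_resp)
  out$p_ctrl_vs_nonresp_fdr <- fdr_adjust(out$p_ctrl_vs_nonresp)
  out
}
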