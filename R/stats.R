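# The statistical battery: normality screening, the non-parametric
# method-comparison tests, and the sphericity diagnostics used before
# repeated-measures modelling. Standard tests are delegated to their stock
# implementations (stats::, nortest::); this module adds the input
# contracts, mean ranks, degenerate-input flags and the Mauchly /
# Huynh-Feldt computations.

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' Lilliefors-corrected one-sample KS test against a normal distribution
#' with mean and sd estimated from the sample (the correction is required
#' because the hypothesized parameters are estimated, as is the case when
#' screening empirical accuracy or correlation samples).
#'
#' @param sample Numeric vector, `n >= 5`, non-constant.
#' @return List: `D` (statistic), `p`.
#' @export
ks_normality <- function(sample) {
  if (length(sample) < 5L) stop_field("ks_normality: need n >= 5 (got %d)", length(sample))
  if (stats::sd(sample) == 0) stop_field("ks_normality: constant sample")
  r <- nortest::lillie.test(sample)
  list(D = unname(r$statistic), p = unname(r$p.value))
}

as_method_matrix <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m) || any(!is.finite(m))) stop_field("method matrix has missing or non-finite cells")
  m
}

#' Friedman test across methods
#'
#' Ranks methods within each observation row (mid-ranks on ties) and tests
#' for a discrepancy in average ranks.
#'
#' @param m Observations x methods matrix (e.g. per-trial accuracies, one
#'   column per transform).
#' @return List: `chi2`, `df`, `p`, `mean_ranks` (named per column).
#' @export
friedman_test <- function(m) {
  m <- as_method_matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) stop_field("friedman_test: need >= 2 rows and columns")
  r <- stats::friedman.test(m)
  ranks <- t(apply(m, 1, rank))
  mr <- colMeans(ranks)
  names(mr) <- colnames(m)
  chi2 <- unname(r$statistic)
  p <- unname(r$p.value)
  if (is.nan(chi2)) {
    # every row fully tied: the tie-corrected statistic is 0/0; the
    # uncorrected statistic is identically zero
    chi2 <- 0
    p <- 1
  }
  list(chi2 = chi2, df = unname(r$parameter), p = p, mean_ranks = mr)
}

#' Pairwise Wilcoxon signed-rank tests
#'
#' One signed-rank test per column pair (zero differences dropped, as in the
#' standard procedure); optional Holm adjustment.
#'
#' @param m Observations x methods matrix.
#' @param correction `"none"` (default) or `"holm"`.
#' @return Data frame: `method_a`, `method_b`, `W`, `p`, `degenerate`
#'   (TRUE when all paired differences are zero; then `W`/`p` are `NA`).
#' @export
wilcoxon_pairwise <- function(m, correction = c("none", "holm")) {
  correction <- match.arg(correction)
  m <- as_method_matrix(m)
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("m", seq_len(ncol(m)))
  pairs <- utils::combn(ncol(m), 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- m[, a] - m[, b]
    if (all(d == 0)) {
      return(data.frame(method_a = cn[a], method_b = cn[b], W = NA_real_,
                        p = NA_real_, degenerate = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(m[, a], m[, b], paired = TRUE))
    data.frame(method_a = cn[a], method_b = cn[b], W = unname(wt$statistic),
               p = unname(wt$p.value), degenerate = FALSE)
  })
  out <- do.call(rbind, out)
  if (correction == "holm") out$p <- stats::p.adjust(out$p, "holm")
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' @param groups List of numeric samples (>= 2 groups, >= 5 values total).
#' @return List: `H`, `df`, `p`, `flag` (`"all_ties"` when every value is
#'   identical; then `H`/`p` are `NA`).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop_field("kruskal_wallis: need >= 2 groups")
  if (any(lengths(groups) < 1L)) stop_field("kruskal_wallis: empty group")
  x <- unlist(groups)
  if (length(x) < 5L) stop_field("kruskal_wallis: need >= 5 values in total")
  if (length(unique(x)) == 1L) {
    return(list(H = NA_real_, df = length(groups) - 1L, p = NA_real_,
                flag = "all_ties"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  r <- stats::kruskal.test(x, g)
  list(H = unname(r$statistic), df = unname(r$parameter),
       p = unname(r$p.value), flag = NULL)
}

#' Mauchly sphericity test and Huynh-Feldt epsilon
#'
#' Mauchly's W from the covariance of orthonormal contrasts with the usual
#' chi-square approximation; the Huynh-Feldt correction factor from its
#' closed form (via the Greenhouse-Geisser epsilon), clipped at 1.
#'
#' @param data Subjects x conditions matrix (`>= 3` conditions, more
#'   subjects than conditions).
#' @return List: `mauchly_W`, `chi2`, `df`, `p`, `gg_epsilon`,
#'   `huynh_feldt_epsilon`, `flag` (`"singular"` when the contrast
#'   covariance is singular; then the test statistics are `NA`).
#' @export
sphericity_epsilon <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data)
  k <- ncol(data)
  if (k < 3L) stop_field("sphericity_epsilon: need >= 3 conditions (sphericity is trivial for k = 2)")
  if (n <= k) stop_field("sphericity_epsilon: need more subjects than conditions")
  # orthonormal contrasts (normalized Helmert, dropping the constant column)
  Cm <- stats::contr.helmert(k)
  Cm <- sweep(Cm, 2, sqrt(colSums(Cm^2)), "/")
  S <- stats::cov(data)
  Tm <- t(Cm) %*% S %*% Cm
  ev <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < .Machine$double.eps * max(abs(ev))) {
    return(list(mauchly_W = NA_real_, chi2 = NA_real_, df = NA_real_,
                p = NA_real_, gg_epsilon = NA_real_,
                huynh_feldt_epsilon = NA_real_, flag = "singular"))
  }
  km1 <- k - 1
  W <- det(Tm) / (sum(diag(Tm)) / km1)^km1
  dfc <- km1 * (km1 + 1) / 2 - 1
  f <- 1 - (2 * km1^2 + km1 + 2) / (6 * km1 * (n - 1))
  chi2 <- -(n - 1) * f * log(W)
  p <- stats::pchisq(chi2, dfc, lower.tail = FALSE)
  gg <- sum(diag(Tm))^2 / (km1 * sum(Tm^2))
  hf <- min(1, (n * km1 * gg - 2) / (km1 * (n - 1 - km1 * gg)))
  list(mauchly_W = W, chi2 = chi2, df = dfc, p = p, gg_epsilon = gg,
       huynh_feldt_epsilon = hf, flag = NULL)
}
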