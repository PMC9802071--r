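#' Paired two-tailed permutation t test
#'
#' The observed statistic is the parametric paired t statistic; the null
#' distribution is built by randomly sign-flipping the paired differences
#' `n_iter` times. The p value uses the add-one rule
#' `(1 + #{|t_perm| >= |t_obs|}) / (n_iter + 1)`, so it is never zero and is
#' bounded below by `1/(n_iter + 1)`. Cohen's d for paired data (mean
#' difference over the SD of the differences) and its noncentral-t confidence
#' interval are attached.
#'
#' @param a,b Paired numeric samples of equal length (>= 2), no missing pairs.
#' @param n_iter Number of sign-flip permutations.
#' @param seed Optional seed.
#' @param alpha Nominal two-sided level stored alongside its Bonferroni
#'   correction for `m_comparisons` tests.
#' @param m_comparisons Number of planned pairwise comparisons.
#' @return Object of class `perm_ttest`: list with `t`, `p`, `n_iter`, `d`,
#'   `d_ci`, `alpha`, `alpha_corrected`, `n`.
#' @export
paired_perm_ttest <- function(a, b, n_iter = 10000L, seed = NULL,
                              alpha = 0.05, m_comparisons = 3L) {
  if (length(a) != length(b)) stop("paired samples differ in length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  if (anyNA(a) || anyNA(b)) stop("missing pairs are not allowed")
  d <- a - b
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    warning("zero-variance differences; p set to 1")
    res <- list(t = NA_real_, p = 1, n_iter = n_iter, d = NA_real_,
                d_ci = c(NA_real_, NA_real_), alpha = alpha,
                alpha_corrected = bonferroni(alpha, m_comparisons), n = n)
    class(res) <- "perm_ttest"
    return(res)
  }
  t_obs <- mean(d) / (sd_d / sqrt(n))
  if (!is.null(seed)) set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n * n_iter, replace = TRUE), n, n_iter)
  m_perm <- colMeans(signs * d)
  ## sum of squares is sign-invariant, so the permuted SD follows from the mean
  ss <- sum(d^2)
  var_perm <- (ss - n * m_perm^2) / (n - 1)
  var_perm[var_perm < 0] <- 0
  t_perm <- m_perm / (sqrt(var_perm) / sqrt(n))
  t_perm[!is.finite(t_perm)] <- Inf  # zero permuted variance, nonzero mean
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (n_iter + 1)
  dd <- cohens_d_paired(a, b)
  res <- list(t = t_obs, p = p, n_iter = n_iter, d = dd$d, d_ci = dd$ci,
              alpha = alpha, alpha_corrected = bonferroni(alpha, m_comparisons),
              n = n)
  class(res) <- "perm_ttest"
  res
}

#' @export
print.perm_ttest <- function(x, ...) {
  cat(sprintf("Paired permutation t test: t = %.3f, p = %.4g (%d iterations)\n",
              x$t, x$p, x$n_iter))
  cat(sprintf("Cohen's d = %.3f [%.3f, %.3f]; alpha = %.3f (corrected %.3f)\n",
              x$d, x$d_ci[1], x$d_ci[2], x$alpha, x$alpha_corrected))
  invisible(x)
}

#' Cohen's d for paired samples with a noncentral-t confidence interval
#'
#' `d = mean(a - b) / sd(a - b)`. The confidence interval inverts the
#' noncentral t distribution of `t = d * sqrt(n)` over the noncentrality
#' parameter.
#'
#' @param a,b Paired samples.
#' @param conf Confidence level.
#' @return List with `d` and `ci` (length-2 vector).
#' @export
cohens_d_paired <- function(a, b, conf = 0.95) {
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (is.na(s) || s == 0) stop("zero-variance differences; d undefined")
  dd <- mean(d) / s
  t <- dd * sqrt(n)
  lo_p <- (1 + conf) / 2
  hi_p <- (1 - conf) / 2
  ## pt(t, df, ncp) is decreasing in ncp; extend the bracket as needed
  f <- function(ncp, target)
    suppressWarnings(stats::pt(t, df = n - 1, ncp = ncp)) - target
  root <- function(target) tryCatch(
    stats::uniroot(f, target = target, interval = c(t - 10, t + 10),
                   extendInt = "downX", tol = 1e-8)$root,
    error = function(e) NA_real_)
  list(d = dd, ci = c(root(lo_p), root(hi_p)) / sqrt(n))
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Nominal level.
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m` (0.05 over three pairwise comparisons gives 0.0167,
#'   conventionally reported as 0.017).
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

ratings_to_matrix <- function(ratings) {
  item <- paste(ratings$target, ratings$response, sep = " / ")
  M <- tapply(ratings$score, list(item, ratings$rater), mean)
  if (anyNA(M)) {
    miss <- which(is.na(M), arr.ind = TRUE)
    stop("incomplete rater x item matrix; missing cell(s): ",
         paste(utils::head(paste(rownames(M)[miss[, 1]], "x",
                                 colnames(M)[miss[, 2]]), 5L), collapse = "; "))
  }
  M
}

#' Two-way fixed-effects intraclass correlation (consistency)
#'
#' ICC(3,k) — average measures over the k raters — from the two-way ANOVA
#' mean squares, `(MS_items - MS_error) / MS_items`; the single-measures
#' variant ICC(3,1) is available via `type = "single"`. Input is either a
#' complete items x raters matrix or a long rating table
#' (`rater`, `target`, `response`, `scale`, `score`), in which case one ICC
#' per scale is returned. Incomplete matrices are rejected with the missing
#' cells named.
#'
#' @param ratings Matrix or long data frame of ratings.
#' @param type `"average"` (ICC(3,k), default) or `"single"` (ICC(3,1)).
#' @return Named numeric vector of ICCs (one per scale; a matrix input yields
#'   a single unnamed value).
#' @export
icc_two_way_fixed <- function(ratings, type = c("average", "single")) {
  type <- match.arg(type)
  ## balanced two-way ANOVA mean squares in closed form (items can number in
  ## the thousands, so no aov model matrix)
  icc_one <- function(M) {
    n <- nrow(M); k <- ncol(M)
    if (n < 2L || k < 2L) stop("need at least 2 items and 2 raters")
    grand <- mean(M)
    ss_items <- k * sum((rowMeans(M) - grand)^2)
    ss_raters <- n * sum((colMeans(M) - grand)^2)
    ss_error <- sum((M - grand)^2) - ss_items - ss_raters
    msi <- ss_items / (n - 1)
    mse <- ss_error / ((n - 1) * (k - 1))
    if (type == "average") (msi - mse) / msi
    else (msi - mse) / (msi + (k - 1) * mse)
  }
  if (is.matrix(ratings)) return(icc_one(ratings))
  if (!all(c("rater", "scale", "score") %in% names(ratings)))
    stop("long ratings need rater, target, response, scale, score columns")
  vapply(split(ratings, ratings$scale),
         function(x) icc_one(ratings_to_matrix(x)), numeric(1))
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input; r undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
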