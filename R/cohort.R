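#' Cohort quality-control filter on aberrant cell fraction
#'
#' Removes samples whose aberrant cell fraction (ACF) is strictly below
#' \code{min_acf} (default 0.36): low-purity samples yield unreliable
#' allele-specific segmentation. Samples with missing ACF are excluded with
#' a warning, never silently retained.
#'
#' @param cohort data frame with one row per sample, including an
#'   \code{acf} column.
#' @param min_acf exclusion threshold (strictly-below rule: exactly 0.36
#'   is retained).
#' @return The filtered data frame; attributes \code{n_excluded} and
#'   \code{excluded_samples} record the removals.
#' @export
qc_filter <- function(cohort, min_acf = 0.36) {
  if (!"acf" %in% names(cohort)) stop("cohort has no 'acf' column")
  missing_acf <- is.na(cohort$acf)
  if (any(missing_acf))
    warning(sum(missing_acf), " sample(s) with missing ACF excluded: ",
            paste(cohort$sample[missing_acf], collapse = ", "))
  drop <- missing_acf | cohort$acf < min_acf
  out <- cohort[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(drop)
  attr(out, "excluded_samples") <- cohort$sample[drop]
  out
}

#' Per-group medians, quartiles, and average ranking
#'
#' Summarizes scores per group with 25th/50th/75th percentiles (linear
#' interpolation between order statistics), then ranks the groups: for each
#' score the groups are ranked by median (highest = rank 1, ties averaged),
#' and the final \code{ranking} orders groups by the mean of those
#' per-score ranks. Ranks rather than raw medians are averaged because the
#' three signatures live on different scales.
#'
#' @param cohort data frame with a grouping column and score columns.
#' @param group_col name of the grouping column.
#' @param score_cols names of the score columns to summarize.
#' @return Data frame with one row per group: \code{n}, then
#'   \code{<score>_q25/_median/_q75} per score, \code{avg_rank}, and
#'   \code{ranking}.
#' @export
group_medians <- function(cohort, group_col,
                          score_cols = c("ntai", "lst", "hrd_loh")) {
  if (!group_col %in% names(cohort))
    stop("no column '", group_col, "' in cohort")
  groups <- cohort[[group_col]]
  keep <- !is.na(groups)
  if (any(!keep)) {
    warning(sum(!keep), " sample(s) with missing '", group_col,
            "' omitted")
    cohort <- cohort[keep, , drop = FALSE]
    groups <- groups[keep]
  }
  levs <- unique(groups)
  out <- data.frame(group = levs, n = as.numeric(table(groups)[levs]),
                    stringsAsFactors = FALSE)
  names(out)[1L] <- group_col
  med <- matrix(NA_real_, length(levs), length(score_cols),
                dimnames = list(levs, score_cols))
  for (sc in score_cols) {
    qs <- vapply(levs, function(g) {
      stats::quantile(cohort[[sc]][groups == g], c(.25, .5, .75),
                      na.rm = TRUE, names = FALSE, type = 7)
    }, numeric(3))
    out[[paste0(sc, "_q25")]] <- qs[1L, ]
    out[[paste0(sc, "_median")]] <- qs[2L, ]
    out[[paste0(sc, "_q75")]] <- qs[3L, ]
    med[, sc] <- qs[2L, ]
  }
  ranks <- apply(med, 2L, function(v) rank(-v, ties.method = "average"))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1L)
  out$avg_rank <- rowMeans(ranks)
  out$ranking <- rank(out$avg_rank, ties.method = "average")
  out[order(out$ranking), , drop = FALSE]
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and pairwise-complete
#' handling of missing values. When either variable has zero rank variance
#' the coefficient is undefined and \code{NA} is returned with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return rho in [-1, 1], or \code{NA}.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance: Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Rank-sum test for a difference between two groups. For combined sample
#' sizes of at most \code{exact_max} the two-sided p-value is computed by
#' exhaustive enumeration of all \code{choose(n, n_a)} group assignments of
#' the observed (tie-averaged) ranks — valid with ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric score vectors (both nonempty).
#' @param exact_max largest \code{length(a) + length(b)} for which the
#'   exact enumeration is used (default 12).
#' @return \code{list(statistic =, p_value =, method =)} where
#'   \code{statistic} is the rank sum of group \code{a}.
#' @examples
#' wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
wilcoxon_ranksum <- function(a, b, exact_max = 12L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be nonempty")
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  n <- na + nb
  eps <- sqrt(.Machine$double.eps)
  if (n <= exact_max) {
    sums <- utils::combn(r, na, sum)
    p_lo <- mean(sums <= W + eps)
    p_hi <- mean(sums >= W - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p_value = p, method = method)
}

#' Fisher's exact test with sample odds ratio
#'
#' Reports the sample (cross-product) odds ratio \code{(a*d)/(b*c)} of a
#' 2x2 contingency table and the two-sided Fisher exact p-value obtained by
#' summing all hypergeometric table probabilities not exceeding the
#' observed table's probability. A zero off-diagonal (resp. diagonal) cell
#' yields an infinite (resp. zero) odds ratio; the p-value is still
#' computed.
#'
#' @param table 2x2 matrix of non-negative counts (or length-4 vector in
#'   row-major order a, b, c, d), with both margins nonzero.
#' @return \code{list(odds_ratio =, p_value =)}.
#' @examples
#' fisher_odds_ratio(matrix(c(1443, 510, 1177, 1513), 2, byrow = TRUE))
#' @export
fisher_odds_ratio <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2L, 2L, byrow = TRUE)
  if (!all(dim(table) == 2L) || any(table < 0) || any(table != round(table)))
    stop("need a 2x2 table of non-negative integer counts")
  a <- table[1L, 1L]; b <- table[1L, 2L]
  c_ <- table[2L, 1L]; d <- table[2L, 2L]
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("both margins must be nonzero")
  or <- if (b == 0 || c_ == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  # hypergeometric enumeration over all tables with the observed margins
  m <- a + b; n2 <- c_ + d; k <- a + c_
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p_value = min(1, p))
}

#' Pairwise Spearman correlation matrix
#'
#' @param cohort data frame of per-sample scores.
#' @param cols columns to correlate.
#' @return Symmetric matrix of Spearman rho (pairwise-complete).
#' @export
score_correlations <- function(cohort,
                               cols = c("ntai", "lst", "hrd_loh")) {
  k <- length(cols)
  out <- matrix(1, k, k, dimnames = list(cols, cols))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    rho <- suppressWarnings(spearman_rho(cohort[[cols[i]]],
                                         cohort[[cols[j]]]))
    out[i, j] <- out[j, i] <- rho
  }
  out
}
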