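#' Independent two-sample t-test for one community pair
#'
#' Two-sided test of mean(a) - mean(b) with 95% confidence interval
#' taken from the same degrees of freedom. Welch's unequal-variance test
#' is the default; set `var_equal = TRUE` for the pooled-variance
#' version. When both samples are constant the statistic is undefined
#' and the result is flagged degenerate.
#'
#' @param a,b Numeric vectors of member-level values, each of length >= 2.
#' @param var_equal Pool the variances? Default `FALSE` (Welch).
#' @return List with `t`, `df`, `p`, `ci_low`, `ci_high`, `degenerate`.
#' @export
pair_t_test <- function(a, b, var_equal = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  res <- tryCatch(
    t.test(a, b, var.equal = var_equal, conf.level = 0.95),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, degenerate = TRUE))
  }
  list(
    t = unname(res$statistic), df = unname(res$parameter),
    p = res$p.value, ci_low = res$conf.int[1], ci_high = res$conf.int[2],
    degenerate = FALSE
  )
}

#' Hommel-adjusted p-values
#'
#' Stepwise adjusted p-values of Hommel's (1988) closed-testing
#' procedure based on Simes' inequality: for each hypothesis, the
#' adjusted p equals the maximum Simes p-value over all intersection
#' hypotheses containing it. Controls the family-wise error rate and is
#' uniformly more powerful than Bonferroni-Holm.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (NAs allowed and
#'   passed through).
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' hommel_adjust(c(0.01, 0.02, 0.03))
hommel_adjust <- function(p) {
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "hommel")
}

#' Cohen's d (pooled, reported as magnitude)
#'
#' `|mean(a) - mean(b)|` divided by the pooled standard deviation with
#' n - 1 weights. Reported as an absolute magnitude; direction is
#' carried by the t statistic and confidence interval. A zero pooled sd
#' yields `NA`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Non-negative effect size, or `NA` when undefined.
#' @export
#' @examples
#' cohens_d(c(1, 2, 3), c(4, 5, 6))
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  n1 <- length(a); n2 <- length(b)
  pooled <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
                   (n1 + n2 - 2))
  if (pooled == 0) return(NA_real_)
  abs(mean(a) - mean(b)) / pooled
}

effect_bands <- c("very small" = 0.01, "small" = 0.2, "medium" = 0.5,
                  "large" = 0.8, "very large" = 1.2, "huge" = 2.0)

#' Interpret an effect size magnitude
#'
#' Maps d onto the conventional bands (0.01 very small, 0.2 small,
#' 0.5 medium, 0.8 large, 1.2 very large, 2.0 huge). A d between two
#' thresholds is labelled with both band names, e.g. 0.97 is
#' "large-very large"; d of at least 2 is "huge" and d below 0.01 is
#' "very small".
#'
#' @param d Numeric vector of non-negative effect sizes.
#' @return Character vector of band labels (`NA` in, `NA` out).
#' @export
#' @examples
#' effect_size_band(c(0.05, 0.97, 3.18))
effect_size_band <- function(d) {
  stopifnot(is.numeric(d))
  vapply(d, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0) stop("effect size magnitude must be >= 0", call. = FALSE)
    if (x < effect_bands[1]) return(names(effect_bands)[1])
    if (x >= effect_bands[length(effect_bands)]) {
      return(names(effect_bands)[length(effect_bands)])
    }
    i <- max(which(effect_bands <= x))
    paste0(names(effect_bands)[i], "-", names(effect_bands)[i + 1])
  }, character(1))
}

#' Pairwise community comparisons for one score
#'
#' Tests every pair of communities on member-level values of one score:
#' t-test, Hommel adjustment applied jointly across the family of pairs
#' (the family is the set of pairs within this one score), Cohen's d
#' with its interpretation band, and the 95% CI of the mean difference.
#' Pairs are ordered by descending community mean, the higher-scoring
#' community listed first, so the t statistic's sign equals the sign of
#' mean(A) - mean(B).
#'
#' @param members Tibble with a `community` column and the score column.
#' @param metric Name of the score column to compare.
#' @param var_equal Pool variances in the t-tests? Default `FALSE`.
#' @return Tibble with one row per pair: `community_a`, `community_b`,
#'   `metric`, `n_a`, `n_b`, `t`, `df`, `p_raw`, `p_adj`, `ci_low`,
#'   `ci_high`, `d`, `band`, `degenerate`.
#' @export
pairwise_compare <- function(members, metric, var_equal = FALSE) {
  stopifnot(is.data.frame(members), metric %in% names(members),
            "community" %in% names(members))
  vals <- split(members[[metric]], members$community)
  if (length(vals) < 2L) stop("need at least 2 communities", call. = FALSE)
  ord <- order(vapply(vals, mean, numeric(1)), decreasing = TRUE)
  vals <- vals[ord]
  labs <- names(vals)
  k <- length(vals)
  pairs <- utils::combn(k, 2)

  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- vals[[i1]]; b <- vals[[i2]]
    tt <- pair_t_test(a, b, var_equal)
    d <- if (tt$degenerate) NA_real_ else cohens_d(a, b)
    tibble::tibble(
      community_a = labs[i1], community_b = labs[i2], metric = metric,
      n_a = length(a), n_b = length(b),
      t = tt$t, df = tt$df, p_raw = tt$p,
      ci_low = tt$ci_low, ci_high = tt$ci_high,
      d = d, band = effect_size_band(d), degenerate = tt$degenerate
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- hommel_adjust(out$p_raw)
  out[, c("community_a", "community_b", "metric", "n_a", "n_b", "t", "df",
          "p_raw", "p_adj", "ci_low", "ci_high", "d", "band", "degenerate")]
}
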