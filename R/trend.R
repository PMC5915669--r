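#' Per-member least-squares slopes over the interaction sequence
#'
#' For each member and score, the ordinary least-squares slope of the
#' per-post score on the interaction index 1..n — the rank of the post
#' in the member's posting order (by timestamp, ties broken by post id),
#' not calendar time, so unequal gaps between posts are ignored by
#' design. A negative readability slope and a positive lexical-diversity
#' slope both indicate improving writing.
#'
#' The `norm_mean4` score is the post-level `mean4` min-max normalized
#' within community before slope fitting; its scale is only meaningful
#' relative to the community's own score range.
#'
#' @param scored Tibble of scored posts from [score_corpus()].
#' @param metrics Score columns to fit. Defaults to the four grades,
#'   `mean4`, `norm_mean4`, `lexdiv` and `n_words`.
#' @return Long tibble: `community`, `member_id`, `metric`, `n_posts`,
#'   `slope`, `intercept`.
#' @export
member_slopes <- function(scored,
                          metrics = c("fk", "smog", "fog", "linsear",
                                      "mean4", "norm_mean4", "lexdiv",
                                      "n_words")) {
  stopifnot(is.data.frame(scored), nrow(scored) > 0L)
  d <- scored[order(scored$community, scored$member_id,
                    scored$timestamp, scored$post_id), , drop = FALSE]
  if ("norm_mean4" %in% metrics && !("norm_mean4" %in% names(d))) {
    d <- d |>
      dplyr::group_by(.data$community) |>
      dplyr::mutate(norm_mean4 = minmax_normalize(.data$mean4)) |>
      dplyr::ungroup()
  }
  key <- paste(d$community, d$member_id, sep = "\r")
  grp <- match(key, unique(key))
  n_g <- tabulate(grp)
  if (any(n_g < 2L)) stop("members with fewer than 2 posts", call. = FALSE)
  n <- length(n_g)
  starts <- cumsum(c(0L, n_g[-n]))
  x <- seq_along(grp) - starts[grp]          # interaction index within member

  sum_x <- as.vector(rowsum(x, grp))
  sum_x2 <- as.vector(rowsum(x^2, grp))
  sxx <- sum_x2 - sum_x^2 / n_g
  first <- starts + 1L

  res <- lapply(metrics, function(m) {
    y <- d[[m]]
    sum_y <- as.vector(rowsum(y, grp))
    sum_xy <- as.vector(rowsum(x * y, grp))
    slope <- (sum_xy - sum_x * sum_y / n_g) / sxx
    intercept <- sum_y / n_g - slope * sum_x / n_g
    tibble::tibble(
      community = d$community[first], member_id = d$member_id[first],
      metric = m, n_posts = n_g, slope = slope, intercept = intercept
    )
  })
  dplyr::bind_rows(res)
}

#' Community-level summary of member slopes
#'
#' Unweighted mean and standard error of the per-member slopes, by
#' community and score; every member contributes one slope regardless of
#' post count, mirroring the member-equalized aggregation of the
#' cross-sectional summaries.
#'
#' @param slopes Long tibble from [member_slopes()].
#' @return Tibble: `community`, `metric`, `n_members`, `slope_mean`,
#'   `slope_se`.
#' @export
community_slope_summary <- function(slopes) {
  slopes |>
    dplyr::group_by(.data$community, .data$metric) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      slope_mean = mean(.data$slope),
      slope_se = sd(.data$slope) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Pairwise community comparison of member slopes
#'
#' Applies the same machinery as [pairwise_compare()] — Welch t-tests,
#' Hommel family adjustment, Cohen's d with bands — to the member-level
#' slopes of one score.
#'
#' @param slopes Long tibble from [member_slopes()].
#' @param metric Which score's slopes to compare.
#' @param var_equal Pool variances? Default `FALSE`.
#' @return Tibble of comparison rows (see [pairwise_compare()]); the
#'   `metric` column is `"slope_<metric>"`.
#' @export
compare_slopes <- function(slopes, metric, var_equal = FALSE) {
  sub <- slopes[slopes$metric == metric, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no slopes for metric ", metric, call. = FALSE)
  wide <- tibble::tibble(community = sub$community, value = sub$slope)
  names(wide)[2] <- paste0("slope_", metric)
  pairwise_compare(wide, paste0("slope_", metric), var_equal)
}
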