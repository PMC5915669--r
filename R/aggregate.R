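#' Per-member mean scores
#'
#' First step of the two-step (member, then community) aggregation: the
#' unweighted arithmetic mean of every score over each member's posts,
#' within community. Averaging per member first prevents one prolific
#' member from skewing a community mean — each member contributes
#' exactly one vote downstream.
#'
#' @param scored Tibble of scored posts from [score_corpus()].
#' @param min_posts Guard threshold: an error is raised if any member
#'   has fewer posts (filtering should have removed them). Default 4.
#' @return Tibble with one row per (community, member): `n_posts` and
#'   means `fk`, `smog`, `fog`, `linsear`, `mean4`, `lexdiv`, `words`.
#' @export
member_means <- function(scored, min_posts = 4) {
  ms <- scored |>
    dplyr::group_by(.data$community, .data$member_id) |>
    dplyr::summarise(
      n_posts = dplyr::n(),
      fk = mean(.data$fk), smog = mean(.data$smog), fog = mean(.data$fog),
      linsear = mean(.data$linsear), mean4 = mean(.data$mean4),
      lexdiv = mean(.data$lexdiv), words = mean(.data$n_words),
      .groups = "drop"
    )
  if (any(ms$n_posts < min_posts)) {
    stop("members with fewer than ", min_posts,
         " posts present; run filter_corpus() first", call. = FALSE)
  }
  ms
}

#' Min-max normalize a vector of member means
#'
#' Maps `x` to `(x - min) / (max - min)`. In a degenerate group where
#' all values coincide, every value maps to 0.5 with a warning.
#'
#' @param x Numeric vector (member mean scores within one community).
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))
minmax_normalize <- function(x) {
  stopifnot(is.numeric(x))
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("degenerate group: all values identical, mapping to 0.5",
            call. = FALSE)
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Add the normalized composite score to member summaries
#'
#' Default variant normalizes each member's `mean4` (the mean of the
#' four grades) within its community. The `"per_metric"` variant
#' min-max normalizes each of the four grades separately within the
#' community and averages the four normalized values, for sensitivity
#' analysis.
#'
#' @param members Tibble from [member_means()].
#' @param variant `"mean4"` (default) or `"per_metric"`.
#' @return `members` with a `norm_mean4` column in `[0, 1]`.
#' @export
add_normalized_scores <- function(members, variant = c("mean4", "per_metric")) {
  variant <- match.arg(variant)
  if (variant == "mean4") {
    members |>
      dplyr::group_by(.data$community) |>
      dplyr::mutate(norm_mean4 = minmax_normalize(.data$mean4)) |>
      dplyr::ungroup()
  } else {
    members |>
      dplyr::group_by(.data$community) |>
      dplyr::mutate(norm_mean4 = (minmax_normalize(.data$fk) +
                                    minmax_normalize(.data$smog) +
                                    minmax_normalize(.data$fog) +
                                    minmax_normalize(.data$linsear)) / 4) |>
      dplyr::ungroup()
  }
}

#' Community-level summary (second aggregation step)
#'
#' Mean and standard error (sample sd over sqrt of member count) of
#' every member-level score, per community. Communities are ordered by
#' ascending normalized composite when present.
#'
#' @param members Tibble from [member_means()], optionally with
#'   `norm_mean4` from [add_normalized_scores()].
#' @return Tibble with one row per community: `n_members` and
#'   `<score>_mean`, `<score>_se` columns.
#' @export
community_summary <- function(members) {
  cols <- intersect(
    c("fk", "smog", "fog", "linsear", "mean4", "norm_mean4", "lexdiv", "words"),
    names(members)
  )
  counts <- table(members$community)
  if (any(counts < 2)) {
    stop("communities with fewer than 2 members: SE undefined (",
         paste(names(counts)[counts < 2], collapse = ", "), ")",
         call. = FALSE)
  }
  out <- members |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      dplyr::across(dplyr::all_of(cols),
                    list(mean = mean, se = ~ sd(.x) / sqrt(length(.x)))),
      .groups = "drop"
    )
  if ("norm_mean4_mean" %in% names(out)) {
    out <- out[order(out$norm_mean4_mean), , drop = FALSE]
  }
  out
}
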