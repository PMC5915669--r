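#' Cross-sectional community analysis, end to end
#'
#' Runs the full first-question pipeline: inclusion filtering, per-post
#' scoring, member-equalized aggregation with per-community min-max
#' normalization, community summary, and pairwise community comparisons
#' (Welch t, Hommel-adjusted p, Cohen's d with band, 95% CI) for each
#' requested score.
#'
#' @param posts Tibble of posts (from [read_corpus()] or
#'   [generate_corpus()]).
#' @param min_words,min_posts Filter thresholds (defaults 5 and 4).
#' @param markers Deletion markers.
#' @param var_equal Pool variances in t-tests? Default `FALSE`.
#' @param norm_variant Normalization variant for
#'   [add_normalized_scores()].
#' @param compare_metrics Member-level scores to compare pairwise.
#' @param out_dir Optional directory: when given, results are written
#'   there as CSV/JSON via [write_report()].
#' @return List with `filter_report`, `scored`, `members`,
#'   `community_summary`, `comparisons` (named list of comparison
#'   tibbles).
#' @export
run_analysis <- function(posts, min_words = 5, min_posts = 4,
                         markers = c("[deleted]", "[removed]"),
                         var_equal = FALSE,
                         norm_variant = "mean4",
                         compare_metrics = c("norm_mean4", "mean4", "lexdiv"),
                         out_dir = NULL) {
  fl <- filter_corpus(posts, min_words, min_posts, markers)
  if (nrow(fl$posts) == 0L) {
    stop("no posts survive filtering; report: ",
         paste(names(fl$report), unlist(fl$report), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  scored <- score_corpus(fl$posts)
  members <- add_normalized_scores(member_means(scored, min_posts),
                                   variant = norm_variant)
  summary <- community_summary(members)
  comparisons <- NULL
  if (length(unique(members$community)) >= 2L) {
    comparisons <- lapply(compare_metrics, function(m) {
      pairwise_compare(members, m, var_equal)
    })
    names(comparisons) <- compare_metrics
  }
  res <- list(
    filter_report = fl$report, scored = scored, members = members,
    community_summary = summary, comparisons = comparisons
  )
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

#' Longitudinal trend analysis, end to end
#'
#' Runs the second-question pipeline on the same filtered corpus:
#' per-post scoring, per-member least-squares slopes over the
#' interaction sequence, community slope summaries, and pairwise
#' community comparisons of the member slopes.
#'
#' @inheritParams run_analysis
#' @param slope_metrics Scores to fit slopes for.
#' @param compare_metrics Slopes to compare across communities.
#' @return List with `filter_report`, `slopes`, `slope_summary`,
#'   `comparisons`.
#' @export
run_trend_analysis <- function(posts, min_words = 5, min_posts = 4,
                               markers = c("[deleted]", "[removed]"),
                               var_equal = FALSE,
                               slope_metrics = c("fk", "smog", "fog",
                                                 "linsear", "mean4",
                                                 "norm_mean4", "lexdiv",
                                                 "n_words"),
                               compare_metrics = c("mean4", "lexdiv"),
                               out_dir = NULL) {
  fl <- filter_corpus(posts, min_words, min_posts, markers)
  if (nrow(fl$posts) == 0L) stop("no posts survive filtering", call. = FALSE)
  scored <- score_corpus(fl$posts)
  slopes <- member_slopes(scored, slope_metrics)
  slope_summary <- community_slope_summary(slopes)
  comparisons <- NULL
  if (length(unique(slopes$community)) >= 2L) {
    comparisons <- lapply(compare_metrics, function(m) {
      compare_slopes(slopes, m, var_equal)
    })
    names(comparisons) <- compare_metrics
  }
  res <- list(
    filter_report = fl$report, slopes = slopes,
    slope_summary = slope_summary, comparisons = comparisons
  )
  if (!is.null(out_dir)) write_trend_report(res, out_dir)
  res
}

#' Format p-values for reports
#'
#' Values below 0.001 render as `"<.001"`; others are rounded to two
#' significant digits with the leading zero dropped, as in journal
#' tables. Stored values keep full precision; this affects display only.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  out <- ifelse(p < 0.001, "<.001",
                sub("^0\\.", ".", formatC(signif(p, 2), format = "fg")))
  out[is.na(p)] <- NA_character_
  out
}

#' Format an effect size with its band label
#'
#' @param d Numeric vector of effect sizes.
#' @return Character vector like `"3.18 (huge)"`.
#' @export
format_effect_size <- function(d) {
  ifelse(is.na(d), NA_character_,
         sprintf("%.2f (%s)", d, effect_size_band(d)))
}

#' Write analysis results to a run directory
#'
#' CSV files are the canonical machine-readable output; a plain-text
#' report with journal-style formatting (p below 0.001 as `"<.001"`,
#' effect sizes with band labels) is derived from them.
#'
#' @param results List from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(results$filter_report,
                       file.path(dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(results$community_summary,
            file.path(dir, "community_summary.csv"), row.names = FALSE)
  write.csv(results$members, file.path(dir, "member_summary.csv"),
            row.names = FALSE)
  for (m in names(results$comparisons)) {
    write.csv(results$comparisons[[m]],
              file.path(dir, paste0("compare_", m, ".csv")),
              row.names = FALSE)
  }
  writeLines(render_comparison_text(results$comparisons),
             file.path(dir, "report.txt"))
  invisible(dir)
}

#' Write trend results to a run directory
#'
#' @param results List from [run_trend_analysis()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_trend_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(results$filter_report,
                       file.path(dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(results$slope_summary, file.path(dir, "slope_summary.csv"),
            row.names = FALSE)
  for (m in names(results$comparisons)) {
    write.csv(results$comparisons[[m]],
              file.path(dir, paste0("compare_slope_", m, ".csv")),
              row.names = FALSE)
  }
  writeLines(render_comparison_text(results$comparisons),
             file.path(dir, "trend_report.txt"))
  invisible(dir)
}

render_comparison_text <- function(comparisons) {
  if (is.null(comparisons) || length(comparisons) == 0L) {
    return("no pairwise comparisons (single community)")
  }
  out <- character(0)
  for (m in names(comparisons)) {
    cmp <- comparisons[[m]]
    out <- c(out, paste0("== ", m, " =="),
             sprintf("%s vs %s: t=%.2f, p=%s, p_adj=%s, 95%% CI %.2f to %.2f, d=%s",
                     cmp$community_a, cmp$community_b, cmp$t,
                     format_p_value(cmp$p_raw), format_p_value(cmp$p_adj),
                     cmp$ci_low, cmp$ci_high, format_effect_size(cmp$d)),
             "")
  }
  out
}
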