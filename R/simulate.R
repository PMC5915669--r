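#' Specification of one synthetic community
#'
#' Defines the generative parameters of a community of posting members.
#' Post texts are built from a pseudo-word vocabulary of known syllable
#' structure; readability is controlled through the polysyllable
#' probability and the mean sentence length, lexical diversity through
#' the vocabulary size and the Zipf repetition exponent.
#'
#' Defaults emulate short online-community posts: 20-60 words per post,
#' about 10 words per sentence, 15% polysyllabic word draws and a mild
#' Zipf repetition skew (giving mean grade levels around 8-9 and
#' type-token ratios around 0.85-0.90), with member-to-member
#' heterogeneity so that between-member variance is non-trivial.
#'
#' @param label Community label.
#' @param n_members Number of members.
#' @param posts_min,posts_max Posts per member, sampled uniformly
#'   (`posts_min` must be >= 4 so generated members are regular members).
#' @param words_min,words_max Target words per post, sampled uniformly.
#' @param sentence_length Mean words per sentence.
#' @param member_sd_sentlen SD of the member-level sentence-length shift.
#' @param p_poly Probability that a word draw is polysyllabic (>= 3
#'   syllables).
#' @param member_sd_poly SD of the member-level shift on `p_poly`.
#' @param vocab_size Vocabulary size (pseudo-words).
#' @param vocab_p_poly Fraction of the vocabulary that is polysyllabic.
#'   Kept separate from `p_poly` (the draw probability) so that shifting
#'   or trending the draw probability never changes the lexicon itself.
#' @param zipf_exponent Zipf repetition exponent; larger values repeat
#'   fewer words and lower lexical diversity (0 = uniform sampling).
#' @param trend_poly Per-interaction additive drift on a member's
#'   `p_poly` (readability trend knob).
#' @param trend_sentlen Per-interaction additive drift on a member's
#'   sentence length.
#' @param deleted_rate Probability a post body is replaced by the
#'   `"[deleted]"` marker.
#' @param short_rate Probability a post is replaced by a 1-3 word stub
#'   (fails the minimum-word filter).
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(label, n_members,
                           posts_min = 4L, posts_max = 8L,
                           words_min = 20L, words_max = 60L,
                           sentence_length = 10,
                           member_sd_sentlen = 1,
                           p_poly = 0.15,
                           member_sd_poly = 0.03,
                           vocab_size = 600L,
                           vocab_p_poly = 0.4,
                           zipf_exponent = 0.8,
                           trend_poly = 0,
                           trend_sentlen = 0,
                           deleted_rate = 0,
                           short_rate = 0) {
  stopifnot(posts_min >= 4L, posts_max >= posts_min,
            words_min >= 5L, words_max >= words_min,
            sentence_length >= 3,
            p_poly >= 0, p_poly <= 1,
            deleted_rate >= 0, deleted_rate <= 1,
            short_rate >= 0, short_rate <= 1,
            deleted_rate + short_rate <= 1,
            vocab_size >= 10L, vocab_p_poly >= 0, vocab_p_poly <= 1)
  spec <- list(
    label = label, n_members = as.integer(n_members),
    posts_min = as.integer(posts_min), posts_max = as.integer(posts_max),
    words_min = as.integer(words_min), words_max = as.integer(words_max),
    sentence_length = sentence_length,
    member_sd_sentlen = member_sd_sentlen,
    p_poly = p_poly, member_sd_poly = member_sd_poly,
    vocab_size = as.integer(vocab_size), vocab_p_poly = vocab_p_poly,
    zipf_exponent = zipf_exponent,
    trend_poly = trend_poly, trend_sentlen = trend_sentlen,
    deleted_rate = deleted_rate, short_rate = short_rate
  )
  class(spec) <- "community_spec"
  spec
}

#' Simulation configuration
#'
#' @param seed Integer seed; a fixed seed yields a byte-identical corpus
#'   and manifest.
#' @param communities List of [community_spec()] objects.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, communities) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            length(communities) >= 1L,
            all(vapply(communities, inherits, logical(1), "community_spec")))
  labels <- vapply(communities, function(s) s$label, character(1))
  stopifnot(!anyDuplicated(labels))
  structure(list(seed = as.integer(seed), communities = communities),
            class = "sim_config")
}

#' Build a pseudo-word vocabulary with known syllable counts
#'
#' Words are concatenations of consonant-vowel-consonant units, so each
#' unit is exactly one vowel run and the package syllabifier recovers
#' the constructed syllable count (no terminal "e", no adjacent vowels
#' across units). A fraction `p_poly` of the vocabulary (rounded) is
#' polysyllabic (3-4 units, alternating along the rank order), the rest
#' easy (1-2 units, alternating), so the syllable-by-rank profile — and
#' with it the Zipf-weighted mean syllables per word — is identical
#' across realizations while the word identities stay random. The
#' construction is verified against [count_syllables()] at build time;
#' a mismatch rate above 1% triggers regeneration with a warning.
#'
#' @param vocab_size Number of distinct words (>= 10).
#' @param p_poly Fraction of the vocabulary that is polysyllabic.
#' @param seed Optional seed; `NULL` (default) uses the current RNG
#'   stream.
#' @return Tibble with columns `word` and `syllables`.
#' @export
build_vocabulary <- function(vocab_size, p_poly, seed = NULL) {
  stopifnot(vocab_size >= 10L, p_poly >= 0, p_poly <= 1)
  if (!is.null(seed)) {
    return(with_local_seed(seed, build_vocabulary(vocab_size, p_poly)))
  }
  # Deterministic syllable-by-rank profile: class sizes are the rounded
  # expectation and syllable counts alternate along the rank order, so
  # every realization has the same Zipf-weighted mean syllables per word.
  # Word identities remain random; grade levels then vary only through
  # sampling, not through which words happened to land on top ranks.
  n_poly <- as.integer(round(vocab_size * p_poly))
  if (p_poly > 0 && p_poly < 1) n_poly <- max(1L, min(vocab_size - 1L, n_poly))
  n_easy <- vocab_size - n_poly
  k <- c(rep_len(c(2L, 1L), n_easy), rep_len(c(3L, 4L), n_poly))

  make_words <- function(k) {
    cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
              "v", "z")
    vow <- c("a", "e", "i", "o", "u")
    total <- sum(k)
    units <- paste0(sample(cons, total, replace = TRUE),
                    sample(vow, total, replace = TRUE),
                    sample(cons, total, replace = TRUE))
    collapse_groups(units, k, sep = "")
  }
  words <- make_words(k)
  for (tries in 1:50) {
    dup <- duplicated(words)
    if (!any(dup)) break
    words[dup] <- make_words(k[dup])
  }
  if (anyDuplicated(words)) stop("could not build a unique vocabulary",
                                 call. = FALSE)
  bad <- count_syllables(words) != k
  if (mean(bad) > 0.01) {
    warning("syllable-template failure rate above 1%; regenerating",
            call. = FALSE)
    words[bad] <- make_words(k[bad])
    bad <- count_syllables(words) != k
  }
  stopifnot(mean(bad) <= 0.01)
  tibble::tibble(word = words, syllables = k)
}

# paste contiguous groups of `words` (group sizes in `sizes`) with spaces,
# via one global paste and vectorized substring extraction
collapse_groups <- function(words, sizes, sep = " ") {
  stopifnot(sum(sizes) == length(words))
  big <- paste(words, collapse = sep)
  cum <- cumsum(nchar(words) + nchar(sep))
  last <- cumsum(sizes)
  first <- last - sizes + 1L
  start <- c(1L, cum[-length(cum)] + 1L)[first]
  substring(big, start, cum[last] - nchar(sep))
}

# uniform integer draws on [lo, hi], safe when lo == hi (unlike sample())
runif_int <- function(n, lo, hi) {
  lo + floor(runif(n) * (hi - lo + 1L))
}

# inverse-CDF draw of n ranks under Zipf weights (cdf precomputed)
draw_zipf <- function(n, cdf) {
  if (n == 0L) return(integer(0))
  findInterval(runif(n), cdf) + 1L
}

zipf_cdf <- function(k, s) {
  w <- seq_len(k)^(-s)
  cumsum(w) / sum(w)
}

#' Plug-in expected grade levels for generator parameters
#'
#' First-order approximation of the expected per-post scores at the
#' parameter means (the SMOG square root and Linsear branch make the
#' exact expectation analytically awkward; these plug-in values are
#' used for manifest bookkeeping and ordering checks, not for
#' calibration, which is done by Monte Carlo probing).
#'
#' @param p_poly Polysyllabic draw probability.
#' @param sentence_length Mean words per sentence.
#' @param easy_syllables Mean syllables of an easy word (default 1.5).
#' @param poly_syllables Mean syllables of a polysyllabic word
#'   (default 3.5).
#' @return List with `fk`, `smog`, `fog`, `linsear`, `mean4`.
#' @export
expected_grades <- function(p_poly, sentence_length,
                            easy_syllables = 1.5, poly_syllables = 3.5) {
  L <- sentence_length
  mu_s <- (1 - p_poly) * easy_syllables + p_poly * poly_syllables
  fk <- 0.39 * L + 11.8 * mu_s - 15.59
  smog <- 1.0430 * sqrt(30 * p_poly * L) + 3.1291
  fog <- 0.4 * (L + 100 * p_poly)
  r <- L * (1 + 2 * p_poly)
  linsear <- if (r > 20) r / 2 else r / 2 - 1
  list(fk = fk, smog = smog, fog = fog, linsear = linsear,
       mean4 = (fk + smog + fog + linsear) / 4)
}

#' Generate a synthetic post corpus with known ground truth
#'
#' Samples, for every community in the configuration, member-level
#' parameters (baseline polysyllable probability and sentence length),
#' then post texts word by word from the community's pseudo-word
#' vocabulary under Zipf repetition weights, applying any per-interaction
#' trends to the member parameters. Deleted-marker and too-short
#' contamination is injected at the configured rates. Timestamps are
#' strictly increasing within member. The returned manifest records the
#' parameters behind every member so recovery tests know the truth.
#'
#' @param config A [sim_config()].
#' @return List with `posts` (tibble in [read_corpus()] layout) and
#'   `manifest` (list: `seed`, one entry per community with its spec,
#'   plug-in expected grades, and per-member realized parameters).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    parts <- lapply(config$communities, generate_community)
    posts <- dplyr::bind_rows(lapply(parts, `[[`, "posts"))
    manifest <- list(
      seed = config$seed,
      communities = lapply(parts, `[[`, "truth")
    )
    list(posts = posts, manifest = manifest)
  })
}

generate_community <- function(spec) {
  vocab <- build_vocabulary(spec$vocab_size, spec$vocab_p_poly)
  easy_words <- vocab$word[vocab$syllables < 3L]
  poly_words <- vocab$word[vocab$syllables >= 3L]
  if (length(easy_words) == 0L) stop("vocabulary has no easy words",
                                     call. = FALSE)
  cdf_easy <- zipf_cdf(length(easy_words), spec$zipf_exponent)
  cdf_poly <- if (length(poly_words)) {
    zipf_cdf(length(poly_words), spec$zipf_exponent)
  } else NULL

  nm <- spec$n_members
  member_id <- sprintf("%s-m%05d", spec$label, seq_len(nm))
  p_m <- pmin(0.995, pmax(0.005, spec$p_poly + rnorm(nm, 0, spec$member_sd_poly)))
  L_m <- pmax(3, spec$sentence_length + rnorm(nm, 0, spec$member_sd_sentlen))

  k_m <- runif_int(nm, spec$posts_min, spec$posts_max)
  n_posts <- sum(k_m)
  m_of_post <- rep.int(seq_len(nm), k_m)
  i_of_post <- sequence(k_m)

  p_post <- pmin(0.995, pmax(0, p_m[m_of_post] + spec$trend_poly * (i_of_post - 1)))
  L_post <- pmax(3, L_m[m_of_post] + spec$trend_sentlen * (i_of_post - 1))

  w_target <- runif_int(n_posts, spec$words_min, spec$words_max)
  n_sent <- pmax(1L, as.integer(round(w_target / L_post)))
  total_sent <- sum(n_sent)
  post_of_sent <- rep.int(seq_len(n_posts), n_sent)
  sent_len <- 1L + rpois(total_sent, L_post[post_of_sent] - 1)
  w_post <- as.vector(rowsum(sent_len, post_of_sent))

  total_words <- sum(sent_len)
  post_of_word <- rep.int(seq_len(n_posts), w_post)
  is_poly <- runif(total_words) < p_post[post_of_word]
  if (any(is_poly) && is.null(cdf_poly)) {
    stop("polysyllabic draws requested but vocabulary has no polysyllabic words",
         call. = FALSE)
  }
  words <- character(total_words)
  words[!is_poly] <- easy_words[draw_zipf(sum(!is_poly), cdf_easy)]
  if (any(is_poly)) {
    words[is_poly] <- poly_words[draw_zipf(sum(is_poly), cdf_poly)]
  }

  # sentence casing and terminators
  ends <- cumsum(sent_len)
  starts <- c(1L, ends[-total_sent] + 1L)
  words[starts] <- paste0(toupper(substr(words[starts], 1L, 1L)),
                          substring(words[starts], 2L))
  term <- sample(c(".", "!", "?"), total_sent, replace = TRUE,
                 prob = c(0.9, 0.06, 0.04))
  words[ends] <- paste0(words[ends], term)

  body <- collapse_groups(words, w_post)

  # contamination
  u <- runif(n_posts)
  del <- u < spec$deleted_rate
  shrt <- !del & u < spec$deleted_rate + spec$short_rate
  body[del] <- "[deleted]"
  if (any(shrt)) {
    n_s <- sum(shrt)
    stub_len <- runif_int(n_s, 1L, 3L)
    stub_words <- easy_words[draw_zipf(sum(stub_len), cdf_easy)]
    body[shrt] <- paste0(collapse_groups(stub_words, stub_len), ".")
  }

  # strictly increasing timestamps per member
  base_m <- sort(1.2e9 + floor(runif(nm) * 1e8))
  gaps <- 3600 + floor(runif(n_posts) * 860400)
  cg <- cumsum(gaps)
  first_of_m <- cumsum(c(0L, k_m[-nm])) + 1L
  offset <- cg[first_of_m] - gaps[first_of_m]
  timestamp <- base_m[m_of_post] + cg - offset[m_of_post]

  posts <- tibble::tibble(
    post_id = sprintf("%s-p%06d", spec$label, seq_len(n_posts)),
    member_id = member_id[m_of_post],
    community = spec$label,
    timestamp = timestamp,
    kind = ifelse(i_of_post == 1L, "submission", "comment"),
    body = body
  )
  truth <- list(
    spec = spec,
    expected = expected_grades(
      spec$p_poly, spec$sentence_length,
      easy_syllables = mean(vocab$syllables[vocab$syllables < 3L]),
      poly_syllables = if (length(poly_words)) {
        mean(vocab$syllables[vocab$syllables >= 3L])
      } else NA_real_
    ),
    members = tibble::tibble(
      member_id = member_id, p_poly = p_m, sentence_length = L_m,
      trend_poly = spec$trend_poly, trend_sentlen = spec$trend_sentlen
    )
  )
  list(posts = posts, truth = truth)
}

#' Shift a community spec's polysyllable probability
#'
#' Convenience for constructing a contrast community: returns `spec`
#' with `p_poly` shifted by `delta` (and a new label if given).
#'
#' @param spec A [community_spec()].
#' @param delta Additive shift on `p_poly`.
#' @param label Optional new label.
#' @return A `community_spec`.
#' @export
shift_spec <- function(spec, delta, label = NULL) {
  spec$p_poly <- min(0.995, max(0.005, spec$p_poly + delta))
  if (!is.null(label)) spec$label <- label
  spec
}

# member-level mean4 values for a probe simulation of one community
probe_member_scores <- function(spec, n_members) {
  spec$n_members <- as.integer(n_members)
  spec$trend_poly <- 0
  spec$trend_sentlen <- 0
  spec$deleted_rate <- 0
  spec$short_rate <- 0
  sim <- generate_community(spec)
  scored <- score_corpus(sim$posts)
  member_means(scored)
}

#' Calibrate a polysyllable-probability shift to a target grade effect
#'
#' Acceptance-style experiments specify community contrasts in grade
#' units (a Cohen's d or an absolute shift of the member-mean composite
#' grade), while the generator's knob is the polysyllable probability.
#' This estimates the local derivative d(mean grade)/d(p_poly) and the
#' between-member SD of the mean grade by Monte Carlo probe simulations
#' at `p_poly +/- probe`, and converts the target into a `p_poly` shift.
#'
#' @param spec Reference [community_spec()].
#' @param target_d Target Cohen's d between member-mean composite
#'   grades (mutually exclusive with `target_shift`).
#' @param target_shift Target absolute shift of the member-mean
#'   composite grade.
#' @param probe Probe offset on `p_poly` (default 0.04).
#' @param n_members Members per probe simulation (default 4000).
#' @param seed Seed for the probe simulations.
#' @return List with `delta_p_poly`, `dgrade_dpoly`, `member_sd`,
#'   `target_grade_shift`.
#' @details The derivative is estimated in two stages: a first central
#'   difference at the reference `p_poly` gives a provisional shift,
#'   then the difference is re-centred at the midpoint between the
#'   reference and the shifted value. Without the re-centring the
#'   mildly nonlinear grade response (the SMOG square root) biases the
#'   realized contrast.
#' @export
calibrate_grade_shift <- function(spec, target_d = NULL, target_shift = NULL,
                                  probe = 0.04, n_members = 4000L, seed = 1L) {
  stopifnot(xor(is.null(target_d), is.null(target_shift)))
  with_local_seed(seed, {
    deriv_at <- function(centre_offset) {
      lo <- probe_member_scores(shift_spec(spec, centre_offset - probe),
                                n_members)
      hi <- probe_member_scores(shift_spec(spec, centre_offset + probe),
                                n_members)
      list(
        deriv = (mean(hi$mean4) - mean(lo$mean4)) / (2 * probe),
        sd = sqrt((stats::var(lo$mean4) + stats::var(hi$mean4)) / 2)
      )
    }
    first <- deriv_at(0)
    shift1 <- if (!is.null(target_d)) target_d * first$sd else target_shift
    second <- deriv_at(shift1 / first$deriv / 2)
    # For a d target, the denominator that matters is the pooled sd of
    # the realized pair; the stage-2 probes straddle the midpoint between
    # reference and shifted community, so their sd estimates it directly.
    shift <- if (!is.null(target_d)) target_d * second$sd else target_shift
    list(
      delta_p_poly = shift / second$deriv,
      dgrade_dpoly = second$deriv,
      member_sd = second$sd,
      target_grade_shift = shift
    )
  })
}

#' Calibrate a per-interaction trend to a target grade slope
#'
#' Converts a target longitudinal slope of the per-post composite grade
#' (grade units per interaction) into the generator's per-interaction
#' drift on the polysyllable probability, using a Monte Carlo estimate
#' of the post-level derivative d(mean grade)/d(p_poly) at the
#' operating point.
#'
#' @param spec Reference [community_spec()].
#' @param target_slope Target slope of the composite grade per
#'   interaction (negative = improving readability).
#' @param probe Probe offset on `p_poly` (default 0.03).
#' @param n_members Members per probe simulation (default 2000).
#' @param seed Seed for the probe simulations.
#' @return List with `trend_poly` and `dgrade_dpoly`.
#' @details A member's `p_poly` drifts from the baseline to roughly
#'   `baseline + trend * (posts - 1)` over their posting history, and
#'   the least-squares slope of the grade responds to the *average*
#'   derivative along that path. The derivative is therefore estimated
#'   in two stages: a provisional drift from a central difference at
#'   the baseline, then re-estimation centred at the trajectory
#'   midpoint. Without the re-centring the grade response's curvature
#'   (the SMOG square root grows steeper at lower `p_poly`) biases the
#'   realized slope by several percent.
#' @export
calibrate_trend <- function(spec, target_slope, probe = 0.03,
                            n_members = 2000L, seed = 1L) {
  with_local_seed(seed, {
    post_mean_at <- function(centre_offset) {
      sp <- shift_spec(spec, centre_offset)
      sp$n_members <- as.integer(n_members)
      sp$trend_poly <- 0
      sp$trend_sentlen <- 0
      sp$deleted_rate <- 0
      sp$short_rate <- 0
      mean(score_corpus(generate_community(sp)$posts)$mean4)
    }
    deriv_at <- function(centre_offset) {
      (post_mean_at(centre_offset + probe) -
         post_mean_at(centre_offset - probe)) / (2 * probe)
    }
    k_mid <- (spec$posts_min + spec$posts_max) / 2
    first <- deriv_at(0)
    centre <- (target_slope / first) * (k_mid - 1) / 2
    second <- deriv_at(centre)
    list(trend_poly = target_slope / second, dgrade_dpoly = second)
  })
}
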