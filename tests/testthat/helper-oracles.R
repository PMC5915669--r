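# Independent oracles used across tests. These deliberately use naive,
# enumerative implementations so they share no code with the package.

# Exhaustive closed-testing adjusted p-values: for each hypothesis, the
# maximum over all subsets containing it of the Simes intersection test
# p-value. Feasible for m <= 6 (2^m - 1 subsets).
closed_testing_oracle <- function(p) {
  m <- length(p)
  stopifnot(m >= 1, m <= 10)
  simes <- function(ps) {
    k <- length(ps)
    min(k * sort(ps) / seq_len(k))
  }
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- 0
    for (mask in seq_len(2^m - 1)) {
      S <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      if (i %in% S) best <- max(best, simes(p[S]))
    }
    adj[i] <- min(1, best)
  }
  adj
}

# OLS slope/intercept via lm(), as the reference for the closed-form
# group-sum implementation in member_slopes().
lm_slope <- function(y) {
  x <- seq_along(y)
  unname(coef(lm(y ~ x)))
}

# Drop the bookkeeping attribute read_corpus() attaches, for equality
# comparisons against in-memory corpora.
strip_read_attrs <- function(posts) {
  attr(posts, "n_malformed") <- NULL
  posts
}

# Tibble constructor for hand-built toy posts.
toy_post <- function(id, member, body, community = "c1",
                     timestamp = 1e9 + id, kind = "comment") {
  tibble::tibble(post_id = sprintf("p%03d", id), member_id = member,
                 community = community, timestamp = timestamp,
                 kind = kind, body = body)
}

# Hand-built 12-post toy corpus: 2 deleted posts, 2 short posts, one
# 3-post member. Hand tally: input 12, deleted 2, short 2, distinct
# members {A, C, D} = 3, regular members {A} = 1, retained posts 4.
toy_corpus_12 <- function() {
  long <- "one two three four five six"
  dplyr::bind_rows(
    toy_post(1, "A", long), toy_post(2, "A", long),
    toy_post(3, "A", long), toy_post(4, "A", long),
    toy_post(5, "C", long), toy_post(6, "C", long), toy_post(7, "C", long),
    toy_post(8, "D", "[deleted]"), toy_post(9, "D", "  [deleted]  "),
    toy_post(10, "D", "yes"), toy_post(11, "D", "ok sure thanks"),
    toy_post(12, "D", long)
  )
}

# Small deterministic scored-post table for aggregation tests: two
# communities, hand-pickable values.
toy_scored <- function() {
  mk <- function(member, community, vals, lex, ts0) {
    n <- length(vals)
    tibble::tibble(
      post_id = sprintf("%s-%s-%d", community, member, seq_len(n)),
      member_id = member, community = community,
      timestamp = ts0 + seq_len(n), kind = "comment",
      fk = vals, smog = vals + 1, fog = vals + 2, linsear = vals - 1,
      mean4 = vals + 0.5, lexdiv = lex, n_words = 10L
    )
  }
  dplyr::bind_rows(
    mk("m1", "c1", c(2, 4, 2, 4), 0.8, 0),
    mk("m2", "c1", c(5, 5, 5, 5), 0.9, 100),
    mk("m3", "c1", c(1, 2, 3, 4), 0.7, 200),
    mk("m4", "c2", c(8, 8, 9, 9), 0.6, 300),
    mk("m5", "c2", c(6, 7, 8, 9), 0.5, 400)
  )
}
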