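test_that("surface statistics match hand counts", {
  st <- text_stats("The cat sat.")
  expect_equal(st$n_sentences, 1L)
  expect_equal(st$n_words, 3L)
  expect_equal(st$n_syllables, 3L)
  expect_equal(st$n_polysyllables, 0L)
  expect_equal(st$n_unique_words, 3L)
  for (fx in fixture_texts) {
    st <- text_stats(fx$text)
    expect_equal(st$n_sentences, fx$n_sentences, info = fx$text)
    expect_equal(st$n_words, fx$n_words, info = fx$text)
    expect_equal(st$n_syllables, fx$n_syllables, info = fx$text)
    expect_equal(st$n_polysyllables, fx$n_polysyllables, info = fx$text)
  }
})

test_that("grade formulas reproduce hand arithmetic", {
  st <- list(n_sentences = 1, n_words = 10, n_syllables = 13,
             n_polysyllables = 0, n_complex = 0)
  expect_equal(flesch_kincaid(st), 0.39 * 10 + 11.8 * 1.3 - 15.59)
  expect_equal(flesch_kincaid(list(n_sentences = 1, n_words = 1,
                                   n_syllables = 1)), -3.40, tolerance = 1e-12)
  expect_equal(smog_index(list(n_polysyllables = 0, n_sentences = 30)), 3.1291)
  expect_equal(smog_index(list(n_polysyllables = 30, n_sentences = 30)),
               1.0430 * sqrt(30) + 3.1291)
  expect_equal(gunning_fog(list(n_words = 10, n_sentences = 1, n_complex = 0)),
               4.0)
  expect_equal(gunning_fog(list(n_words = 10, n_sentences = 1, n_complex = 10)),
               44.0)
  # Linsear: r = 20 takes the else branch, r = 25 the main branch
  expect_equal(linsear_write(list(linsear_points = 100, linsear_sentences = 5)),
               9.0)
  expect_equal(linsear_write(list(linsear_points = 100, linsear_sentences = 4)),
               12.5)
  expect_equal(linsear_write(list(linsear_points = 10, linsear_sentences = 1)),
               4.0)
})

test_that("grades are invariant to duplicating the document", {
  texts <- c("The happy dog ran home.",
             "Depression and anxiety affect everyone in the community.",
             "Forum posts need reading. Reading needs strength.")
  for (tx in texts) {
    one <- score_post(tx)
    two <- score_post(paste(tx, tx))
    for (m in c("fk", "smog", "fog", "linsear")) {
      expect_equal(two[[m]], one[[m]], tolerance = 1e-9, info = m)
    }
    expect_lt(two$lexdiv, one$lexdiv + 1e-12)
  }
})

test_that("lexical diversity is the type-token ratio on lowercased tokens", {
  expect_equal(lexical_diversity(c("the", "quick", "brown", "fox")), 1.0)
  expect_equal(lexical_diversity(rep("the", 5)), 0.2)
  expect_equal(score_post("The the cat Cat")$lexdiv, 0.5)
  # k-fold repetition: unique count constant, total scales by k
  toks <- tokenize_words("one two three four two", lowercase = TRUE)
  expect_equal(lexical_diversity(rep(toks, 3)),
               lexical_diversity(toks) / 3)
})

test_that("mean4 is exactly the mean of the four grades", {
  for (fx in fixture_texts[1:5]) {
    v <- score_post(fx$text)
    expect_identical(v$mean4, (v$fk + v$smog + v$fog + v$linsear) / 4)
  }
})

test_that("scalar and vectorized scoring agree bit for bit", {
  sim <- generate_corpus(sim_config(404, list(
    community_spec("x", 12, posts_min = 4, posts_max = 6)
  )))
  sc <- score_corpus(sim$posts)
  for (i in seq_len(nrow(sc))) {
    sp <- score_post(sc$body[i])
    for (m in c("fk", "smog", "fog", "linsear", "mean4", "lexdiv")) {
      expect_identical(sc[[m]][i], sp[[m]])
    }
    expect_equal(sc$n_words[i], sp$n_words)
  }
  # determinism: rescoring gives identical results
  expect_identical(sc, score_corpus(sim$posts))
})

test_that("linsear span truncates at 100 words", {
  w <- rep(c("cat", "communication"), 60)  # alternating easy/hard
  txt <- paste(paste(w[1:110], collapse = " "), ".")
  st <- text_stats(txt)
  expect_equal(st$n_words, 110L)
  # 100-word span: 50 easy (1 pt) + 50 hard (3 pt)
  expect_equal(st$linsear_points, 50L + 150L)
  expect_equal(st$linsear_sentences, 1L)
})

test_that("the four grades are positively correlated over a synthetic corpus", {
  sim <- generate_corpus(sim_config(77, list(
    community_spec("v", 100, posts_min = 5, posts_max = 5,
                   member_sd_poly = 0.08, member_sd_sentlen = 2.5)
  )))
  sc <- score_corpus(sim$posts)
  expect_gte(nrow(sc), 500)
  cors <- cor(sc[, c("fk", "smog", "fog", "linsear")])
  expect_true(all(cors[upper.tri(cors)] > 0))
})
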