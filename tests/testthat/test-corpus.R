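test_that("JSONL round trip preserves posts and counts malformed lines", {
  posts <- toy_corpus_12()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(posts, path)
  back <- strip_read_attrs(read_corpus(path))
  expect_equal(as.data.frame(back), as.data.frame(posts))

  # inject one malformed line among the records
  lines <- readLines(path)
  writeLines(c(lines[1:2], "{not json", lines[3:length(lines)]), path)
  expect_warning(back2 <- read_corpus(path), "malformed")
  expect_equal(nrow(back2), nrow(posts))
  expect_equal(attr(back2, "n_malformed"), 1L)

  # missing required field is skipped too
  writeLines(c(lines, '{"id":"x","author":"a","body":"hello"}'), path)
  expect_warning(back3 <- read_corpus(path), "malformed")
  expect_equal(nrow(back3), nrow(posts))
})

test_that("community filter keeps only requested labels", {
  posts <- dplyr::bind_rows(
    toy_post(1, "A", "one two three four five", community = "depression"),
    toy_post(2, "B", "one two three four five", community = "happy"),
    toy_post(3, "C", "one two three four five", community = "depression"),
    toy_post(4, "D", "one two three four five", community = "loseit"),
    toy_post(5, "E", "one two three four five", community = "happy")
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(posts, path)
  got <- read_corpus(path, communities = "depression")
  expect_equal(nrow(got), 2L)
  expect_true(all(got$community == "depression"))
})

test_that("deletion-marker filter matches the exact trimmed marker only", {
  posts <- dplyr::bind_rows(
    toy_post(1, "A", "[deleted]"),
    toy_post(2, "A", "  [deleted] "),
    toy_post(3, "A", "[deleted] but edited"),
    toy_post(4, "A", "[removed]"),
    toy_post(5, "A", "fine text here today yes"),
    toy_post(6, "A", "more fine text here today")
  )
  res <- filter_deleted(posts)
  expect_equal(res$removed, 3L)
  expect_equal(res$posts$post_id, c("p003", "p005", "p006"))
  # with the [removed] marker disabled
  res2 <- filter_deleted(posts, markers = "[deleted]")
  expect_equal(res2$removed, 2L)
})

test_that("short-post filter uses the metrics tokenizer with boundary at 5", {
  posts <- dplyr::bind_rows(
    toy_post(1, "A", "yes"),
    toy_post(2, "A", "one two three four five"),
    toy_post(3, "A", "one two three four"),
    toy_post(4, "A", "punct! only? counts... words, right."),
    toy_post(5, "A", "!!! ??? ... -- ::")
  )
  res <- filter_short(posts)
  expect_equal(res$removed, 3L)
  expect_equal(res$posts$post_id, c("p002", "p004"))
})

test_that("regular-member selection is per community with boundary at 4", {
  long <- "one two three four five"
  posts <- dplyr::bind_rows(
    lapply(1:5, function(i) toy_post(i, "A", long)),
    lapply(6:9, function(i) toy_post(i, "B", long)),
    lapply(10:11, function(i) toy_post(i, "C", long)),
    # C is regular in c2 even though not in c1
    lapply(12:15, function(i) toy_post(i, "C", long, community = "c2"))
  )
  res <- select_regular_members(posts)
  expect_equal(nrow(res$members), 3L)
  expect_equal(nrow(res$posts), 13L)
  expect_setequal(
    paste(res$members$community, res$members$member_id),
    c("c1 A", "c1 B", "c2 C")
  )
})

test_that("filter pipeline counts reconcile on the hand-tallied toy corpus", {
  res <- filter_corpus(toy_corpus_12())
  expect_equal(res$report$n_input, 12L)
  expect_equal(res$report$n_deleted_removed, 2L)
  expect_equal(res$report$n_short_removed, 2L)
  expect_equal(res$report$n_members_input, 3L)
  expect_equal(res$report$n_regular_members, 1L)
  expect_equal(res$report$n_posts_retained, 4L)
  expect_true(all(res$posts$member_id == "A"))
})

test_that("filtering is idempotent and short-filter precedes member count", {
  res1 <- filter_corpus(toy_corpus_12())
  res2 <- filter_corpus(res1$posts)
  expect_equal(as.data.frame(res2$posts), as.data.frame(res1$posts))
  expect_equal(res2$report$n_deleted_removed, 0L)
  expect_equal(res2$report$n_short_removed, 0L)
  expect_equal(res2$report$n_posts_retained, res1$report$n_posts_retained)

  # a member with 4 posts of which 1 is short must be excluded
  posts <- dplyr::bind_rows(
    toy_post(1, "E", "one two three four five"),
    toy_post(2, "E", "one two three four five"),
    toy_post(3, "E", "one two three four five"),
    toy_post(4, "E", "too short")
  )
  res3 <- filter_corpus(posts)
  expect_equal(res3$report$n_posts_retained, 0L)
  expect_equal(res3$report$n_short_removed, 1L)
})

test_that("empty corpus yields an all-zero report", {
  res <- filter_corpus(toy_corpus_12()[0, ])
  expect_true(all(unlist(res$report) == 0))
  expect_equal(nrow(res$posts), 0L)
})
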