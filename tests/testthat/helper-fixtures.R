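# Pinned formula fixtures: short texts with hand-tabulated surface counts
# (sentences, words, syllables, polysyllabic words, per the package's
# stated segmentation and syllabification rules) and the four grade
# levels computed independently from those counts and frozen here.
# Linsear points for these texts are n_words + 2 * n_polysyllables
# (every text is under 100 words, so the span is the whole text).
fixture_texts <- list(
  list(text = "The cat sat.",
       n_sentences = 1L, n_words = 3L, n_syllables = 3L, n_polysyllables = 0L,
       fk = -2.6199999999999974, smog = 3.1291, fog = 1.2000000000000002, linsear = 0.5),
  list(text = "The happy dog ran home.",
       n_sentences = 1L, n_words = 5L, n_syllables = 6L, n_polysyllables = 0L,
       fk = 0.5200000000000031, smog = 3.1291, fog = 2.0, linsear = 1.5),
  list(text = "Banana bread is beautiful.",
       n_sentences = 1L, n_words = 4L, n_syllables = 8L, n_polysyllables = 2L,
       fk = 9.57, smog = 11.20814326018867, fog = 21.6, linsear = 3.0),
  list(text = "Communication requires understanding. People write sentences.",
       n_sentences = 2L, n_words = 6L, n_syllables = 18L, n_polysyllables = 4L,
       fk = 20.98, smog = 11.20814326018867, fog = 27.86666666666667, linsear = 2.5),
  list(text = "My gym has a queue. Everyone waits.",
       n_sentences = 2L, n_words = 7L, n_syllables = 9L, n_polysyllables = 1L,
       fk = 0.946428571428573, smog = 7.168621630094336, fog = 7.114285714285714, linsear = 1.25),
  list(text = "Science is simple. The ocean is big. Ideas fly.",
       n_sentences = 3L, n_words = 9L, n_syllables = 12L, n_polysyllables = 0L,
       fk = 1.3133333333333361, smog = 3.1291, fog = 1.2000000000000002, linsear = 0.5),
  list(text = "The average estimate was twelve.",
       n_sentences = 1L, n_words = 5L, n_syllables = 9L, n_polysyllables = 2L,
       fk = 7.600000000000001, smog = 11.20814326018867, fog = 18.0, linsear = 3.5),
  list(text = "Depression and anxiety affect everyone in the community.",
       n_sentences = 1L, n_words = 8L, n_syllables = 18L, n_polysyllables = 4L,
       fk = 14.080000000000002, smog = 14.554592549557764, fog = 23.200000000000003, linsear = 7.0),
  list(text = "Happy people write happy sentences about happy things.",
       n_sentences = 1L, n_words = 8L, n_syllables = 15L, n_polysyllables = 1L,
       fk = 9.655000000000001, smog = 8.841846274778883, fog = 8.200000000000001, linsear = 4.0),
  list(text = "Run! Stop! Go now!",
       n_sentences = 3L, n_words = 4L, n_syllables = 4L, n_polysyllables = 0L,
       fk = -3.2699999999999996, smog = 3.1291, fog = 0.5333333333333333, linsear = -0.33333333333333337),
  list(text = "The yellow circle and the purple table sit on the red mat.",
       n_sentences = 1L, n_words = 12L, n_syllables = 16L, n_polysyllables = 0L,
       fk = 4.823333333333334, smog = 3.1291, fog = 4.800000000000001, linsear = 5.0),
  list(text = "Forum posts need reading. Reading needs strength.",
       n_sentences = 2L, n_words = 7L, n_syllables = 10L, n_polysyllables = 0L,
       fk = 2.6321428571428562, smog = 3.1291, fog = 1.4000000000000001, linsear = 0.75),
  list(text = "A banana.",
       n_sentences = 1L, n_words = 2L, n_syllables = 4L, n_polysyllables = 1L,
       fk = 8.790000000000003, smog = 8.841846274778883, fog = 20.8, linsear = 1.0),
  list(text = "Everyone everywhere understands everything.",
       n_sentences = 1L, n_words = 4L, n_syllables = 14L, n_polysyllables = 4L,
       fk = 27.270000000000007, smog = 14.554592549557764, fog = 41.6, linsear = 5.0),
  list(text = "Cake cake cake cake cake. Cake cake cake cake cake.",
       n_sentences = 2L, n_words = 10L, n_syllables = 10L, n_polysyllables = 0L,
       fk = -1.8399999999999999, smog = 3.1291, fog = 2.0, linsear = 1.5),
  list(text = "Health forums help people manage anxiety and depression every day.",
       n_sentences = 1L, n_words = 10L, n_syllables = 19L, n_polysyllables = 3L,
       fk = 10.73, smog = 13.023866798666859, fog = 16.0, linsear = 7.0),
  list(text = "We go. We run. We fly. We sing.",
       n_sentences = 4L, n_words = 8L, n_syllables = 8L, n_polysyllables = 0L,
       fk = -3.01, smog = 3.1291, fog = 0.8, linsear = 0.0),
  list(text = "Understanding readability requires patience and careful analysis.",
       n_sentences = 1L, n_words = 7L, n_syllables = 22L, n_polysyllables = 5L,
       fk = 24.225714285714286, smog = 15.903189008614273, fog = 31.371428571428574, linsear = 7.5),
  list(text = "The quick brown fox jumps over the lazy dog near the tree.",
       n_sentences = 1L, n_words = 12L, n_syllables = 14L, n_polysyllables = 0L,
       fk = 2.8566666666666656, smog = 3.1291, fog = 4.800000000000001, linsear = 5.0),
  list(text = "Schizophrenia is a serious condition. Communities provide support and hope.",
       n_sentences = 2L, n_words = 10L, n_syllables = 21L, n_polysyllables = 3L,
       fk = 11.14, smog = 10.125756701596842, fog = 14.0, linsear = 3.0),
  list(text = "One two three four five six seven eight nine ten eleven twelve.",
       n_sentences = 1L, n_words = 12L, n_syllables = 15L, n_polysyllables = 1L,
       fk = 3.84, smog = 8.841846274778883, fog = 8.133333333333335, linsear = 6.0),
  list(text = "It is what it is.",
       n_sentences = 1L, n_words = 5L, n_syllables = 5L, n_polysyllables = 0L,
       fk = -1.8399999999999999, smog = 3.1291, fog = 2.0, linsear = 1.5)
)

# Hand-syllabified word table, fixed by applying the package's stated
# rules (vowel-run counting with y as a vowel, terminal silent "e"
# except after consonant + "le", one syllable per digit group, clamp to
# 1) before implementation.
syllable_table <- c(
  a = 1, the = 1, cat = 1, dog = 1, tree = 1, happy = 2, cake = 1,
  table = 2, little = 2, apple = 2, orange = 2, banana = 3,
  beautiful = 3, queue = 1, rhythm = 1, my = 1, fly = 1, syllable = 3,
  understanding = 4, communication = 5, readability = 5, science = 1,
  ocean = 2, idea = 2, area = 2, simple = 2, people = 2, sentence = 2,
  paragraph = 3, write = 1, reading = 2, yellow = 2, gym = 1,
  strength = 1, twelve = 1, circle = 2, purple = 2, estimate = 3,
  average = 3, everyone = 3, health = 1, community = 4, online = 2,
  post = 1, forum = 2, anxiety = 3, depression = 3, schizophrenia = 4,
  `2024` = 1, covid19 = 3
)
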