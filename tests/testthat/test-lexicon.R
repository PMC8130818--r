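test_that("tokenizer lowercases, strips urls/mentions and splits hashtags", {
  toks <- tokenize_text("Check https://example.com/x @user #Privacy NOW!!")
  expect_equal(toks[[1]], c("check", "privacy", "now"))
  expect_equal(tokenize_text("don't panic")[[1]], c("don't", "panic"))
  expect_equal(tokenize_text("")[[1]], character(0))
})

test_that("lexicon construction enforces its invariants", {
  expect_s3_class(tiny_lexicon(), "valence_lexicon")
  expect_error(valence_lexicon(c(Good = 1)), "lowercase")
  expect_error(valence_lexicon(c(good = 1), negators = "good"), "unique")
  expect_error(valence_lexicon(c(good = 5)), "\\[-4, 4\\]")
  expect_error(valence_lexicon(c(good = NaN)), "finite")
})

test_that("lexicon file round-trips through the sectioned format", {
  lex <- fixture_lexicon()
  expect_gt(length(lex$entries), 200)
  expect_true(all(c("good", "bad") %in% names(lex$entries)))
  expect_equal(unname(lex$entries["good"]), 1.9)
  expect_true("not" %in% lex$negators)
  expect_equal(unname(lex$boosters["very"]), 0.293)
  # filter keywords must carry no valence (generator relies on this)
  kw_tokens <- unlist(tokenize_text(c(app_keyword_spec()$keywords,
                                      covid_keyword_spec()$keywords)))
  expect_length(intersect(kw_tokens, names(lex$entries)), 0)
})

test_that("rule-based scorer matches hand-computed fixture cases", {
  lex <- tiny_lexicon()
  # single valence token: v / sqrt(v^2 + 15)
  expect_equal(score_text("good", lex), 1.9 / sqrt(1.9^2 + 15), tolerance = 1e-6)
  # negation flips and dampens: 1.9 * -0.74 = -1.406
  expect_equal(score_text("not good", lex), -1.406 / sqrt(1.406^2 + 15),
               tolerance = 1e-6)
  # booster immediately before the token adds toward its sign
  s_vg <- 1.9 + 0.293
  expect_equal(score_text("very good", lex), s_vg / sqrt(s_vg^2 + 15),
               tolerance = 1e-6)
  # booster then negation: (1.9 + 0.293) * -0.74
  s_nvg <- (1.9 + 0.293) * -0.74
  expect_equal(score_text("not very good", lex), s_nvg / sqrt(s_nvg^2 + 15),
               tolerance = 1e-6)
  # negation window reaches 3 tokens back, not 4
  expect_lt(score_text("not the same good", lex), 0)
  expect_gt(score_text("not a b c d good", lex), 0)
  # multiple hits sum before normalization
  s2 <- 1.9 + 3.1
  expect_equal(score_text("good and great", lex), s2 / sqrt(s2^2 + 15),
               tolerance = 1e-6)
  # no lexicon hits score exactly zero
  expect_identical(score_text("nothing relevant here", lex), 0)
  expect_warning(out <- score_text("   ", lex), "empty text")
  expect_identical(out, 0)
})

test_that("mean-polarity channel averages rescaled valences", {
  lex <- tiny_lexicon()
  expect_equal(score_text_mean("good", lex), 1.9 / 4)
  expect_equal(score_text_mean("good bad", lex), mean(c(1.9, -2.5) / 4))
  expect_equal(score_text_mean("not good", lex), (1.9 / 4) * -0.5)
  expect_identical(score_text_mean("nothing here", lex), 0)
})

test_that("scores stay in [-1, 1] on random unicode fuzz", {
  set.seed(42)
  alphabet <- c(letters, " ", " ", "!", "?", "é", "ü", "你",
                "\U0001F600", "#", "@", "'", "0", "7")
  words <- c(names(fixture_lexicon()$entries), "not", "very", "zzz")
  fuzz <- vapply(seq_len(2000), function(i) {
    if (i %% 2 == 0)
      paste(sample(words, sample(1:12, 1), replace = TRUE), collapse = " ")
    else
      paste(sample(alphabet, sample(1:60, 1), replace = TRUE), collapse = "")
  }, character(1))
  a <- suppressWarnings(score_text(fuzz))
  b <- suppressWarnings(score_text_mean(fuzz))
  expect_true(all(is.finite(a)) && all(a >= -1 & a <= 1))
  expect_true(all(is.finite(b)) && all(b >= -1 & b <= 1))
})

test_that("appending an unnegated valence token moves the score monotonically", {
  lex <- fixture_lexicon()
  set.seed(7)
  words <- c(names(lex$entries), "today", "phone", "news")
  for (i in 1:40) {
    base <- paste(sample(words, sample(1:8, 1), replace = TRUE), collapse = " ")
    s0 <- suppressWarnings(score_text(base, lex))
    expect_gte(score_text(paste(base, "excellent"), lex), s0)
    expect_lte(score_text(paste(base, "awful"), lex), s0)
  }
})

test_that("mirrored lexicon flips the score sign exactly", {
  lex <- tiny_lexicon()
  mirror <- valence_lexicon(
    entries = stats::setNames(-lex$entries, names(lex$entries)),
    boosters = lex$boosters, negators = lex$negators)
  texts <- c("good", "not good", "very good bad", "never very great awful")
  expect_equal(score_text(texts, mirror), -score_text(texts, lex))
})

test_that("normalization saturates toward 1 for large raw sums", {
  expect_equal(sentitrace:::normalize_valence(1e6, 15), 1, tolerance = 1e-6)
  expect_equal(sentitrace:::normalize_valence(-1e6, 15), -1, tolerance = 1e-6)
  expect_identical(sentitrace:::normalize_valence(0, 15), 0)
})

test_that("emphasis rules only apply behind the flag", {
  lex <- tiny_lexicon()
  plain <- score_text("GOOD", lex)
  expect_equal(plain, score_text("good", lex))
  emph <- score_text("GOOD", lex, emphasis = TRUE)
  expect_gt(emph, plain)
  bang <- score_text("good!!!", lex, emphasis = TRUE)
  expect_gt(bang, score_text("good", lex, emphasis = TRUE))
})
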