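test_that("ensemble config enforces weight and threshold invariants", {
  expect_error(sentiment_ensemble(weight_a = 0.5, weight_b = 0.6), "equal 1")
  expect_error(sentiment_ensemble(weight_a = -0.1, weight_b = 1.1), "\\[0, 1\\]")
  expect_error(sentiment_ensemble(positive_threshold = 0), "positive_threshold")
  expect_error(sentiment_ensemble(negative_threshold = 0.1), "negative_threshold")
  ens <- sentiment_ensemble()
  expect_equal(unname(coef(ens)), c(0.48, 0.52))
})

test_that("weighted averaging matches direct arithmetic and is affine", {
  ens <- sentiment_ensemble(weight_a = 0.48, weight_b = 0.52)
  expect_equal(combine_lexicon(0.5, 0.5, ens), 0.5)
  expect_equal(combine_lexicon(1.0, 0.0, ens), 0.48)
  expect_equal(combine_lexicon(0.0, 1.0, ens), 0.52)
  half <- sentiment_ensemble(weight_a = 0.5, weight_b = 0.5)
  expect_equal(combine_lexicon(-0.2, 0.6, half), 0.2)
  set.seed(1)
  a <- stats::runif(1000, -1, 1); b <- stats::runif(1000, -1, 1)
  expect_equal(combine_lexicon(a, b, ens), 0.48 * a + 0.52 * b)
  expect_true(all(abs(combine_lexicon(a, b, ens)) <= 1))
  # affinity: a shift of delta in channel A moves the output by w_a * delta
  d <- 0.125
  expect_equal(combine_lexicon(a + d, b, ens) - combine_lexicon(a, b, ens),
               rep(0.48 * d, length(a)), tolerance = 1e-12)
})

test_that("score-to-label thresholds map boundaries to the non-neutral classes", {
  ens <- sentiment_ensemble()   # thresholds +/- 0.05
  expect_equal(score_to_label(c(0, 0.049, -0.049), ens), rep("neutral", 3))
  expect_equal(score_to_label(0.05, ens), "positive")
  expect_equal(score_to_label(-0.05, ens), "negative")
  expect_equal(score_to_label(-0.06, ens), "negative")
  expect_equal(score_to_label(c(1, -1), ens), c("positive", "negative"))
})

test_that("fusion rule table matches the hard-coded oracle on all 9 cells", {
  oracle <- data.frame(
    lexicon_label   = rep(c("positive", "neutral", "negative"), each = 3),
    contextual_label = rep(c("positive", "neutral", "negative"), times = 3),
    final_label     = c("positive", "positive", "positive",   # lexicon positive
                        "positive", "neutral", "negative",    # lexicon neutral
                        "positive", "neutral", "negative"),   # lexicon negative
    stringsAsFactors = FALSE)
  ens <- sentiment_ensemble()
  for (i in seq_len(9))
    expect_equal(fuse(oracle$lexicon_label[i], oracle$contextual_label[i], ens),
                 oracle$final_label[i],
                 label = sprintf("cell (%s, %s)", oracle$lexicon_label[i],
                                 oracle$contextual_label[i]))
  tab <- fusion_table(ens)
  merged <- merge(tab, oracle, by = c("lexicon_label", "contextual_label"))
  expect_equal(merged$final_label.x, merged$final_label.y)
  # the two stated branches: positive -> lexicon; neutral/negative -> contextual
  expect_equal(fuse("positive", "negative", ens), "positive")
  expect_equal(fuse("neutral", "negative", ens), "negative")
})

test_that("alternative fusion reading branches on the contextual label", {
  alt <- sentiment_ensemble(fusion = "contextual_branch")
  expect_equal(fuse("negative", "positive", alt), "negative")
  expect_equal(fuse("neutral", "positive", alt), "neutral")
  expect_equal(fuse("positive", "neutral", alt), "neutral")
  expect_equal(fuse("positive", "negative", alt), "negative")
})

test_that("classify_corpus hits all 9 fusion cells on an engineered corpus", {
  cells <- expand.grid(lex = c(0.5, 0, -0.5),
                       ctx = c("positive", "neutral", "negative"),
                       stringsAsFactors = FALSE)
  posts <- make_posts(sprintf("a=%g b=%g ctx=%s", cells$lex, cells$lex, cells$ctx))
  ens <- test_ensemble(weight_a = 0.5)
  sc <- predict(ens, posts)
  lex_lab <- score_to_label(cells$lex, ens)
  expect_equal(sc$lexicon_label, lex_lab)
  expect_equal(sc$contextual_label, cells$ctx)
  expect_equal(sc$final_label, fuse(lex_lab, cells$ctx, ens))
  expect_equal(sc$lexicon_ensemble_score, cells$lex)
})

test_that("classification is deterministic and text-driven", {
  posts <- make_posts(rep("good covid tracing app news", 2))
  sc <- classify_corpus(posts)
  cols <- setdiff(names(sc), "post_id")
  expect_equal(as.list(sc[1, cols]), as.list(sc[2, cols]))
  empty <- classify_corpus(posts[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  expect_true(all(sentitrace:::SCORE_COLUMNS %in% names(empty)))
})

test_that("with the contextual channel mirroring the lexicon, fusion is the identity", {
  register_test_channels()
  posts <- make_posts(sprintf("a=%g b=%g", c(0.6, 0, -0.6), c(0.6, 0, -0.6)))
  # contextual channel reproducing the lexicon label exactly
  register_scorer("echo_ctx", function(text)
    score_to_label(suppressWarnings(as.numeric(
      ifelse(grepl("a=", text), sub(".*a=(-?[0-9.]+).*", "\\1", text), "0"))),
      sentiment_ensemble()), type = "label", overwrite = TRUE)
  ens <- sentiment_ensemble(weight_a = 0.5, weight_b = 0.5,
                            channel_a = "test_a", channel_b = "test_b",
                            contextual = "echo_ctx")
  sc <- predict(ens, posts)
  expect_equal(sc$final_label, sc$lexicon_label)
})

test_that("channel failures flag posts and surface in diagnostics", {
  register_test_channels()
  register_scorer("fragile", function(text) {
    if (length(text) == 1L && grepl("boom", text)) stop("scorer exploded")
    out <- rep(0.5, length(text))
    if (any(grepl("boom", text))) stop("scorer exploded")
    out
  }, type = "polarity", overwrite = TRUE)
  posts <- make_posts(c("fine one", "boom here", "fine two"))
  ens <- sentiment_ensemble(channel_a = "fragile", channel_b = "test_b",
                            contextual = "test_ctx")
  sc <- predict(ens, posts)
  d <- attr(sc, "diagnostics")
  expect_equal(d$n_failed, 1L)
  expect_equal(d$failed_ids, posts$post_id[2])
  expect_true(is.na(sc$final_label[2]))
  expect_false(anyNA(sc$final_label[-2]))
})

test_that("scorer registry enforces the contract on a probe battery", {
  expect_error(register_scorer("bad_range", function(text) rep(1.5, length(text)),
                               type = "polarity"), "range")
  expect_error(register_scorer("bad_label", function(text) rep("meh", length(text)),
                               type = "label"), "labels outside")
  counter <- new.env(); counter$i <- 0
  expect_error(register_scorer("nondet", function(text) {
    counter$i <- counter$i + 1
    rep(if (counter$i %% 2) 0.1 else 0.2, length(text))
  }, type = "polarity", deterministic = TRUE), "deterministic")
  register_scorer("dup_test", function(text) rep(0, length(text)),
                  type = "polarity", overwrite = TRUE)
  expect_error(register_scorer("dup_test", function(text) rep(0, length(text)),
                               type = "polarity"), "already registered")
  expect_true(all(c("lexicon_a", "lexicon_b", "keyword_context") %in%
                    list_scorers()$name))
})
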