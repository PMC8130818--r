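scored_fixture <- function(scores, labels, timestamps, platforms = "platform_a",
                           region = NA_character_, latitude = NA_real_,
                           longitude = NA_real_) {
  sc <- make_posts(rep("x", length(scores)), timestamp = timestamps,
                   platform = platforms, region = region,
                   latitude = latitude, longitude = longitude)
  sc$lexicon_a_score <- sc$lexicon_b_score <- sc$lexicon_ensemble_score <- scores
  sc$lexicon_label <- sc$contextual_label <- sc$final_label <- labels
  sc
}

test_that("overall proportions match a brute-force counting oracle", {
  labels <- c(rep("positive", 25), rep("negative", 3), rep("neutral", 5))
  sc <- scored_fixture(rep(0, 33), labels, "2020-03-02T12:00:00Z")
  p <- overall_proportions(sc)
  expect_equal(unname(p), c(25, 5, 3) / 33)
  expect_equal(sum(p), 1)
  one <- scored_fixture(0, "negative", "2020-03-02T12:00:00Z")
  expect_equal(unname(overall_proportions(one)), c(0, 0, 1))
  expect_error(overall_proportions(sc[0, , drop = FALSE]), "empty")
})

test_that("weekly pooled mean equals the grand mean across platforms", {
  sc <- scored_fixture(c(0.2, 0.4, 0.9), rep("positive", 3),
                       c("2020-03-02T01:00:00Z", "2020-03-04T01:00:00Z",
                         "2020-03-08T23:00:00Z"),
                       platforms = c("platform_a", "platform_a", "platform_b"))
  wk <- weekly_series(sc)
  expect_equal(nrow(wk), 1)
  expect_equal(wk$mean_score, 0.5)
  expect_equal(wk$n_a, 2); expect_equal(wk$n_b, 1)
  # equal-platform weighting is the alternative, by flag
  wk_eq <- weekly_series(sc, weighting = "equal")
  expect_equal(wk_eq$mean_score, mean(c(mean(c(0.2, 0.4)), 0.9)))
})

test_that("weekly series covers every ISO week in the span, empty weeks flagged", {
  sc <- scored_fixture(c(0.5, -0.5), c("positive", "negative"),
                       c("2020-03-01T12:00:00Z", "2020-10-31T12:00:00Z"))
  wk <- weekly_series(sc)
  # 2020-03-01 falls in ISO week 2020-W09, 2020-10-31 in 2020-W44
  expect_equal(nrow(wk), 36)
  expect_equal(wk$iso_week[1], 9)
  expect_equal(wk$iso_year[1], 2020)
  expect_equal(wk$iso_week[36], 44)
  expect_true(all(wk$n[2:35] == 0))
  expect_true(all(is.na(wk$mean_score[wk$n == 0])))
  expect_equal(sum(wk$n), 2)
})

test_that("weekly and regional aggregation conserve counts and ignore order", {
  for (seed in 1:5) {
    spec <- generator_spec(n_posts = 300, seed = seed, p_geo = 0.7)
    sc <- classify_corpus(generate_corpus(spec))
    wk <- weekly_series(sc)
    expect_equal(sum(wk$n_a + wk$n_b), nrow(sc))
    # pooled weekly mean equals the grand mean over that week's posts
    d <- as.Date(format(sc$timestamp, "%Y-%m-%d", tz = "UTC"))
    ws <- sentitrace:::iso_week_start(d)
    for (i in which(wk$n > 0)) {
      expect_equal(wk$mean_score[i],
                   mean(sc$lexicon_ensemble_score[ws == wk$week_start[i]]),
                   tolerance = 1e-12)
    }
    rs <- region_summaries(sc, region_lookup = uk_counties())
    expect_equal(sum(rs$n_posts), sum(!is.na(sc$region)))
    # permutation invariance
    perm <- sc[sample.int(nrow(sc)), , drop = FALSE]
    wk2 <- weekly_series(perm)
    expect_equal(wk2, wk)
    rs2 <- region_summaries(perm, region_lookup = uk_counties())
    expect_equal(as.data.frame(rs2)[order(rs2$region_id), ],
                 as.data.frame(rs)[order(rs$region_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("region summaries match a direct computation oracle", {
  sc <- scored_fixture(c(0.8, 0.6, -0.5, 0.1),
                       c("positive", "positive", "negative", "neutral"),
                       "2020-03-02T12:00:00Z",
                       region = c("region-a", "region-a", "region-b", NA))
  rs <- region_summaries(sc, min_n = 1)
  rs_a <- rs[rs$region_id == "region-a", ]
  expect_equal(rs_a$mean_score, 0.7)
  expect_equal(rs_a$n_posts, 2)
  expect_equal(rs_a$prop_positive, 1)
  expect_equal(rs[rs$region_id == "region-b", ]$mean_score, -0.5)
  # the non-geo post is excluded and counted as unresolvable
  expect_equal(attr(rs, "diagnostics")$n_unresolved, 1)
  top <- region_rankings(rs, k = 1, direction = "most_positive")
  expect_equal(top$region_id, "region-a")
  bottom <- region_rankings(rs, k = 1, direction = "most_negative")
  expect_equal(bottom$region_id, "region-b")
})

test_that("regions below min_n stay in the output but leave the rankings", {
  sc <- scored_fixture(c(rep(0.5, 5), -0.9),
                       c(rep("positive", 5), "negative"),
                       "2020-03-02T12:00:00Z",
                       region = c(rep("big-region", 5), "tiny-region"))
  rs <- region_summaries(sc, min_n = 5)
  expect_true("tiny-region" %in% rs$region_id)
  expect_false(rs$eligible[rs$region_id == "tiny-region"])
  rk <- region_rankings(rs, k = 5, direction = "most_negative")
  expect_false("tiny-region" %in% rk$region_id)
})

test_that("zero-post regions from the lookup are flagged, not fabricated", {
  sc <- scored_fixture(0.5, "positive", "2020-03-02T12:00:00Z",
                       region = "greater-london")
  rs <- region_summaries(sc, region_lookup = uk_counties())
  kent <- rs[rs$region_id == "kent", ]
  expect_equal(kent$n_posts, 0)
  expect_true(is.na(kent$mean_score))
})

test_that("coordinates resolve by point-in-polygon; outside points are logged", {
  gj <- write_square_boundaries(withr::local_tempfile(fileext = ".geojson"))
  bounds <- read_region_boundaries(gj)
  sc <- scored_fixture(c(0.5, -0.5, 0.9), c("positive", "negative", "positive"),
                       "2020-03-02T12:00:00Z",
                       longitude = c(-1.5, 1.5, 10), latitude = c(0.5, 0.5, 50))
  rs <- region_summaries(sc, boundaries = bounds, min_n = 1)
  expect_equal(rs$n_posts[rs$region_id == "region-west"], 1)
  expect_equal(rs$mean_score[rs$region_id == "region-west"], 0.5)
  expect_equal(rs$n_posts[rs$region_id == "region-east"], 1)
  expect_equal(attr(rs, "diagnostics")$n_unresolved, 1)
})

test_that("term frequencies count, rank and exclude as configured", {
  sc <- scored_fixture(rep(-0.5, 3), rep("negative", 3), "2020-03-02T12:00:00Z")
  sc$text <- c("privacy worries about the data breach",
               "data breach worries everyone",
               "such worries and the privacy problem")
  tf <- term_frequencies(sc, label = "negative")
  expect_equal(tf$term[1], "worries")
  expect_equal(tf$count[1], 3L)
  # the filter keyword "privacy" and stopwords are excluded
  expect_false("privacy" %in% tf$term)
  expect_false("the" %in% tf$term)
  expect_false("about" %in% tf$term)
  # count ties are broken lexicographically and counts never increase
  expect_true(all(diff(tf$count) <= 0))
  breach_data <- tf[tf$count == 2, "term"]
  expect_equal(breach_data, sort(breach_data))
  # empty stratum gives an empty table
  empty <- term_frequencies(sc, label = "positive")
  expect_equal(nrow(empty), 0)
  # a time window stratifies the counts
  tfw <- term_frequencies(sc, window = corpus_window("2020-04-01", "2020-04-30"))
  expect_equal(nrow(tfw), 0)
})
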