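#' Class-conditional vocabulary pools for the generator
#'
#' Positive and negative pools are the fixture lexicon's signed terms; the
#' neutral/noise pool is a curated list of topic words carrying no valence,
#' disjoint from the lexicon's entries, boosters, negators and from every
#' thematic filter keyword token (so keyword presence never leaks valence or
#' class information into generated text).
#'
#' @param lexicon the [valence_lexicon] supplying the signed pools.
#' @return list with elements `positive`, `negative`, `neutral`, `covid`,
#'   `app`.
#' @export
default_vocab <- function(lexicon = fixture_lexicon()) {
  noise <- unique(c(
    "this", "today", "week", "weekend", "morning", "evening", "phone",
    "mobile", "device", "android", "iphone", "update", "version", "download",
    "install", "government", "minister", "council", "nhs", "news", "report",
    "people", "public", "everyone", "anyone", "data", "number", "system",
    "network", "country", "city", "town", "street", "office", "school",
    "work", "home", "family", "friend", "neighbour", "radio", "television",
    "article", "story", "message", "thread", "question", "answer", "thing",
    "way", "point", "case", "time", "day", "month", "year", "using", "used",
    "make", "made", "take", "took", "go", "went", "come", "came", "see",
    "saw", "look", "read", "write", "say", "said", "tell", "told", "think",
    "thought", "know", "knew", "get", "got", "keep", "kept", "still",
    "again", "here", "now", "soon", "later", "maybe", "perhaps", "around",
    "near", "far", "big", "small", "long", "short", "early", "late", "open",
    "closed", "full", "empty", "new", "old", "next", "last", "first",
    "second", "third"))
  list(positive = names(lexicon$entries)[lexicon$entries > 0],
       negative = names(lexicon$entries)[lexicon$entries < 0],
       neutral = noise,
       covid = covid_keyword_spec()$keywords,
       app = app_keyword_spec()$keywords)
}

#' Specification for a synthetic two-platform post corpus
#'
#' The defaults emulate the shape of the motivating study corpus: 10,000
#' posts split 8000 / 2000 across the two platform roles, class proportions
#' 76/12/12 (positive/neutral/negative), a March 1 - October 31 2020 span,
#' and UK county region labels. `separability` is the fraction of each
#' post's content words drawn from its class-conditional valence pool (the
#' rest are neutral noise), so both easy and hard classification regimes are
#' generable; neutral posts contain noise words only.
#'
#' @param n_posts number of posts (> 0).
#' @param platform_split share of posts on platform A (default 0.8).
#' @param class_proportions named triple over [sentiment_levels()] summing
#'   to 1 (default `c(positive = 0.76, neutral = 0.12, negative = 0.12)`).
#' @param start_date,end_date corpus date span (inclusive, UTC dates).
#' @param weekly_trend optional data.frame with columns `week_start` (the
#'   Monday of an ISO week) and `prop_positive`/`prop_neutral`/
#'   `prop_negative`, overriding the class proportions for those weeks.
#' @param region_distribution named probability vector over region ids
#'   (default uniform over [uk_counties()]).
#' @param p_geo probability a post carries a region label (default 0.6; the
#'   remainder emulate non-geo-tagged posts).
#' @param separability fraction of content words drawn from the class pool
#'   (default 0.9, a high-separability regime).
#' @param terms_per_post content words per post (default 8).
#' @param keyword_rate probability a post is planted with one first-step and
#'   one second-step filter keyword (default 1, so the whole corpus survives
#'   the two-step thematic filter).
#' @param vocab vocabulary pools, see [default_vocab()].
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_posts = 10000, platform_split = 0.8,
                           class_proportions = c(positive = 0.76,
                                                 neutral = 0.12,
                                                 negative = 0.12),
                           start_date = "2020-03-01", end_date = "2020-10-31",
                           weekly_trend = NULL, region_distribution = NULL,
                           p_geo = 0.6, separability = 0.9,
                           terms_per_post = 8, keyword_rate = 1,
                           vocab = default_vocab(), seed = 1) {
  stopifnot(n_posts > 0, platform_split >= 0, platform_split <= 1,
            p_geo >= 0, p_geo <= 1, separability >= 0, separability <= 1,
            keyword_rate >= 0, keyword_rate <= 1, terms_per_post >= 1)
  class_proportions <- class_proportions[sentiment_levels()]
  if (any(is.na(class_proportions)) ||
      abs(sum(class_proportions) - 1) > 1e-12)
    stop("class_proportions must cover ", paste(sentiment_levels(), collapse = "/"),
         " and sum to 1")
  if (is.null(region_distribution)) {
    ids <- uk_counties()$region_id
    region_distribution <- stats::setNames(rep(1 / length(ids), length(ids)), ids)
  }
  if (abs(sum(region_distribution) - 1) > 1e-12)
    stop("region_distribution must sum to 1")
  if (!is.null(weekly_trend)) {
    need <- c("week_start", "prop_positive", "prop_neutral", "prop_negative")
    if (!all(need %in% names(weekly_trend)))
      stop("weekly_trend needs columns: ", paste(need, collapse = ", "))
    s <- with(weekly_trend, prop_positive + prop_neutral + prop_negative)
    if (any(abs(s - 1) > 1e-12)) stop("weekly_trend proportions must sum to 1")
  }
  for (pool in c("neutral", "covid", "app"))
    if (length(vocab[[pool]]) == 0L)
      stop("infeasible generator spec: empty vocabulary pool '", pool, "'")
  for (cls in c("positive", "negative"))
    if (class_proportions[[cls]] > 0 && separability > 0 &&
        length(vocab[[cls]]) == 0L)
      stop("infeasible generator spec: empty vocabulary pool '", cls, "'")
  structure(list(n_posts = as.integer(n_posts), platform_split = platform_split,
                 class_proportions = class_proportions,
                 start_date = as.Date(start_date), end_date = as.Date(end_date),
                 weekly_trend = weekly_trend,
                 region_distribution = region_distribution, p_geo = p_geo,
                 separability = separability,
                 terms_per_post = as.integer(terms_per_post),
                 keyword_rate = keyword_rate, vocab = vocab,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("<generator_spec: %d posts, split %.2f, classes %s, %s..%s, seed %d>\n",
              x$n_posts, x$platform_split,
              paste(sprintf("%.2f", x$class_proportions), collapse = "/"),
              x$start_date, x$end_date, x$seed))
  invisible(x)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic post corpus with known ground truth
#'
#' Each post is assigned an ISO week uniformly over the span, a gold class
#' from the (possibly week-dependent) class proportions, a timestamp uniform
#' within its week clipped to the span, a platform by the platform split, a
#' region (with probability `p_geo`), and text composed of class-conditional
#' valence terms plus neutral noise plus (with probability `keyword_rate`)
#' one first-step and one second-step filter keyword phrase. Fully
#' deterministic given the spec, including its seed.
#'
#' @param spec a [generator_spec()].
#' @return a validated corpus data.frame with `gold_label` set.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    n <- spec$n_posts
    mondays <- seq(iso_week_start(spec$start_date),
                   iso_week_start(spec$end_date), by = 7L)
    wk <- sample(mondays, n, replace = TRUE)
    props_for_week <- function(w) {
      if (!is.null(spec$weekly_trend)) {
        hit <- which(as.Date(spec$weekly_trend$week_start) == w)
        if (length(hit))
          return(c(positive = spec$weekly_trend$prop_positive[hit[1]],
                   neutral = spec$weekly_trend$prop_neutral[hit[1]],
                   negative = spec$weekly_trend$prop_negative[hit[1]]))
      }
      spec$class_proportions
    }
    gold <- character(n)
    uw <- unique(wk)
    for (k in seq_along(uw)) {
      w <- uw[k]
      in_w <- which(wk == w)
      p <- props_for_week(w)
      gold[in_w] <- sample(sentiment_levels(), length(in_w), replace = TRUE,
                           prob = p)
    }
    day_lo <- as.integer(pmax(spec$start_date, wk) - wk)
    day_hi <- as.integer(pmin(spec$end_date, wk + 6L) - wk)
    day <- day_lo + floor(stats::runif(n) * (day_hi - day_lo + 1L))
    secs <- floor(stats::runif(n) * 86400)
    timestamp <- as.POSIXct(as.numeric(as.POSIXct(wk, tz = "UTC")) +
                              day * 86400 + secs,
                            origin = "1970-01-01", tz = "UTC")
    platform <- ifelse(stats::runif(n) < spec$platform_split,
                       "platform_a", "platform_b")
    region <- ifelse(stats::runif(n) < spec$p_geo,
                     sample(names(spec$region_distribution), n, replace = TRUE,
                            prob = spec$region_distribution),
                     NA_character_)
    n_class <- ifelse(gold == "neutral", 0L,
                      round(spec$separability * spec$terms_per_post))
    n_noise <- spec$terms_per_post - n_class
    keyworded <- stats::runif(n) < spec$keyword_rate
    text <- vapply(seq_len(n), function(i) {
      units <- character(0)
      if (n_class[i] > 0L)
        units <- c(units, sample(spec$vocab[[gold[i]]], n_class[i], replace = TRUE))
      if (n_noise[i] > 0L)
        units <- c(units, sample(spec$vocab$neutral, n_noise[i], replace = TRUE))
      if (keyworded[i])
        units <- c(units, sample(spec$vocab$covid, 1L), sample(spec$vocab$app, 1L))
      paste(sample(units), collapse = " ")
    }, character(1))
    posts <- data.frame(post_id = sprintf("post%07d", seq_len(n)),
                        platform = platform,
                        timestamp = timestamp,
                        text = text,
                        region = region,
                        latitude = NA_real_, longitude = NA_real_,
                        language = "en",
                        gold_label = gold,
                        stringsAsFactors = FALSE)
    validate_posts(posts, context = "generated corpus")
  })
}

#' Draw a labelled validation subsample
#'
#' Emulates a manually labelled validation set (the motivating study used
#' 1000 randomly selected, team-labelled posts): a uniform random subsample
#' without replacement of the generated corpus, seed-deterministic.
#'
#' @param spec a [generator_spec()].
#' @param n_labelled subsample size, at most `spec$n_posts`.
#' @param corpus optionally, an already generated corpus for this spec (to
#'   avoid regenerating).
#' @return a corpus data.frame of `n_labelled` posts with gold labels.
#' @export
generate_labelled_validation <- function(spec, n_labelled, corpus = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (n_labelled > spec$n_posts)
    stop("n_labelled (", n_labelled, ") exceeds corpus size (", spec$n_posts, ")")
  if (is.null(corpus)) corpus <- generate_corpus(spec)
  with_seed(spec$seed + 1L, {
    idx <- sort(sample.int(nrow(corpus), n_labelled))
    corpus[idx, , drop = FALSE]
  })
}
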