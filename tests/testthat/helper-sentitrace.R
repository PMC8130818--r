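# shared fixtures, all built in code

# minimal lexicon with known valences for hand-computable cases
tiny_lexicon <- function() {
  valence_lexicon(
    entries = c(good = 1.9, great = 3.1, bad = -2.5, awful = -2.0),
    boosters = c(very = 0.293),
    negators = c("not", "never"))
}

# quick corpus builder; recycles scalar arguments
make_posts <- function(text,
                       timestamp = "2020-03-02T12:00:00Z",
                       platform = "platform_a",
                       region = NA_character_,
                       latitude = NA_real_, longitude = NA_real_,
                       language = "en",
                       gold_label = NA_character_,
                       post_id = NULL) {
  n <- length(text)
  df <- data.frame(
    post_id = post_id %||% sprintf("t%04d", seq_len(n)),
    platform = rep_len(platform, n),
    timestamp = rep_len(timestamp, n),
    text = text,
    region = rep_len(region, n),
    latitude = rep_len(latitude, n), longitude = rep_len(longitude, n),
    language = rep_len(language, n),
    gold_label = rep_len(gold_label, n),
    stringsAsFactors = FALSE)
  validate_posts(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic test channels that replay scores/labels encoded in the text,
# e.g. "a=0.3 b=-0.3 ctx=neutral"; defaults 0 / neutral when the tag is absent
register_test_channels <- function() {
  parse_tag <- function(text, tag, default) {
    pat <- paste0(".*", tag, "=(-?[0-9.]+|[a-z]+).*")
    ifelse(grepl(paste0(tag, "="), text), sub(pat, "\\1", text), default)
  }
  register_scorer("test_a", function(text)
    as.numeric(parse_tag(text, "a", "0")), type = "polarity", overwrite = TRUE)
  register_scorer("test_b", function(text)
    as.numeric(parse_tag(text, "b", "0")), type = "polarity", overwrite = TRUE)
  register_scorer("test_ctx", function(text)
    parse_tag(text, "ctx", "neutral"), type = "label", overwrite = TRUE)
  invisible()
}

# ensemble wired to the replay channels
test_ensemble <- function(weight_a = 0.48, ...) {
  register_test_channels()
  sentiment_ensemble(weight_a = weight_a, channel_a = "test_a",
                     channel_b = "test_b", contextual = "test_ctx", ...)
}

# labelled corpus in which channel B strictly dominates: positive posts are
# recoverable only through the lexicon positive branch, with graded magnitudes
# so each grid step above the minimum loses one more positive post
dominant_b_corpus <- function() {
  cut_b <- function(cutoff) 0.05 / (1 - 2 * cutoff)   # correct iff weight_a <= cutoff
  bpos <- vapply(c(0.41, 0.43, 0.45, 0.47), cut_b, numeric(1))
  texts <- c(
    sprintf("a=%g b=%g ctx=neutral", -bpos, bpos),              # gold positive
    "a=0 b=0 ctx=neutral",                                      # gold neutral
    sprintf("a=%g b=%g ctx=negative", bpos[1], -bpos[1]))       # gold negative
  make_posts(texts, gold_label = c(rep("positive", 4), "neutral", "negative"))
}

# two 1-degree square counties around the origin, as a GeoJSON file
write_square_boundaries <- function(path) {
  square <- function(x0, y0)
    list(list(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1),
              c(x0, y0)))
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(region_id = "region-west"),
         geometry = list(type = "Polygon", coordinates = square(-2, 0))),
    list(type = "Feature", properties = list(region_id = "region-east"),
         geometry = list(type = "Polygon", coordinates = square(1, 0)))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  path
}
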