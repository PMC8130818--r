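#' Overall sentiment class proportions
#'
#' @param scored scored corpus; flagged (NA-label) posts are excluded.
#' @return named numeric vector over [sentiment_levels()], summing to 1.
#' @export
overall_proportions <- function(scored) {
  lab <- scored$final_label[!is.na(scored$final_label)]
  if (length(lab) == 0L) stop("overall_proportions: empty corpus")
  tab <- table(factor(lab, levels = sentiment_levels()))
  stats::setNames(as.numeric(tab) / length(lab), sentiment_levels())
}

iso_week_start <- function(d) d - (as.integer(format(d, "%u")) - 1L)

post_date <- function(timestamp) as.Date(format(timestamp, "%Y-%m-%d", tz = "UTC"))

#' Weekly cross-platform sentiment series
#'
#' Bins posts into ISO-8601 weeks on the UTC calendar date and emits one
#' point per ISO week intersecting the corpus span, including empty weeks
#' (`n = 0`, `NA` mean). The cross-platform combination is post-count
#' weighted by default, i.e. `mean_score` is the pooled mean over all of the
#' week's posts; `weighting = "equal"` instead averages the two per-platform
#' weekly means.
#'
#' @param scored scored corpus; flagged posts are excluded.
#' @param weighting `"pooled"` (post-count weighting) or `"equal"`.
#' @param score_column which continuous score to average.
#' @param label_column which label column the class proportions use.
#' @return data.frame of class `weekly_series` with columns `iso_year`,
#'   `iso_week`, `week_start`, `n_a`, `n_b`, `n`, `mean_score`,
#'   `prop_positive`, `prop_neutral`, `prop_negative`.
#' @export
weekly_series <- function(scored, weighting = c("pooled", "equal"),
                          score_column = "lexicon_ensemble_score",
                          label_column = "final_label") {
  weighting <- match.arg(weighting)
  keep <- !is.na(scored[[label_column]])
  scored <- scored[keep, , drop = FALSE]
  if (nrow(scored) == 0L) stop("weekly_series: no scorable posts")
  d <- post_date(scored$timestamp)
  wk <- iso_week_start(d)
  weeks <- seq(min(wk), max(wk), by = 7L)
  rows <- lapply(weeks, function(w) {
    in_w <- wk == w
    n_a <- sum(in_w & scored$platform == "platform_a")
    n_b <- sum(in_w & scored$platform == "platform_b")
    n <- n_a + n_b
    if (n == 0L) {
      ms <- NA_real_; pp <- pn <- pg <- NA_real_
    } else {
      s <- scored[[score_column]][in_w]
      if (weighting == "pooled" || n_a == 0L || n_b == 0L) {
        ms <- mean(s)
      } else {
        ms <- mean(c(mean(s[scored$platform[in_w] == "platform_a"]),
                     mean(s[scored$platform[in_w] == "platform_b"])))
      }
      lab <- scored[[label_column]][in_w]
      pp <- mean(lab == "positive"); pn <- mean(lab == "neutral")
      pg <- mean(lab == "negative")
    }
    data.frame(iso_year = as.integer(format(w, "%G")),
               iso_week = as.integer(format(w, "%V")),
               week_start = w, n_a = n_a, n_b = n_b, n = n,
               mean_score = ms, prop_positive = pp, prop_neutral = pn,
               prop_negative = pg)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("weekly_series", "data.frame")
  out
}

#' @export
plot.weekly_series <- function(x, ...) {
  graphics::plot(x$week_start, x$mean_score, type = "b",
                 xlab = "ISO week (week start)", ylab = "mean sentiment score",
                 ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' The packaged UK county lookup
#'
#' A small county-level region lookup (region_id, name, macro_region) used by
#' the synthetic generator and as the default spatial scope.
#'
#' @return data.frame with columns `region_id`, `name`, `macro_region`.
#' @export
uk_counties <- function() {
  path <- system.file("extdata", "uk_counties.tsv", package = "sentitrace")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# ray-casting point-in-ring test; ring is a 2-column (lon, lat) matrix
point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if (((yi > lat) != (yj > lat)) &&
        (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi))
      inside <- !inside
    j <- i
  }
  inside
}

point_in_polygon <- function(lon, lat, rings) {
  # first ring is the outer boundary, any further rings are holes
  if (!point_in_ring(lon, lat, rings[[1]])) return(FALSE)
  if (length(rings) > 1L)
    for (h in rings[-1]) if (point_in_ring(lon, lat, h)) return(FALSE)
  TRUE
}

#' Read region boundaries from GeoJSON
#'
#' Supports FeatureCollections of Polygon and MultiPolygon features; each
#' feature must carry the region identifier in its properties.
#'
#' @param path GeoJSON file.
#' @param id_property name of the property holding the region id.
#' @return a named list (region_id -> list of polygons, each a list of
#'   (lon, lat) ring matrices), class `region_boundaries`.
#' @export
read_region_boundaries <- function(path, id_property = "region_id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  out <- list()
  for (f in gj$features) {
    rid <- f$properties[[id_property]]
    if (is.null(rid)) stop("feature without property '", id_property, "' in ", path)
    geom <- f$geometry
    as_ring <- function(r) do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
    polys <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, as_ring)),
      MultiPolygon = lapply(geom$coordinates, function(p) lapply(p, as_ring)),
      stop("unsupported geometry type '", geom$type, "' for region ", rid))
    out[[rid]] <- c(out[[rid]], polys)
  }
  structure(out, class = "region_boundaries")
}

resolve_region <- function(scored, boundaries = NULL) {
  region <- scored$region
  need_geo <- is.na(region) & !is.na(scored$latitude) & !is.na(scored$longitude)
  if (!is.null(boundaries) && any(need_geo)) {
    ids <- names(boundaries)
    for (i in which(need_geo)) {
      for (rid in ids) {
        hit <- any(vapply(boundaries[[rid]], function(poly)
          point_in_polygon(scored$longitude[i], scored$latitude[i], poly), TRUE))
        if (hit) { region[i] <- rid; break }
      }
    }
  }
  region
}

#' Per-region sentiment summaries
#'
#' Assigns each geo-resolvable post to exactly one region — by its region
#' code when present, else by point-in-polygon against supplied boundaries —
#' and summarizes sentiment per region. Posts with no geographic metadata, or
#' coordinates outside every polygon, are excluded and counted as
#' unresolvable in the `diagnostics` attribute. Regions known to the lookup
#' but receiving no posts are emitted with `n_posts = 0`, never fabricated
#' scores. Regions with fewer than `min_n` posts are present in the output
#' but flagged ineligible for rankings.
#'
#' @param scored scored corpus.
#' @param region_lookup optional data.frame with a `region_id` column (e.g.
#'   [uk_counties()]); defines the region scope.
#' @param boundaries optional [read_region_boundaries()] result for
#'   coordinate resolution.
#' @param min_n minimum post count for ranking eligibility (default 5).
#' @param score_column,label_column columns to summarize.
#' @return data.frame of class `region_summary` with columns `region_id`,
#'   `n_posts`, `mean_score`, `prop_positive`, `prop_negative`, `eligible`.
#' @export
region_summaries <- function(scored, region_lookup = NULL, boundaries = NULL,
                             min_n = 5,
                             score_column = "lexicon_ensemble_score",
                             label_column = "final_label") {
  keep <- !is.na(scored[[label_column]])
  scored <- scored[keep, , drop = FALSE]
  region <- resolve_region(scored, boundaries)
  scope <- if (!is.null(region_lookup)) region_lookup$region_id else
    sort(unique(region[!is.na(region)]))
  out_of_scope <- !is.na(region) & !region %in% scope
  if (any(out_of_scope)) region[out_of_scope] <- NA
  resolvable <- !is.na(region)
  rows <- lapply(scope, function(rid) {
    in_r <- resolvable & region == rid
    n <- sum(in_r)
    data.frame(region_id = rid, n_posts = n,
               mean_score = if (n) mean(scored[[score_column]][in_r]) else NA_real_,
               prop_positive = if (n) mean(scored[[label_column]][in_r] == "positive") else NA_real_,
               prop_negative = if (n) mean(scored[[label_column]][in_r] == "negative") else NA_real_,
               eligible = n >= min_n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "diagnostics") <- list(
    n_unresolved = sum(!resolvable),
    unresolved_ids = scored$post_id[!resolvable])
  class(out) <- c("region_summary", "data.frame")
  out
}

#' Rank regions by mean sentiment
#'
#' @param summaries a [region_summaries()] result.
#' @param k how many regions to return.
#' @param direction `"most_positive"` or `"most_negative"`.
#' @return the top-k eligible regions, ordered.
#' @export
region_rankings <- function(summaries, k = 5,
                            direction = c("most_positive", "most_negative")) {
  direction <- match.arg(direction)
  el <- summaries[summaries$eligible & !is.na(summaries$mean_score), , drop = FALSE]
  ord <- if (direction == "most_positive")
    order(-el$mean_score, el$region_id) else order(el$mean_score, el$region_id)
  utils::head(el[ord, , drop = FALSE], k)
}

#' A minimal English stopword list
#' @return lowercase character vector.
#' @export
default_stopwords <- function() {
  c("a", "about", "after", "all", "also", "am", "an", "and", "any", "are",
    "as", "at", "be", "because", "been", "but", "by", "can", "could", "did",
    "do", "does", "for", "from", "had", "has", "have", "he", "her", "him",
    "his", "how", "i", "if", "in", "into", "is", "it", "its", "just", "me",
    "more", "most", "my", "of", "on", "one", "only", "or", "other", "our",
    "out", "over", "she", "should", "some", "such", "than", "that", "the",
    "their", "them", "then", "there", "these", "they", "this", "to", "too",
    "under", "up", "us", "was", "we", "were", "what", "when", "where",
    "which", "while", "who", "why", "will", "with", "would", "you", "your")
}

#' Sentiment-stratified term frequency table (word-cloud data)
#'
#' Tokenizes the selected stratum with the same tokenizer the scorers use,
#' removes stopwords and the thematic filter keywords themselves (the terms
#' that defined the corpus carry no topical information within it), and
#' returns ranked counts: descending count, ties broken lexicographically.
#'
#' @param scored scored corpus.
#' @param label optional sentiment stratum (one of [sentiment_levels()]).
#' @param window optional [corpus_window()] restricting the time stratum.
#' @param stopwords terms to exclude (default [default_stopwords()]).
#' @param exclude_specs list of [keyword_filter_spec()]s whose phrase tokens
#'   are excluded; default the two packaged thematic filters.
#' @param label_column which label column defines the stratum.
#' @return data.frame with columns `term`, `count`, ranked.
#' @export
term_frequencies <- function(scored, label = NULL, window = NULL,
                             stopwords = default_stopwords(),
                             exclude_specs = list(covid_keyword_spec(),
                                                  app_keyword_spec()),
                             label_column = "final_label") {
  keep <- !is.na(scored[[label_column]])
  if (!is.null(label)) {
    stopifnot(label %in% sentiment_levels())
    keep <- keep & scored[[label_column]] == label
  }
  if (!is.null(window)) {
    d <- post_date(scored$timestamp)
    keep <- keep & d >= window$start_date & d <= window$end_date
  }
  texts <- scored$text[keep]
  if (length(texts) == 0L)
    return(data.frame(term = character(0), count = integer(0)))
  toks <- unlist(tokenize_text(texts))
  drop <- unique(c(stopwords,
                   unlist(lapply(exclude_specs, function(s)
                     unlist(tokenize_text(s$keywords))))))
  toks <- toks[!toks %in% drop]
  if (length(toks) == 0L)
    return(data.frame(term = character(0), count = integer(0)))
  tab <- table(toks)
  out <- data.frame(term = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
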