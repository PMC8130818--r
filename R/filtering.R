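#' Keyword filter specification
#'
#' A named list of lowercase keyword phrases plus a matching mode.
#' `token_phrase` (the default) matches a phrase as a contiguous run of whole
#' tokens after lowercasing and punctuation stripping, so `"tracking"` matches
#' `"tracking!"` but not `"backtracking"`; `substring` matches anywhere in the
#' case-folded raw text.
#'
#' @param name spec name (used in logs and manifests).
#' @param keywords character vector of phrases; case-folded, must be unique.
#' @param match_mode `"token_phrase"` or `"substring"`.
#' @return object of class `keyword_filter_spec`.
#' @export
keyword_filter_spec <- function(name, keywords,
                                match_mode = c("token_phrase", "substring")) {
  match_mode <- match.arg(match_mode)
  keywords <- tolower(trimws(as.character(keywords)))
  if (length(keywords) == 0L || any(!nzchar(keywords)))
    stop("keyword_filter_spec: keywords must be a non-empty set of non-empty phrases")
  if (anyDuplicated(keywords))
    stop("keyword_filter_spec: duplicate phrase(s) after case-folding: ",
         paste(unique(keywords[duplicated(keywords)]), collapse = ", "))
  structure(list(name = name, keywords = keywords, match_mode = match_mode),
            class = "keyword_filter_spec")
}

#' @export
print.keyword_filter_spec <- function(x, ...) {
  cat(sprintf("<keyword_filter_spec '%s': %d phrase(s), %s matching>\n",
              x$name, length(x$keywords), x$match_mode))
  invisible(x)
}

#' The default second-step thematic filter: contact tracing app keywords
#'
#' The eleven app-related phrases used for second-step thematic filtering:
#' "covid app", "tracing app", "contact tracing", "privacy", "security",
#' "app security", "app privacy", "contain virus spread", "movement tracking",
#' "tracking", "surveillance".
#'
#' @param match_mode see [keyword_filter_spec()].
#' @return a `keyword_filter_spec`.
#' @export
app_keyword_spec <- function(match_mode = "token_phrase") {
  keyword_filter_spec("contact-tracing-app", c(
    "covid app", "tracing app", "contact tracing", "privacy", "security",
    "app security", "app privacy", "contain virus spread", "movement tracking",
    "tracking", "surveillance"), match_mode = match_mode)
}

#' A default first-step pandemic keyword filter
#'
#' The first-step filter is configurable because upstream data sources apply
#' their own predefined pandemic keyword lists; this default covers the
#' generic terms the synthetic generator plants.
#'
#' @inheritParams app_keyword_spec
#' @return a `keyword_filter_spec`.
#' @export
covid_keyword_spec <- function(match_mode = "token_phrase") {
  keyword_filter_spec("covid-19", c("covid", "covid19", "coronavirus", "pandemic",
                                    "sars cov 2"), match_mode = match_mode)
}

keyword_matches <- function(text, spec) {
  if (spec$match_mode == "substring") {
    folded <- tolower(text)
    hit <- rep(FALSE, length(folded))
    for (kw in spec$keywords) hit <- hit | grepl(kw, folded, fixed = TRUE)
    return(hit)
  }
  toks <- tokenize_text(text, strip_urls = FALSE, strip_mentions = FALSE)
  padded <- vapply(toks, function(t) paste0(" ", paste(t, collapse = " "), " "), "")
  phrases <- vapply(spec$keywords,
                    function(k) paste(tokenize_text(k)[[1]], collapse = " "), "")
  hit <- rep(FALSE, length(padded))
  for (p in phrases) hit <- hit | grepl(paste0(" ", p, " "), padded, fixed = TRUE)
  hit
}

#' Apply a keyword filter to a corpus
#'
#' Retains exactly the posts whose case-folded text matches at least one
#' keyword under the spec's match mode. Order-preserving and idempotent;
#' an empty result is valid.
#'
#' @param posts corpus data.frame.
#' @param spec a [keyword_filter_spec()].
#' @param verbose log retained/dropped counts.
#' @return the retained subsequence of `posts`.
#' @export
apply_keyword_filter <- function(posts, spec, verbose = FALSE) {
  stopifnot(inherits(spec, "keyword_filter_spec"))
  if (nrow(posts) == 0L) return(posts)
  keep <- keyword_matches(posts$text, spec)
  if (verbose)
    message(sprintf("keyword filter '%s': retained %d / %d posts",
                    spec$name, sum(keep), length(keep)))
  posts[keep, , drop = FALSE]
}

#' Two-step thematic filter
#'
#' Applies the pandemic-level filter first and the app-level filter second;
#' equal by construction to composing [apply_keyword_filter()] in that order.
#'
#' @param posts corpus data.frame.
#' @param covid_spec first-step spec (default [covid_keyword_spec()]).
#' @param app_spec second-step spec (default [app_keyword_spec()]).
#' @param verbose log retained/dropped counts at each step.
#' @return the retained subsequence of `posts`.
#' @export
two_step_filter <- function(posts, covid_spec = covid_keyword_spec(),
                            app_spec = app_keyword_spec(), verbose = FALSE) {
  step1 <- apply_keyword_filter(posts, covid_spec, verbose = verbose)
  apply_keyword_filter(step1, app_spec, verbose = verbose)
}

#' Corpus window: date span, language and region scope
#'
#' @param start_date,end_date inclusive UTC calendar dates (`Date` or
#'   `"YYYY-MM-DD"` strings).
#' @param language declared language code, or `NULL` to skip language
#'   filtering.
#' @param region_scope character vector of admissible region codes, or `NULL`
#'   for no regional restriction.
#' @return object of class `corpus_window`.
#' @export
corpus_window <- function(start_date, end_date, language = "en",
                          region_scope = NULL) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) stop("corpus_window: unparseable date")
  if (start_date > end_date) stop("corpus_window: start_date must be <= end_date")
  structure(list(start_date = start_date, end_date = end_date,
                 language = language, region_scope = region_scope),
            class = "corpus_window")
}

#' Apply a corpus window to a corpus
#'
#' Retains posts whose UTC calendar date lies inside the inclusive
#' `[start_date, end_date]` span, whose declared language matches (posts with
#' no language column or `NA` language are flagged through with one warning —
#' language identification is out of scope), and whose region code lies in
#' `region_scope` when one is declared. Posts with no geographic metadata are
#' retained here; they are excluded later by spatial aggregation only.
#'
#' @param posts corpus data.frame.
#' @param window a [corpus_window()].
#' @param verbose log retained/dropped counts.
#' @return the retained subsequence of `posts`.
#' @export
apply_window <- function(posts, window, verbose = FALSE) {
  stopifnot(inherits(window, "corpus_window"))
  if (nrow(posts) == 0L) return(posts)
  d <- as.Date(format(posts$timestamp, "%Y-%m-%d", tz = "UTC"))
  keep <- d >= window$start_date & d <= window$end_date
  if (!is.null(window$language)) {
    lang <- posts$language
    unknown <- is.na(lang)
    if (any(unknown & keep))
      warning(sum(unknown & keep), " post(s) lack a declared language; ",
              "retained without language filtering")
    keep <- keep & (unknown | lang == window$language)
  }
  if (!is.null(window$region_scope)) {
    keep <- keep & (is.na(posts$region) | posts$region %in% window$region_scope)
  }
  if (verbose)
    message(sprintf("window filter: retained %d / %d posts", sum(keep), nrow(posts)))
  posts[keep, , drop = FALSE]
}
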