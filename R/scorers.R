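#' Register a sentiment scoring channel
#'
#' A polarity channel is a vectorized function `character -> numeric in
#' [-1, 1]`; a label channel (the contextual-classifier slot) is a vectorized
#' function `character -> one of "positive"/"neutral"/"negative"`. Before
#' registration every contract is run against a fixed probe battery of texts
#' (empty, plain, emotive, unicode); a contract whose output leaves the legal
#' range, has the wrong length, or — when declared deterministic — disagrees
#' with itself on a second pass is refused.
#'
#' @param name unique channel name.
#' @param fn the scoring function.
#' @param type `"polarity"` or `"label"`.
#' @param deterministic contract flag: same text, same output.
#' @param overwrite replace an existing registration of the same name.
#' @return the channel name, invisibly.
#' @export
register_scorer <- function(name, fn, type = c("polarity", "label"),
                            deterministic = TRUE, overwrite = FALSE) {
  type <- match.arg(type)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name), is.function(fn))
  if (!overwrite && name %in% names(.sentitrace$scorers))
    stop("a scorer named '", name, "' is already registered")
  probe <- c("", "good", "not good at all", "this is terrible!!!",
             "café naïve ☃ \U0001F600", "plain text with no opinion",
             "very very very good good good")
  out1 <- suppressWarnings(fn(probe))
  if (length(out1) != length(probe))
    stop("scorer '", name, "' is not vectorized over its input")
  if (type == "polarity") {
    if (!is.numeric(out1) || any(!is.finite(out1)) || any(out1 < -1 | out1 > 1))
      stop("scorer '", name, "' violated the polarity range [-1, 1] on the probe battery")
  } else {
    if (!all(as.character(out1) %in% sentiment_levels()))
      stop("scorer '", name, "' returned labels outside {",
           paste(sentiment_levels(), collapse = ", "), "}")
  }
  if (deterministic) {
    out2 <- suppressWarnings(fn(probe))
    if (!identical(as.vector(out1), as.vector(out2)))
      stop("scorer '", name, "' declared deterministic but disagreed with itself on the probe battery")
  }
  .sentitrace$scorers[[name]] <- list(name = name, fn = fn, type = type,
                                      deterministic = deterministic)
  invisible(name)
}

#' List registered scoring channels
#' @return data.frame with columns name, type, deterministic.
#' @export
list_scorers <- function() {
  s <- .sentitrace$scorers
  data.frame(name = vapply(s, `[[`, "", "name"),
             type = vapply(s, `[[`, "", "type"),
             deterministic = vapply(s, `[[`, TRUE, "deterministic"),
             row.names = NULL, stringsAsFactors = FALSE)
}

get_scorer <- function(name, type = NULL) {
  s <- .sentitrace$scorers[[name]]
  if (is.null(s)) stop("no scorer registered under the name '", name, "'")
  if (!is.null(type) && s$type != type)
    stop("scorer '", name, "' has type '", s$type, "', expected '", type, "'")
  s
}

#' The three sentiment classes, in fixed reporting order
#' @return `c("positive", "neutral", "negative")`
#' @export
sentiment_levels <- function() c("positive", "neutral", "negative")

#' Deterministic keyword-table contextual classifier
#'
#' A transparent stand-in for the contextual (full-sentence) classifier
#' channel: it counts positive-valence and negative-valence lexicon tokens
#' (a negator in the three preceding tokens flips a token's sign) and labels
#' the post by majority sign, neutral on a tie or no hits. It exists so the
#' fusion logic — the part of the ensemble this package contributes — is
#' exercised with a deterministic, dependency-free channel; any external
#' contextual model can be registered in its place via [register_scorer()].
#'
#' @inheritParams score_text
#' @return character vector of labels in `sentiment_levels()`.
#' @export
keyword_context_classifier <- function(text, lexicon = fixture_lexicon(),
                                       negation_window = 3) {
  toks <- tokenize_text(text)
  vapply(toks, function(tk) {
    if (length(tk) == 0L) return("neutral")
    v <- unname(lexicon$entries[tk])
    hit <- which(!is.na(v))
    if (length(hit) == 0L) return("neutral")
    signs <- vapply(hit, function(j) {
      sj <- sign(v[j])
      if (j > 1L) {
        lo <- max(1L, j - negation_window)
        if (any(tk[lo:(j - 1L)] %in% lexicon$negators)) sj <- -sj
      }
      sj
    }, numeric(1))
    npos <- sum(signs > 0); nneg <- sum(signs < 0)
    if (npos > nneg) "positive" else if (nneg > npos) "negative" else "neutral"
  }, character(1))
}

register_builtin_scorers <- function() {
  register_scorer("lexicon_a", function(text) score_text(text),
                  type = "polarity", overwrite = TRUE)
  register_scorer("lexicon_b", function(text) score_text_mean(text),
                  type = "polarity", overwrite = TRUE)
  register_scorer("keyword_context", function(text) keyword_context_classifier(text),
                  type = "label", overwrite = TRUE)
  invisible()
}
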