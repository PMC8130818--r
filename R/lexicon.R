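#' Valence lexicon container
#'
#' A valence lexicon maps lowercase terms to signed valences on the
#' conventional \[-4, 4\] dictionary scale, plus two auxiliary tables:
#' *boosters* (degree adverbs adding a signed increment toward a following
#' valence token's sign, e.g. "very") and *negators* (terms that flip and
#' dampen a following valence token, e.g. "not").
#'
#' @param entries named numeric vector, term -> valence in \[-4, 4\].
#' @param boosters named numeric vector, term -> signed increment.
#' @param negators character vector of negation terms.
#' @return An object of class `valence_lexicon`.
#' @export
valence_lexicon <- function(entries, boosters = numeric(0), negators = character(0)) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("lexicon entries must be a named numeric vector")
  boosters <- if (length(boosters)) boosters else stats::setNames(numeric(0), character(0))
  terms <- c(names(entries), names(boosters), negators)
  if (any(terms != tolower(terms)))
    stop("lexicon terms must be lowercase")
  if (anyDuplicated(terms))
    stop("lexicon terms must be unique across entries, boosters and negators: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  if (any(!is.finite(entries)) || any(!is.finite(boosters)))
    stop("lexicon valences and booster increments must be finite")
  if (any(abs(entries) > 4))
    stop("term valences must lie in [-4, 4]")
  structure(list(entries = entries, boosters = boosters, negators = negators),
            class = "valence_lexicon")
}

#' @export
print.valence_lexicon <- function(x, ...) {
  cat(sprintf("<valence_lexicon: %d terms (%d positive, %d negative), %d boosters, %d negators>\n",
              length(x$entries), sum(x$entries > 0), sum(x$entries < 0),
              length(x$boosters), length(x$negators)))
  invisible(x)
}

#' Read a valence lexicon from a sectioned delimited text file
#'
#' The format is two tab-separated columns (term, valence), with optional
#' `[boosters]` (term, increment) and `[negators]` (term only) sections.
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path path to the lexicon file.
#' @return A [valence_lexicon].
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- "entries"
  entries <- character(0); vals <- numeric(0)
  boosters <- character(0); bvals <- numeric(0)
  negators <- character(0)
  for (ln in lines) {
    if (ln == "[boosters]") { section <- "boosters"; next }
    if (ln == "[negators]") { section <- "negators"; next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (section == "negators") {
      negators <- c(negators, parts[[1]])
    } else {
      if (length(parts) < 2) stop("malformed lexicon line (expected term<TAB>value): ", ln)
      v <- suppressWarnings(as.numeric(parts[[2]]))
      if (is.na(v)) stop("non-numeric valence for term '", parts[[1]], "'")
      if (section == "entries") { entries <- c(entries, parts[[1]]); vals <- c(vals, v) }
      else { boosters <- c(boosters, parts[[1]]); bvals <- c(bvals, v) }
    }
  }
  valence_lexicon(stats::setNames(vals, entries),
                  stats::setNames(bvals, boosters), negators)
}

#' The packaged fixture lexicon
#'
#' A small (~250-term) self-contained English valence lexicon shipped with the
#' package, used by the built-in scoring channels, the synthetic corpus
#' generator and the test suite. It deliberately excludes the thematic filter
#' keywords (e.g. "privacy", "tracking") so keyword presence never leaks
#' valence into generated corpora.
#'
#' @return A [valence_lexicon].
#' @export
fixture_lexicon <- function() {
  if (is.null(.sentitrace$fixture_lexicon)) {
    path <- system.file("extdata", "fixture_lexicon.tsv", package = "sentitrace")
    .sentitrace$fixture_lexicon <- read_lexicon(path)
  }
  .sentitrace$fixture_lexicon
}

#' Tokenize post text
#'
#' Lowercases, optionally strips URLs and user mentions, detaches hashtag
#' markers from their word, and splits on any run of characters that is not a
#' letter, digit or apostrophe.
#'
#' @param text character vector of post texts.
#' @param strip_urls,strip_mentions drop URLs / @-mentions before splitting.
#' @return A list of character token vectors, one per input text.
#' @export
tokenize_text <- function(text, strip_urls = TRUE, strip_mentions = TRUE) {
  x <- tolower(as.character(text))
  if (strip_urls)
    x <- gsub("(https?://|www\\.)\\S+", " ", x, perl = TRUE)
  if (strip_mentions)
    x <- gsub("(^|\\s)@[[:alnum:]_]+", " ", x, perl = TRUE)
  x <- gsub("#", " ", x, fixed = TRUE)
  toks <- strsplit(x, "[^\\p{L}\\p{N}']+", perl = TRUE)
  lapply(toks, function(t) t[nzchar(t)])
}

# score -> score/sqrt(score^2 + alpha); maps an unbounded valence sum into (-1, 1)
normalize_valence <- function(s, alpha = 15) s / sqrt(s * s + alpha)

#' Rule-based valence scoring of text (channel A convention)
#'
#' Sums lexicon term valences over the tokenized text with two grammatical
#' rules: a booster immediately preceding a valence token adds its increment
#' toward the token's sign, and a negator within the preceding
#' `negation_window` tokens multiplies the (possibly boosted) valence by
#' `negation_factor` (sign flip plus dampening). The raw sum `s` is then
#' normalized to `s / sqrt(s^2 + alpha)`, so scores lie in (-1, 1) and a text
#' with no lexicon hits scores exactly 0.
#'
#' @param text character vector of texts to score.
#' @param lexicon a [valence_lexicon]; defaults to [fixture_lexicon()].
#' @param alpha normalization constant (default 15).
#' @param negation_window how many preceding tokens a negator reaches (default 3).
#' @param negation_factor multiplier applied by negation (default -0.74).
#' @param emphasis if `TRUE`, apply all-caps and exclamation amplification
#'   (off by default; the default scorer is minimal and auditable).
#' @return numeric vector of polarity scores in \[-1, 1\].
#' @export
score_text <- function(text, lexicon = fixture_lexicon(), alpha = 15,
                       negation_window = 3, negation_factor = -0.74,
                       emphasis = FALSE) {
  stopifnot(inherits(lexicon, "valence_lexicon"))
  raw <- as.character(text)
  toks <- tokenize_text(raw)
  out <- vapply(seq_along(toks), function(i) {
    tk <- toks[[i]]
    if (length(tk) == 0L) {
      warning("empty text after normalization; scoring 0")
      return(0)
    }
    caps <- NULL
    if (emphasis) {
      ct <- tokenize_text_keepcase(raw[[i]])
      if (length(ct) == length(tk))
        caps <- ct == toupper(ct) & ct != tolower(ct) & nchar(ct) > 1
    }
    v <- unname(lexicon$entries[tk])
    hit <- which(!is.na(v))
    if (length(hit) == 0L) return(0)
    s <- 0
    for (j in hit) {
      val <- v[j]
      if (j > 1L) {
        b <- lexicon$boosters[tk[j - 1L]]
        if (!is.na(b)) val <- val + sign(val) * unname(b)
      }
      if (emphasis && !is.null(caps) && isTRUE(caps[j]))
        val <- val + sign(val) * 0.733
      if (j > 1L && negation_window > 0L) {
        lo <- max(1L, j - negation_window)
        if (any(tk[lo:(j - 1L)] %in% lexicon$negators))
          val <- val * negation_factor
      }
      s <- s + val
    }
    if (emphasis) {
      n_excl <- min(3L, lengths(regmatches(raw[[i]], gregexpr("!", raw[[i]], fixed = TRUE))))
      if (s != 0) s <- s + sign(s) * 0.292 * n_excl
    }
    normalize_valence(s, alpha)
  }, numeric(1))
  out
}

tokenize_text_keepcase <- function(text) {
  x <- gsub("(https?://|www\\.)\\S+", " ", text, perl = TRUE)
  x <- gsub("(^|\\s)@[[:alnum:]_]+", " ", x, perl = TRUE)
  x <- gsub("#", " ", x, fixed = TRUE)
  t <- strsplit(x, "[^\\p{L}\\p{N}']+", perl = TRUE)[[1]]
  t[nzchar(t)]
}

#' Mean-polarity lexicon scoring of text (channel B convention)
#'
#' The second lexicon channel: each lexicon hit contributes its valence
#' rescaled to \[-1, 1\] (valence / 4); a negator immediately preceding a hit
#' multiplies its polarity by -0.5 (flip with dampening). The text score is
#' the mean polarity over hits, or 0 when the text has no lexicon hits, so the
#' channel reacts to average tone where channel A reacts to accumulated tone.
#'
#' @inheritParams score_text
#' @return numeric vector of polarity scores in \[-1, 1\].
#' @export
score_text_mean <- function(text, lexicon = fixture_lexicon()) {
  stopifnot(inherits(lexicon, "valence_lexicon"))
  toks <- tokenize_text(text)
  vapply(toks, function(tk) {
    if (length(tk) == 0L) return(0)
    v <- unname(lexicon$entries[tk]) / 4
    hit <- which(!is.na(v))
    if (length(hit) == 0L) return(0)
    p <- vapply(hit, function(j) {
      pj <- v[j]
      if (j > 1L && tk[j - 1L] %in% lexicon$negators) pj <- pj * -0.5
      pj
    }, numeric(1))
    mean(p)
  }, numeric(1))
}
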