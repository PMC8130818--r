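#' @title Post corpora as validated data frames
#' @description
#' A corpus is an ordinary `data.frame` with one row per post and columns
#' `post_id` (unique string), `platform` (`"platform_a"` / `"platform_b"`,
#' the two source roles), `timestamp` (`POSIXct`, UTC), `text` (non-empty
#' UTF-8), and optionally `region` (county-level code), `latitude`/`longitude`
#' (WGS84 decimal degrees), `language` and `gold_label` (one of
#' [sentiment_levels()]). `validate_posts()` checks every invariant and either
#' returns the corpus or raises an error naming each offending row.
#' @name posts
NULL

PLATFORM_LEVELS <- c("platform_a", "platform_b")

POST_COLUMNS <- c("post_id", "platform", "timestamp", "text",
                  "region", "latitude", "longitude", "language", "gold_label")

SCORE_COLUMNS <- c("lexicon_a_score", "lexicon_b_score", "lexicon_ensemble_score",
                   "lexicon_label", "contextual_label", "final_label")

# strict ISO-8601 with an explicit zone designator; zone-less timestamps are
# rejected so weekly binning is never ambiguous
parse_utc_timestamp <- function(x) {
  x <- as.character(x)
  ok <- grepl(
    "^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}(:\\d{2})?(\\.\\d+)?(Z|z|[+-]\\d{2}:?\\d{2}|[+-]\\d{4})$",
    x)
  out <- rep(as.POSIXct(NA), length(x))
  if (any(ok)) {
    y <- x[ok]
    y <- sub("[Zz]$", "+0000", y)
    y <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", y)
    y <- sub("^(\\d{4}-\\d{2}-\\d{2}) ", "\\1T", y)
    no_sec <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}[+-]", y)
    y[no_sec] <- sub("^(\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2})", "\\1:00", y[no_sec])
    out[ok] <- as.POSIXct(y, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
  }
  out
}

format_utc_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Validate a post corpus
#'
#' @param posts data.frame of posts (see [posts]).
#' @param context label used in error messages (e.g. the source file).
#' @return `posts`, invisibly, with canonical column order and types.
#' @export
validate_posts <- function(posts, context = "posts") {
  required <- c("post_id", "platform", "timestamp", "text")
  missing <- setdiff(required, names(posts))
  if (length(missing))
    stop(context, ": missing required column(s): ", paste(missing, collapse = ", "))
  for (col in setdiff(POST_COLUMNS, names(posts)))
    posts[[col]] <- if (col %in% c("latitude", "longitude")) NA_real_ else NA_character_
  posts$post_id <- as.character(posts$post_id)
  posts$text <- as.character(posts$text)
  problems <- character(0)
  dup <- unique(posts$post_id[duplicated(posts$post_id)])
  if (length(dup))
    problems <- c(problems, paste0("duplicate post_id: ", paste(dup, collapse = ", ")))
  bad_platform <- which(!posts$platform %in% PLATFORM_LEVELS)
  for (i in bad_platform)
    problems <- c(problems, sprintf("row %d: unknown platform '%s'", i, posts$platform[i]))
  if (!inherits(posts$timestamp, "POSIXct")) {
    parsed <- parse_utc_timestamp(posts$timestamp)
    bad_ts <- which(is.na(parsed))
    for (i in bad_ts)
      problems <- c(problems, sprintf(
        "row %d: unparseable or zone-less timestamp '%s'", i, as.character(posts$timestamp[i])))
    posts$timestamp <- parsed
  }
  attr(posts$timestamp, "tzone") <- "UTC"
  empty <- which(!nzchar(trimws(posts$text)) | is.na(posts$text))
  for (i in empty)
    problems <- c(problems, sprintf("row %d: empty text", i))
  bad_gold <- which(!is.na(posts$gold_label) &
                      !posts$gold_label %in% sentiment_levels())
  for (i in bad_gold)
    problems <- c(problems, sprintf("row %d: invalid gold_label '%s'", i, posts$gold_label[i]))
  if (length(problems))
    stop(context, ": ", length(problems), " validation problem(s):\n  ",
         paste(problems, collapse = "\n  "))
  posts[, POST_COLUMNS]
}

#' Read a post corpus from delimited or JSON-lines text
#'
#' Every row is validated against the corpus invariants; malformed rows are
#' collected and reported together with their file line numbers — no row is
#' silently dropped. Row order is preserved.
#'
#' @param path input file.
#' @param format `"csv"` or `"jsonl"` (default guessed from the extension).
#' @param platform_map optional named character vector mapping source platform
#'   names (e.g. `"facebook"`) onto the two platform roles.
#' @param col_map optional named character vector mapping canonical column
#'   names onto the file's column names, e.g. `c(post_id = "id")`.
#' @return a validated corpus data.frame.
#' @export
read_posts <- function(path, format = NULL, platform_map = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  format <- format %||% (if (grepl("\\.jsonl?$", path)) "jsonl" else "csv")
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(ln) as.data.frame(jsonlite::fromJSON(ln),
                                                     stringsAsFactors = FALSE))
    df <- if (length(rows)) do.call(rbind_fill, rows) else
      data.frame(post_id = character(0), platform = character(0),
                 timestamp = character(0), text = character(0))
    df <- clean_raw_posts(df)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character")
  }
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df))
        stop("read_posts: column '", src, "' (mapped to '", canon, "') not in file")
      names(df)[names(df) == src] <- canon
    }
  }
  if ("platform" %in% names(df) && !is.null(platform_map)) {
    mapped <- unname(platform_map[df$platform])
    keep <- df$platform %in% PLATFORM_LEVELS
    df$platform <- ifelse(is.na(mapped) & keep, df$platform, mapped)
  }
  validate_posts(clean_raw_posts(df), context = path)
}

# coerce optional columns read as raw character: "" means absent
clean_raw_posts <- function(df) {
  for (col in c("latitude", "longitude"))
    if (col %in% names(df)) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  if (nrow(df)) {
    for (col in c("region", "language", "gold_label"))
      if (col %in% names(df)) {
        v <- as.character(df[[col]])
        v[is.na(v) | !nzchar(trimws(v))] <- NA
        df[[col]] <- v
      }
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[, cols, drop = FALSE]
  }))
}

#' Write a corpus of posts or scored posts to text
#'
#' Numeric score columns are serialized at full double precision so that
#' `read_scored(write_scored(x))` is the identity; text is written as UTF-8
#' with standard CSV quoting, so embedded delimiters, quotes and emoji
#' round-trip.
#'
#' @param posts corpus (or scored corpus) data.frame.
#' @param path output file.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path, format = NULL) {
  format <- format %||% (if (grepl("\\.jsonl?$", path)) "jsonl" else "csv")
  df <- posts
  if (inherits(df$timestamp, "POSIXct")) df$timestamp <- format_utc_timestamp(df$timestamp)
  num_cols <- names(df)[vapply(df, is.numeric, TRUE)]
  # full double precision so write/read is the identity on scores
  for (col in num_cols)
    df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                        sprintf("%.17g", df[[col]]))
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(df)) for (i in seq_len(nrow(df))) {
      row <- as.list(df[i, , drop = FALSE])
      row <- row[!vapply(row, function(v)
        is.null(v) || (length(v) == 1L && is.na(v)), TRUE)]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, na = "null"), con)
    }
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_posts
#' @param scored a scored corpus as produced by [predict.sentiment_ensemble()].
#' @export
write_scored <- function(scored, path, format = NULL) {
  missing <- setdiff(SCORE_COLUMNS, names(scored))
  if (length(missing))
    stop("write_scored: not a scored corpus; missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- with(scored, abs(lexicon_a_score) > 1 | abs(lexicon_b_score) > 1 |
                abs(lexicon_ensemble_score) > 1)
  if (any(bad, na.rm = TRUE)) stop("write_scored: polarity score outside [-1, 1]")
  write_posts(scored, path, format)
}

#' Read back a scored corpus written by [write_scored()]
#' @inheritParams read_posts
#' @return a validated scored-corpus data.frame.
#' @export
read_scored <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.jsonl?$", path)) "jsonl" else "csv")
  if (format == "jsonl") {
    df <- read_posts(path, format = "jsonl")
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(ln) as.data.frame(jsonlite::fromJSON(ln),
                                                     stringsAsFactors = FALSE))
    raw <- if (length(rows)) do.call(rbind_fill, rows) else df
    for (col in SCORE_COLUMNS) {
      if (!col %in% names(raw))
        stop("read_scored: missing score column '", col, "' in ", path)
      df[[col]] <- if (grepl("score", col)) as.numeric(raw[[col]]) else
        as.character(raw[[col]])
    }
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                           colClasses = "character")
    df <- validate_posts(clean_raw_posts(raw), context = path)
    for (col in SCORE_COLUMNS) {
      if (!col %in% names(raw))
        stop("read_scored: missing score column '", col, "' in ", path)
      df[[col]] <- if (grepl("score", col)) as.numeric(raw[[col]]) else
        ifelse(nzchar(raw[[col]]), raw[[col]], NA_character_)
    }
  }
  sc <- df[, grep("score", SCORE_COLUMNS, value = TRUE)]
  if (nrow(df) && any(abs(as.matrix(sc)) > 1, na.rm = TRUE))
    stop("read_scored: polarity score outside [-1, 1] in ", path)
  df
}
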