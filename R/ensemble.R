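#' Hybrid rule-based ensemble sentiment classifier
#'
#' Constructs the ensemble configuration: two lexicon polarity channels are
#' combined by a weighted average (`weight_a * a + weight_b * b`), the
#' combined score is mapped to a 3-class label by thresholds, and the lexicon
#' label is fused with a contextual classifier channel by a fixed if-else
#' rule (see [fuse()]). Default weights are 0.48 / 0.52 — the channel-B
#' lexicon takes the slightly higher weight, reflecting its marginally better
#' accuracy on positive sentiment in validation of the original tuning — and
#' the label thresholds are the conventional +/-0.05 for normalized valence
#' scores.
#'
#' @param weight_a,weight_b lexicon channel weights; must be in \[0, 1\] and
#'   sum to 1 (within 1e-12).
#' @param positive_threshold score at or above which the label is positive
#'   (must be > 0).
#' @param negative_threshold score at or below which the label is negative
#'   (must be < 0).
#' @param channel_a,channel_b names of registered polarity channels.
#' @param contextual name of a registered label channel.
#' @param fusion `"lexicon_positive"` (default: the lexicon label decides
#'   whether the positive branch applies) or `"contextual_branch"` (the
#'   contextual label decides; see [fusion_table()]).
#' @return object of class `sentiment_ensemble`.
#' @seealso [predict.sentiment_ensemble()], [tune_weights()], [fuse()]
#' @export
sentiment_ensemble <- function(weight_a = 0.48, weight_b = 1 - weight_a,
                               positive_threshold = 0.05,
                               negative_threshold = -0.05,
                               channel_a = "lexicon_a", channel_b = "lexicon_b",
                               contextual = "keyword_context",
                               fusion = c("lexicon_positive", "contextual_branch")) {
  fusion <- match.arg(fusion)
  if (!is.numeric(weight_a) || !is.numeric(weight_b) ||
      weight_a < 0 || weight_a > 1 || weight_b < 0 || weight_b > 1)
    stop("channel weights must lie in [0, 1]")
  if (abs(weight_a + weight_b - 1) > 1e-12)
    stop("weight_a + weight_b must equal 1 (got ", weight_a + weight_b, ")")
  if (!(positive_threshold > 0)) stop("positive_threshold must be > 0")
  if (!(negative_threshold < 0)) stop("negative_threshold must be < 0")
  structure(list(weight_a = weight_a, weight_b = weight_b,
                 positive_threshold = positive_threshold,
                 negative_threshold = negative_threshold,
                 channel_a = channel_a, channel_b = channel_b,
                 contextual = contextual, fusion = fusion),
            class = "sentiment_ensemble")
}

#' @export
print.sentiment_ensemble <- function(x, ...) {
  cat("Hybrid rule-based sentiment ensemble\n")
  cat(sprintf("  lexicon channels : %s x %.3f + %s x %.3f\n",
              x$channel_a, x$weight_a, x$channel_b, x$weight_b))
  cat(sprintf("  label thresholds : positive >= %+.3f, negative <= %+.3f\n",
              x$positive_threshold, x$negative_threshold))
  cat(sprintf("  contextual fusion: %s (%s)\n", x$contextual, x$fusion))
  invisible(x)
}

#' @export
coef.sentiment_ensemble <- function(object, ...) {
  c(weight_a = object$weight_a, weight_b = object$weight_b)
}

#' Weighted average of the two lexicon channel scores
#'
#' @param score_a,score_b polarity scores in \[-1, 1\].
#' @param config a [sentiment_ensemble()].
#' @return `weight_a * score_a + weight_b * score_b`, guaranteed in \[-1, 1\].
#' @export
combine_lexicon <- function(score_a, score_b, config = sentiment_ensemble()) {
  stopifnot(inherits(config, "sentiment_ensemble"))
  config$weight_a * score_a + config$weight_b * score_b
}

#' Map a continuous polarity score to a 3-class label
#'
#' Positive iff `score >= positive_threshold`; negative iff
#' `score <= negative_threshold`; neutral otherwise (boundaries belong to the
#' non-neutral classes).
#'
#' @param score numeric polarity score(s) in \[-1, 1\].
#' @param config a [sentiment_ensemble()].
#' @return character vector of labels.
#' @export
score_to_label <- function(score, config = sentiment_ensemble()) {
  stopifnot(inherits(config, "sentiment_ensemble"))
  ifelse(score >= config$positive_threshold, "positive",
         ifelse(score <= config$negative_threshold, "negative", "neutral"))
}

#' Rule-based fusion of lexicon and contextual channel labels
#'
#' Under the default `"lexicon_positive"` rule, the lexicon ensemble governs
#' positive sentiment and the contextual channel governs the rest: if the
#' lexicon label is positive the final label is positive; otherwise the
#' contextual channel's label is final (even when that label is positive).
#' Under `"contextual_branch"` the roles of the branch test are swapped: if
#' the contextual label is positive the lexicon label is final, otherwise the
#' contextual label is final. Both rules are total on the 9
#' (lexicon, contextual) cells; see [fusion_table()].
#'
#' @param lexicon_label,contextual_label label vectors in [sentiment_levels()].
#' @param config a [sentiment_ensemble()] (only its `fusion` field is used).
#' @return character vector of final labels.
#' @export
fuse <- function(lexicon_label, contextual_label, config = sentiment_ensemble()) {
  stopifnot(inherits(config, "sentiment_ensemble"))
  if (config$fusion == "lexicon_positive")
    ifelse(lexicon_label == "positive", "positive", contextual_label)
  else
    ifelse(contextual_label == "positive", lexicon_label, contextual_label)
}

#' The full 9-cell fusion rule table
#'
#' @param config a [sentiment_ensemble()].
#' @return data.frame with columns `lexicon_label`, `contextual_label`,
#'   `final_label`, one row per input cell.
#' @export
fusion_table <- function(config = sentiment_ensemble()) {
  g <- expand.grid(lexicon_label = sentiment_levels(),
                   contextual_label = sentiment_levels(),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$final_label <- fuse(g$lexicon_label, g$contextual_label, config)
  g
}

#' Classify a corpus with the ensemble
#'
#' Scores every post on both lexicon channels, combines them by the weighted
#' average, thresholds to the lexicon label, obtains the contextual channel's
#' label, and fuses. Posts on which a channel fails are flagged (`NA` scores
#' and labels) and reported in the `diagnostics` attribute; downstream
#' aggregation excludes them.
#'
#' @param object a [sentiment_ensemble()].
#' @param newdata corpus data.frame (see [posts]).
#' @param ... unused.
#' @return the corpus with columns `lexicon_a_score`, `lexicon_b_score`,
#'   `lexicon_ensemble_score`, `lexicon_label`, `contextual_label`,
#'   `final_label` appended; attribute `diagnostics` carries
#'   `n_failed`/`failed_ids`.
#' @export
predict.sentiment_ensemble <- function(object, newdata, ...) {
  posts <- newdata
  n <- nrow(posts)
  scored <- posts
  if (n == 0L) {
    for (col in SCORE_COLUMNS)
      scored[[col]] <- if (grepl("score", col)) numeric(0) else character(0)
    attr(scored, "diagnostics") <- list(n_failed = 0L, failed_ids = character(0))
    return(scored)
  }
  ch_a <- get_scorer(object$channel_a, "polarity")$fn
  ch_b <- get_scorer(object$channel_b, "polarity")$fn
  ch_c <- get_scorer(object$contextual, "label")$fn
  run_channel <- function(fn, template) {
    out <- tryCatch(suppressWarnings(fn(posts$text)), error = function(e) NULL)
    if (!is.null(out) && length(out) == n) return(out)
    # vectorized call failed: isolate per-post failures
    vapply(posts$text, function(t)
      tryCatch(suppressWarnings(fn(t)), error = function(e) template),
      template, USE.NAMES = FALSE)
  }
  a <- run_channel(ch_a, NA_real_)
  b <- run_channel(ch_b, NA_real_)
  ctx <- run_channel(ch_c, NA_character_)
  scored$lexicon_a_score <- a
  scored$lexicon_b_score <- b
  scored$lexicon_ensemble_score <- combine_lexicon(a, b, object)
  scored$lexicon_label <- score_to_label(scored$lexicon_ensemble_score, object)
  scored$contextual_label <- as.character(ctx)
  scored$final_label <- fuse(scored$lexicon_label, scored$contextual_label, object)
  failed <- is.na(a) | is.na(b) | is.na(ctx)
  if (any(failed))
    for (col in SCORE_COLUMNS)
      scored[[col]][failed] <- if (grepl("score", col)) NA_real_ else NA_character_
  attr(scored, "diagnostics") <- list(n_failed = sum(failed),
                                      failed_ids = posts$post_id[failed])
  scored
}

#' @rdname predict.sentiment_ensemble
#' @param posts corpus data.frame.
#' @param config a [sentiment_ensemble()].
#' @export
classify_corpus <- function(posts, config = sentiment_ensemble()) {
  predict(config, posts)
}

#' Grid-search tuning of the lexicon channel weights
#'
#' Evaluates the full classifier at every candidate `weight_a` on a labelled
#' validation corpus (the original study used 1000 team-labelled posts) and
#' selects the weight maximizing macro-averaged recall over the three
#' classes. Ties are broken toward the weight closest to 0.5, then toward the
#' smaller weight, so selection is reproducible. Full per-weight confusion
#' matrices are returned for inspection.
#'
#' @param labelled corpus data.frame in which every post has a `gold_label`;
#'   all three classes must be represented.
#' @param grid candidate `weight_a` values in \[0, 1\] (`weight_b = 1 -
#'   weight_a`); default `seq(0.40, 0.60, by = 0.02)`.
#' @param config base [sentiment_ensemble()] supplying thresholds and
#'   channels.
#' @return object of class `ensemble_tuning`: list with `best_weight_a`,
#'   `best_config`, `grid` (data.frame of weight_a, macro_recall),
#'   `confusions` (list of [validate_scored()] results per weight) and `n`.
#' @export
tune_weights <- function(labelled, grid = seq(0.40, 0.60, by = 0.02),
                         config = sentiment_ensemble()) {
  if (nrow(labelled) == 0L) stop("tune_weights: labelled corpus is empty")
  if (any(is.na(labelled$gold_label)))
    stop("tune_weights: every post must carry a gold_label")
  present <- sentiment_levels() %in% labelled$gold_label
  if (!all(present))
    stop("tune_weights: labelled corpus is missing class(es): ",
         paste(sentiment_levels()[!present], collapse = ", "))
  if (any(grid < 0 | grid > 1)) stop("tune_weights: grid values must lie in [0, 1]")
  # channel outputs do not depend on the weights; score once, reweight cheaply
  base <- predict(sentiment_ensemble(
    weight_a = 0.5, weight_b = 0.5,
    positive_threshold = config$positive_threshold,
    negative_threshold = config$negative_threshold,
    channel_a = config$channel_a, channel_b = config$channel_b,
    contextual = config$contextual, fusion = config$fusion), labelled)
  results <- lapply(grid, function(w) {
    cfg <- sentiment_ensemble(
      weight_a = w, weight_b = 1 - w,
      positive_threshold = config$positive_threshold,
      negative_threshold = config$negative_threshold,
      channel_a = config$channel_a, channel_b = config$channel_b,
      contextual = config$contextual, fusion = config$fusion)
    sc <- base
    sc$lexicon_ensemble_score <- combine_lexicon(sc$lexicon_a_score,
                                                 sc$lexicon_b_score, cfg)
    sc$lexicon_label <- score_to_label(sc$lexicon_ensemble_score, cfg)
    sc$final_label <- fuse(sc$lexicon_label, sc$contextual_label, cfg)
    validate_scored(sc)
  })
  macro <- vapply(results, function(r) r$macro_recall, numeric(1))
  best_obj <- max(macro)
  cand <- which(macro >= best_obj - 1e-12)
  cand <- cand[order(abs(grid[cand] - 0.5), grid[cand])]
  best <- cand[[1]]
  out <- list(best_weight_a = grid[[best]],
              best_config = sentiment_ensemble(
                weight_a = grid[[best]], weight_b = 1 - grid[[best]],
                positive_threshold = config$positive_threshold,
                negative_threshold = config$negative_threshold,
                channel_a = config$channel_a, channel_b = config$channel_b,
                contextual = config$contextual, fusion = config$fusion),
              grid = data.frame(weight_a = grid, macro_recall = macro),
              confusions = results, n = nrow(labelled))
  class(out) <- "ensemble_tuning"
  out
}

#' @export
print.ensemble_tuning <- function(x, ...) {
  cat(sprintf("Ensemble weight tuning on %d labelled posts (%d grid points)\n",
              x$n, nrow(x$grid)))
  cat(sprintf("  best weight_a = %.3f (weight_b = %.3f), macro recall = %.4f\n",
              x$best_weight_a, 1 - x$best_weight_a,
              max(x$grid$macro_recall)))
  invisible(x)
}

#' @export
summary.ensemble_tuning <- function(object, ...) {
  print(object)
  cat("\nObjective over the grid:\n")
  print(object$grid, row.names = FALSE)
  invisible(object$grid)
}

#' @export
coef.ensemble_tuning <- function(object, ...) {
  c(weight_a = object$best_weight_a, weight_b = 1 - object$best_weight_a)
}

#' @export
plot.ensemble_tuning <- function(x, ...) {
  graphics::plot(x$grid$weight_a, x$grid$macro_recall, type = "b",
                 xlab = "weight on lexicon channel A",
                 ylab = "macro-averaged recall", ...)
  graphics::abline(v = x$best_weight_a, lty = 2)
  invisible(x)
}
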