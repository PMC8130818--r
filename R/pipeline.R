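#' Default pipeline configuration
#'
#' Returns the default end-to-end configuration as a plain list: simulate the
#' default corpus profile, apply the two-step thematic filter and the
#' March-October 2020 window, classify with the default ensemble, and write
#' weekly, regional and term-frequency summaries. Any field can be
#' overridden; a configuration may also be read from a YAML file via
#' [read_pipeline_config()].
#'
#' @param seed seed for the simulated corpus.
#' @param n_posts simulated corpus size.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1, n_posts = 2000) {
  list(
    seed = seed,
    simulate = list(n_posts = n_posts, seed = seed),
    input = NULL,                       # or list(path=, format=, platform_map=)
    lexicon = NULL,                     # path to a lexicon file; NULL = packaged
    filter = list(
      covid_keywords = covid_keyword_spec()$keywords,
      app_keywords = app_keyword_spec()$keywords,
      match_mode = "token_phrase",
      window = list(start_date = "2020-03-01", end_date = "2020-10-31",
                    language = "en")),
    ensemble = list(weight_a = 0.48, positive_threshold = 0.05,
                    negative_threshold = -0.05, fusion = "lexicon_positive",
                    contextual = "keyword_context"),
    aggregation = list(min_n = 5)
  )
}

#' @rdname default_pipeline_config
#' @param path YAML file containing (a subset of) the configuration fields.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("pipeline config not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  modify <- function(base, new) {
    for (nm in names(new))
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]))
        modify(base[[nm]], new[[nm]]) else new[[nm]]
    base
  }
  modify(cfg, user)
}

#' Run the full surveillance pipeline
#'
#' Executes simulate-or-ingest, two-step thematic filtering plus the corpus
#' window, ensemble classification, and aggregation (overall proportions,
#' weekly series, region summaries, positive/negative term tables), writing
#' every artifact plus a run manifest into a fresh, immutable run directory.
#' A rerun with the same configuration and inputs produces byte-identical
#' delimited outputs. Any stage error aborts with the stage name after
#' writing a partial manifest.
#'
#' @param config configuration list (see [default_pipeline_config()]) or the
#'   path to a YAML configuration file.
#' @param out_root directory under which the run directory is created.
#' @param run_id name of the run directory; default is a timestamped id. The
#'   directory must not already exist — prior runs are never mutated.
#' @return the run directory path, invisibly; the manifest is also returned
#'   as attribute `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_root = tempdir(), run_id = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  run_id <- run_id %||% format(Sys.time(), "run-%Y%m%dT%H%M%OS3")
  run_dir <- file.path(out_root, run_id)
  if (dir.exists(run_dir))
    stop("run directory already exists (runs are immutable): ", run_dir)
  dir.create(run_dir, recursive = TRUE)
  manifest <- list(tool = paste0("sentitrace ",
                                 as.character(utils::packageVersion("sentitrace"))),
                   run_id = run_id,
                   started = format_utc_timestamp(Sys.time()),
                   seed = config$seed, config = config,
                   input_digests = list(), counts = list())
  write_manifest <- function()
    jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  lexicon <- stage("lexicon", {
    if (is.null(config$lexicon)) fixture_lexicon()
    else if (!file.exists(config$lexicon))
      stop("lexicon file not found: ", config$lexicon)
    else read_lexicon(config$lexicon)
  })

  posts <- stage("ingest", {
    if (!is.null(config$input)) {
      manifest$input_digests[[config$input$path]] <-
        unname(tools::md5sum(config$input$path))
      do.call(read_posts, config$input)
    } else {
      spec <- do.call(generator_spec, config$simulate %||% list())
      generate_corpus(spec)
    }
  })
  manifest$counts$ingested <- nrow(posts)

  filtered <- stage("filter", {
    fc <- config$filter
    covid_spec <- keyword_filter_spec("covid-19", fc$covid_keywords,
                                      match_mode = fc$match_mode)
    app_spec <- keyword_filter_spec("contact-tracing-app", fc$app_keywords,
                                    match_mode = fc$match_mode)
    themed <- two_step_filter(posts, covid_spec, app_spec)
    w <- fc$window
    windowed <- apply_window(themed, corpus_window(w$start_date, w$end_date,
                                                   language = w$language,
                                                   region_scope = w$region_scope))
    manifest$counts$after_keyword_filter <- nrow(themed)
    windowed
  })
  manifest$counts$after_window <- nrow(filtered)

  scored <- stage("classify", {
    if (!is.null(config$lexicon)) {
      register_scorer("run_lexicon_a", function(text) score_text(text, lexicon),
                      type = "polarity", overwrite = TRUE)
      register_scorer("run_lexicon_b", function(text) score_text_mean(text, lexicon),
                      type = "polarity", overwrite = TRUE)
      ch <- c("run_lexicon_a", "run_lexicon_b")
    } else ch <- c("lexicon_a", "lexicon_b")
    ec <- config$ensemble
    ens <- sentiment_ensemble(weight_a = ec$weight_a,
                              positive_threshold = ec$positive_threshold,
                              negative_threshold = ec$negative_threshold,
                              channel_a = ch[1], channel_b = ch[2],
                              contextual = ec$contextual, fusion = ec$fusion)
    predict(ens, filtered)
  })
  diag <- attr(scored, "diagnostics")
  manifest$counts$classified <- nrow(scored) - diag$n_failed
  manifest$counts$flagged <- diag$n_failed

  stage("aggregate", {
    write_scored(scored, file.path(run_dir, "scored.csv"))
    props <- overall_proportions(scored)
    utils::write.csv(data.frame(label = names(props), proportion = unname(props)),
                     file.path(run_dir, "proportions.csv"), row.names = FALSE)
    wk <- weekly_series(scored)
    utils::write.csv(as.data.frame(wk), file.path(run_dir, "weekly.csv"),
                     row.names = FALSE)
    rs <- region_summaries(scored, region_lookup = uk_counties(),
                           min_n = config$aggregation$min_n)
    utils::write.csv(as.data.frame(rs), file.path(run_dir, "regions.csv"),
                     row.names = FALSE)
    for (lab in c("positive", "negative")) {
      tf <- term_frequencies(scored, label = lab)
      utils::write.csv(tf, file.path(run_dir, sprintf("terms_%s.csv", lab)),
                       row.names = FALSE)
    }
    manifest$counts$weeks <- nrow(wk)
    manifest$counts$regions_with_posts <- sum(rs$n_posts > 0)
    invisible(NULL)
  })

  manifest$finished <- format_utc_timestamp(Sys.time())
  write_manifest()
  yaml::write_yaml(config, file.path(run_dir, "config.yaml"))
  structure(invisible(run_dir), manifest = manifest)
}
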