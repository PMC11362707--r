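#' Build a PPHR engine from a consultation corpus
#'
#' Runs the full offline pipeline: preprocess question texts, fit the
#' embedding backend and index every historical question, fit winsor
#' bounds and per-physician response stats, build TF-IDF keyword profiles
#' and the physician-similarity matrix. The returned engine answers
#' queries through [recommend()].
#'
#' @param records Record tibble (training corpus).
#' @param backend Embedding backend (see [embedding-backends]); default
#'   [hash_ngram_backend()].
#' @param config Settings from [recommender_config()].
#' @param stoplist Character vector of stop words (default none).
#' @param tokenizer_mode,tokenizer_ngram,segmenter Passed to
#'   [preprocess_corpus()].
#' @param tfidf_top_n Keywords per physician profile (default 20).
#' @param winsor Logical: winsorize response times at the 5th/95th
#'   percentiles before computing stats (default TRUE).
#' @return A `pphr_engine` object.
#' @export
build_engine <- function(records, backend = hash_ngram_backend(),
                         config = recommender_config(),
                         stoplist = character(),
                         tokenizer_mode = "word", tokenizer_ngram = 2,
                         segmenter = NULL, tfidf_top_n = 20,
                         winsor = TRUE) {
  if (!nrow(records)) {
    stop("cannot build an engine from an empty corpus", call. = FALSE)
  }
  tokenized <- preprocess_corpus(records,
    mode = tokenizer_mode, ngram = tokenizer_ngram,
    segmenter = segmenter, stoplist = stoplist
  )
  texts <- vapply(tokenized$tokens, paste, character(1), collapse = " ")
  encoder <- fit_backend(backend, texts)
  index <- embed_texts(texts, encoder, ids = tokenized$question_id)

  resp_times <- records$response_time_min[records$response_status]
  resp_times <- resp_times[!is.na(resp_times)]
  bounds <- if (winsor && length(resp_times)) fit_winsor_bounds(resp_times) else NULL
  stats <- compute_physician_stats(records, bounds)
  global_rt <- global_mean_response_time(records, bounds)

  docs <- aggregate_by_physician(tokenized, records)
  keywords <- tfidf_top_keywords(docs, top_n = tfidf_top_n)
  profiles <- build_profiles(keywords, encoder)

  q2p <- stats::setNames(records$physician_code, records$question_id)
  structure(
    list(
      corpus = tibble::tibble(
        question_id = tokenized$question_id,
        physician_code = unname(q2p[tokenized$question_id]),
        text = texts
      ),
      index = index,
      question_to_physician = q2p,
      stats = stats,
      profiles = profiles,
      bounds = bounds,
      global_mean_rt = global_rt,
      encoder = encoder,
      config = config,
      tokenizer = list(
        mode = tokenizer_mode, ngram = tokenizer_ngram,
        stoplist = stoplist, segmenter = segmenter
      ),
      n_records = nrow(records)
    ),
    class = "pphr_engine"
  )
}

#' @export
print.pphr_engine <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<pphr_engine> %d questions, %d physicians [%s]\n",
      "  top_m=%d threshold=%.2f k=%d aggregation=%s rate_exponent=%g\n"
    ),
    length(x$index$ids), nrow(x$stats), x$index$backend_tag,
    x$config$top_m, x$config$threshold, x$config$k,
    x$config$aggregation, x$config$rate_exponent
  ))
  invisible(x)
}

# Preprocess + embed one query with the engine's pipeline.
.embed_query <- function(engine, query_text) {
  tok <- preprocess_corpus(
    tibble::tibble(question_id = "query", question_text = query_text),
    mode = engine$tokenizer$mode, ngram = engine$tokenizer$ngram,
    segmenter = engine$tokenizer$segmenter,
    stoplist = engine$tokenizer$stoplist
  )
  text <- paste(tok$tokens[[1]], collapse = " ")
  engine$encoder(text)[1, ]
}

#' Recommend physicians for a new question
#'
#' Runs the engine's pipeline on a free-text question and returns the
#' top-K list. The `mode` selects the ablation:
#' `"PFB"` (retrieval only, ranked by `init_score`), `"PPH"` (retrieval +
#' semantic expansion, ranked by aggregate `physician_score`), or
#' `"PPHR"` (the full model with response-rate weighting).
#'
#' @param engine A `pphr_engine`.
#' @param query_text The patient's question (free text).
#' @param k List length; default from the engine config (14).
#' @param mode `"PPHR"` (default), `"PFB"` or `"PPH"`.
#' @param query_id Optional identifier carried through to the result.
#' @return A `pphr_recommendation` (see [rank_candidates()]).
#' @export
recommend <- function(engine, query_text, k = engine$config$k,
                      mode = c("PPHR", "PFB", "PPH"),
                      query_id = NA_character_) {
  stopifnot(inherits(engine, "pphr_engine"))
  mode <- match.arg(mode)
  qv <- .embed_query(engine, query_text)
  direct <- generate_candidates(
    qv, engine$index, engine$question_to_physician,
    top_m = engine$config$top_m, top_k = engine$config$top_k_physicians
  )
  cand <- if (mode == "PFB") {
    direct
  } else {
    expand_candidates(direct, engine$profiles$similarity,
      threshold = engine$config$threshold
    )
  }
  rank_candidates(cand, engine$stats, k,
    mode = mode, config = engine$config, query_id = query_id
  )
}

#' Persist an engine state to a directory
#'
#' Writes a plain-text snapshot: the run configuration (YAML), physician
#' stats (CSV), keyword profiles (JSONL), the physician-similarity matrix
#' (CSV) and the preprocessed question corpus (TSV). [load_engine()]
#' rebuilds the engine from the snapshot deterministically (the encoder is
#' re-fitted to the stored corpus, which for the bundled backends
#' reproduces identical vectors).
#'
#' @param engine A `pphr_engine`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_engine <- function(engine, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- engine$config
  cfg$backend_tag <- engine$index$backend_tag
  cfg$tokenizer_mode <- engine$tokenizer$mode
  cfg$tokenizer_ngram <- engine$tokenizer$ngram
  cfg$global_mean_rt <- engine$global_mean_rt
  if (!is.null(engine$bounds)) {
    cfg$winsor_lower <- engine$bounds$lower_min
    cfg$winsor_upper <- engine$bounds$upper_min
  }
  cfg$tfidf_top_n <- max(vapply(
    engine$profiles$profiles$keywords, nrow, integer(1)
  ))
  cfg$backend_name <- sub("\\(.*$", "", engine$index$backend_tag)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  write_physician_stats(engine$stats, file.path(dir, "stats.csv"))
  write_profiles(engine$profiles,
    file.path(dir, "profiles.jsonl"),
    file.path(dir, "similarity.csv")
  )
  utils::write.table(
    engine$corpus,
    file.path(dir, "corpus.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"
  )
  invisible(dir)
}

#' Load an engine state from a directory
#'
#' Rebuilds a `pphr_engine` from a [save_engine()] snapshot. The embedding
#' backend is re-fitted to the stored preprocessed corpus; for the bundled
#' deterministic backends this reproduces the saved vectors exactly. The
#' stored question texts are already preprocessed, so the loaded engine
#' tokenizes queries with the saved tokenizer settings but indexes the
#' snapshot verbatim.
#'
#' @param dir Directory written by [save_engine()].
#' @param backend Embedding backend to fit; when `NULL`, reconstructed from
#'   the snapshot's `backend_name` with default parameters.
#' @return A `pphr_engine`.
#' @export
load_engine <- function(dir, backend = NULL) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path)) {
    stop(
      "no engine state at ", dir,
      " (missing config.yaml); run the build step first",
      call. = FALSE
    )
  }
  cfg <- yaml::read_yaml(cfg_path)
  corpus <- tibble::as_tibble(utils::read.table(
    file.path(dir, "corpus.tsv"),
    sep = "\t", header = TRUE,
    colClasses = "character", quote = "", comment.char = "",
    fileEncoding = "UTF-8"
  ))
  stats <- tibble::as_tibble(utils::read.csv(
    file.path(dir, "stats.csv"),
    colClasses = c(physician_code = "character")
  ))
  # rate and mean are derived quantities; recompute them from the exact
  # stored counts so a text round-trip cannot perturb ranking scores
  stats$response_rate <- stats$n_responded / stats$n_total
  stats$mean_response_time_min <- ifelse(
    stats$n_responded > 0,
    stats$total_response_time_min / stats$n_responded,
    NA_real_
  )
  if (is.null(backend)) {
    backend <- switch(cfg$backend_name,
      hash_ngram = hash_ngram_backend(),
      paragraph_vector = paragraph_vector_backend(),
      stop("cannot reconstruct backend '", cfg$backend_name,
        "'; pass backend=",
        call. = FALSE
      )
    )
  }
  encoder <- fit_backend(backend, corpus$text)
  index <- embed_texts(corpus$text, encoder, ids = corpus$question_id)
  kw_lines <- readLines(file.path(dir, "profiles.jsonl"),
    encoding = "UTF-8",
    warn = FALSE
  )
  keywords <- list()
  for (l in kw_lines[nzchar(kw_lines)]) {
    obj <- jsonlite::fromJSON(l)
    kw <- tibble::as_tibble(obj$keywords)
    if (!nrow(kw)) kw <- tibble::tibble(term = character(), weight = numeric())
    keywords[[as.character(obj$physician_code)]] <- kw
  }
  profiles <- build_profiles(keywords, encoder)
  bounds <- if (!is.null(cfg$winsor_lower)) {
    structure(
      list(lower_min = cfg$winsor_lower, upper_min = cfg$winsor_upper),
      class = "winsor_bounds"
    )
  } else {
    NULL
  }
  structure(
    list(
      corpus = corpus,
      index = index,
      question_to_physician = stats::setNames(
        corpus$physician_code, corpus$question_id
      ),
      stats = stats,
      profiles = profiles,
      bounds = bounds,
      global_mean_rt = cfg$global_mean_rt,
      encoder = encoder,
      config = recommender_config(
        top_m = cfg$top_m, top_k_physicians = cfg$top_k_physicians,
        threshold = cfg$threshold, k = cfg$k,
        aggregation = cfg$aggregation, rate_exponent = cfg$rate_exponent
      ),
      tokenizer = list(
        mode = cfg$tokenizer_mode, ngram = cfg$tokenizer_ngram,
        stoplist = character(), segmenter = NULL
      ),
      n_records = nrow(corpus)
    ),
    class = "pphr_engine"
  )
}
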