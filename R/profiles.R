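#' Aggregate tokenized questions into per-physician pseudo-documents
#'
#' Each physician's document is the concatenation of the token lists of all
#' questions addressed to them, in corpus order. Physicians with no
#' questions are absent from the result.
#'
#' @param tokenized Tibble from [preprocess_corpus()] (`question_id`,
#'   `tokens` list-column).
#' @param records Record tibble mapping `question_id` to `physician_code`.
#' @return Named list: physician code -> character vector of tokens.
#' @export
aggregate_by_physician <- function(tokenized, records) {
  idx <- match(tokenized$question_id, records$question_id)
  if (anyNA(idx)) {
    orphan <- tokenized$question_id[which(is.na(idx))[1]]
    stop("question_id not present in records: ", orphan, call. = FALSE)
  }
  phys <- records$physician_code[idx]
  docs <- split(tokenized$tokens, phys)
  lapply(docs, function(x) unlist(x, use.names = FALSE))
}

#' Top TF-IDF keywords per physician document
#'
#' For term `t` in document `d`: `TF(t, d)` is by default the relative
#' frequency of `t` in `d` (`count / length`, switchable to the raw count),
#' and `IDF(t)` is by default the smoothed inverse document frequency
#' `ln((1 + N) / (1 + df(t))) + 1` (switchable to the plain
#' `ln(N / df(t))`, which gives weight 0 to terms present in every
#' document). The product ranks terms; the `top_n` highest-weighted terms
#' describe what a physician is consulted about. Ties are broken by
#' ascending term so the selection is deterministic.
#'
#' Result tables should name the variant used; the default is
#' relative-frequency TF with smoothed IDF.
#'
#' @param documents Named list from [aggregate_by_physician()].
#' @param top_n Keywords to keep per document (default 20).
#' @param tf_mode `"relative"` or `"raw"`.
#' @param idf_mode `"smooth"` or `"plain"`.
#' @return Named list: code -> tibble(`term`, `weight`) with non-increasing
#'   positive weights (at most `top_n` rows). Empty documents yield an
#'   empty table with a warning.
#' @export
tfidf_top_keywords <- function(documents, top_n = 20,
                               tf_mode = c("relative", "raw"),
                               idf_mode = c("smooth", "plain")) {
  tf_mode <- match.arg(tf_mode)
  idf_mode <- match.arg(idf_mode)
  if (!length(documents)) {
    stop("no documents", call. = FALSE)
  }
  n_docs <- length(documents)
  df_tab <- table(unlist(lapply(documents, unique), use.names = FALSE))
  idf <- if (idf_mode == "smooth") {
    log((1 + n_docs) / (1 + as.numeric(df_tab))) + 1
  } else {
    log(n_docs / as.numeric(df_tab))
  }
  names(idf) <- names(df_tab)

  out <- lapply(names(documents), function(code) {
    doc <- documents[[code]]
    if (!length(doc)) {
      warning("physician ", code, " has an empty document; no keywords",
        call. = FALSE
      )
      return(tibble::tibble(term = character(), weight = numeric()))
    }
    counts <- table(doc)
    tf <- if (tf_mode == "relative") {
      as.numeric(counts) / length(doc)
    } else {
      as.numeric(counts)
    }
    w <- tf * idf[names(counts)]
    res <- tibble::tibble(term = names(counts), weight = unname(w))
    res <- res[order(-res$weight, res$term), ]
    res <- res[res$weight > 0, ]
    utils::head(res, top_n)
  })
  names(out) <- names(documents)
  out
}

#' Build physician profiles and their pairwise similarity
#'
#' Each physician's profile text is their keywords joined by single spaces
#' in descending-weight order; the profile vector is its embedding, and the
#' physician-physician similarity matrix is the pairwise cosine of profile
#' vectors. This similarity is the `expand_score` source of the
#' recommender's semantic-expansion step. Physicians with no keywords get
#' no profile (they can never be expansion targets) and are reported via a
#' warning.
#'
#' @param keywords Named list from [tfidf_top_keywords()].
#' @param backend Embedding backend or fitted encoder (see
#'   [embedding-backends]).
#' @return A `physician_profiles` object: list with `profiles` (tibble:
#'   `physician_code`, `profile_text`, `keywords` list-column),
#'   `vectors` (an `embedding_matrix`) and `similarity` (square symmetric
#'   matrix with unit diagonal, dimnames = physician codes).
#' @export
build_profiles <- function(keywords, backend = hash_ngram_backend()) {
  keep <- vapply(keywords, nrow, integer(1)) > 0
  if (any(!keep)) {
    warning(
      "no profile for physician(s) without keywords: ",
      paste(names(keywords)[!keep], collapse = ", "),
      call. = FALSE
    )
  }
  keywords <- keywords[keep]
  if (!length(keywords)) {
    stop("no physician has any keywords; cannot build profiles", call. = FALSE)
  }
  codes <- names(keywords)
  profile_text <- vapply(
    keywords, function(k) paste(k$term, collapse = " "), character(1)
  )
  emb <- embed_texts(unname(profile_text), backend, ids = codes)
  sim <- emb$vectors %*% t(emb$vectors)
  sim <- (sim + t(sim)) / 2 # enforce exact symmetry
  diag(sim) <- 1
  dimnames(sim) <- list(codes, codes)
  structure(
    list(
      profiles = tibble::tibble(
        physician_code = codes,
        profile_text = unname(profile_text),
        keywords = unname(keywords)
      ),
      vectors = emb,
      similarity = sim
    ),
    class = "physician_profiles"
  )
}

#' @export
print.physician_profiles <- function(x, ...) {
  cat(sprintf(
    "<physician_profiles> %d physicians [%s]\n",
    nrow(x$profiles), x$vectors$backend_tag
  ))
  invisible(x)
}

#' Export profiles as JSONL and similarity as CSV
#'
#' @param profiles A `physician_profiles` object.
#' @param jsonl_path Path for keyword profiles (one JSON object per
#'   physician).
#' @param sim_path Optional path for the similarity matrix as square CSV.
#' @return `jsonl_path`, invisibly.
#' @export
write_profiles <- function(profiles, jsonl_path, sim_path = NULL) {
  con <- file(jsonl_path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  p <- profiles$profiles
  for (i in seq_len(nrow(p))) {
    writeLines(jsonlite::toJSON(
      list(
        physician_code = p$physician_code[i],
        keywords = p$keywords[[i]]
      ),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    ), con)
  }
  if (!is.null(sim_path)) {
    utils::write.csv(profiles$similarity, sim_path, row.names = TRUE)
  }
  invisible(jsonl_path)
}
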