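#' Text-embedding backends
#'
#' The recommender is encoder-agnostic: any backend that maps texts to
#' fixed-dimension L2-normalized vectors can drive it. Three backends are
#' provided behind one contract:
#'
#' * [hash_ngram_backend()] — the default. Character n-grams are mapped by a
#'   stable polynomial hash into `dim` buckets; the bucket-count vector is
#'   L2-normalized. Fully deterministic, needs no training and no model
#'   download, and platform-stable (the hash is fixed arithmetic on Unicode
#'   code points, not `R`'s internal hashing).
#' * [paragraph_vector_backend()] — a corpus-trained static paragraph
#'   embedding: every vocabulary word receives a seeded random Gaussian
#'   vector and a document is the TF-IDF-weighted sum of its word vectors
#'   (random-indexing family). Deterministic for a fixed seed; used as the
#'   non-contextual baseline encoder.
#' * [transformer_backend()] — delegates to a user-configured pretrained
#'   sentence encoder (e.g. a multilingual SBERT model served from another
#'   process). If no encoder function is configured, using it raises an
#'   explicit backend-unavailable error; there is never a silent fallback.
#'
#' A backend is *fitted* to a corpus with [fit_backend()], which returns an
#' encoder function usable for both the corpus and later queries.
#'
#' @name embedding-backends
NULL

# Stable polynomial hash of a string over its Unicode code points.
# h <- (h * 31 + cp) mod 2^25; exact in double arithmetic.
.hash_string <- function(s, mod = 2^25) {
  cps <- utf8ToInt(s)
  h <- 0
  for (cp in cps) {
    h <- (h * 31 + cp) %% mod
  }
  h
}

#' Hashed character n-gram backend
#'
#' @param dim Number of hash buckets (embedding dimension), default 256.
#' @param ngram Character n-gram size, default 3.
#' @return A backend object.
#' @export
hash_ngram_backend <- function(dim = 256, ngram = 3) {
  structure(
    list(
      name = "hash_ngram", dim = dim, ngram = ngram,
      tag = sprintf("hash_ngram(dim=%d,n=%d)", dim, ngram)
    ),
    class = c("hash_ngram_backend", "pphr_backend")
  )
}

#' Corpus-trained paragraph-vector backend
#'
#' @param dim Embedding dimension, default 64.
#' @param seed Seed for the word projection vectors, default 42.
#' @return A backend object.
#' @export
paragraph_vector_backend <- function(dim = 64, seed = 42) {
  structure(
    list(
      name = "paragraph_vector", dim = dim, seed = seed,
      tag = sprintf("paragraph_vector(dim=%d,seed=%d)", dim, seed)
    ),
    class = c("paragraph_vector_backend", "pphr_backend")
  )
}

#' Pretrained transformer sentence-encoder backend
#'
#' @param model_id Identifier of the sentence-encoder model the deployment
#'   serves (default `"distiluse-base-multilingual-cased"`).
#' @param encode_fun Function taking a character vector and returning a
#'   numeric matrix with one row per text. When `NULL` (no encoder wired
#'   in), fitting the backend raises a backend-unavailable error.
#' @param dim Expected embedding dimension (default 512).
#' @return A backend object.
#' @export
transformer_backend <- function(model_id = "distiluse-base-multilingual-cased",
                                encode_fun = NULL, dim = 512) {
  structure(
    list(
      name = "transformer", model_id = model_id,
      encode_fun = encode_fun, dim = dim,
      tag = sprintf("transformer(%s)", model_id)
    ),
    class = c("transformer_backend", "pphr_backend")
  )
}

#' @export
print.pphr_backend <- function(x, ...) {
  cat("<pphr_backend>", x$tag, "\n")
  invisible(x)
}

.l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop("embedding produced a zero vector (empty text?)", call. = FALSE)
  }
  m / nrm
}

#' Fit a backend to a corpus
#'
#' Returns an encoder: a function mapping a character vector of texts to an
#' L2-normalized embedding matrix, with a `tag` attribute recording
#' provenance. Stateless backends (hash n-gram) ignore the corpus; the
#' paragraph-vector backend builds its vocabulary and IDF table from it.
#'
#' @param backend A backend object.
#' @param texts Corpus texts used for training where applicable.
#' @return Encoder function.
#' @export
fit_backend <- function(backend, texts = character()) {
  UseMethod("fit_backend")
}

#' @export
fit_backend.hash_ngram_backend <- function(backend, texts = character()) {
  dim <- backend$dim
  ngram <- backend$ngram
  enc <- function(texts) {
    grams <- lapply(texts, tokenize_text, mode = "chargram", ngram = ngram)
    vocab <- unique(unlist(grams, use.names = FALSE))
    bucket <- vapply(vocab, function(g) .hash_string(g) %% dim + 1, numeric(1))
    m <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      if (length(grams[[i]])) {
        m[i, ] <- tabulate(bucket[match(grams[[i]], vocab)], nbins = dim)
      }
    }
    .l2_normalize_rows(m)
  }
  attr(enc, "tag") <- backend$tag
  attr(enc, "embedding_dim") <- dim
  enc
}

#' @export
fit_backend.paragraph_vector_backend <- function(backend, texts = character()) {
  dim <- backend$dim
  seed <- backend$seed
  cache <- new.env(parent = emptyenv())
  word_vec <- function(w) {
    # Word projections are seeded from a hash of the word so they are
    # identical across sessions and independent of corpus order.
    if (is.null(cache[[w]])) {
      cache[[w]] <- withr::with_seed(
        as.integer((.hash_string(w) + seed) %% (2^31 - 1)),
        stats::rnorm(dim)
      )
    }
    cache[[w]]
  }
  toks <- lapply(texts, function(t) tokenize_text(t, mode = "word"))
  n_docs <- max(length(toks), 1)
  df <- table(unlist(lapply(toks, unique), use.names = FALSE))
  idf <- function(w) {
    d <- if (w %in% names(df)) df[[w]] else 0
    log((1 + n_docs) / (1 + d)) + 1
  }
  enc <- function(texts) {
    m <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      tok <- tokenize_text(texts[i], mode = "word")
      if (!length(tok)) next
      tf <- table(tok) / length(tok)
      for (w in names(tf)) {
        m[i, ] <- m[i, ] + tf[[w]] * idf(w) * word_vec(w)
      }
    }
    .l2_normalize_rows(m)
  }
  attr(enc, "tag") <- backend$tag
  attr(enc, "embedding_dim") <- dim
  enc
}

#' @export
fit_backend.transformer_backend <- function(backend, texts = character()) {
  if (is.null(backend$encode_fun)) {
    stop(
      "transformer backend unavailable: no encoder configured for model '",
      backend$model_id, "'. Supply encode_fun= or use hash_ngram_backend().",
      call. = FALSE
    )
  }
  f <- backend$encode_fun
  enc <- function(texts) .l2_normalize_rows(f(texts))
  attr(enc, "tag") <- backend$tag
  attr(enc, "embedding_dim") <- backend$dim
  enc
}

#' Embed a set of texts
#'
#' Fits (if needed) and applies a backend, returning an `embedding_matrix`:
#' ids, one L2-normalized vector per id, the dimension and a provenance
#' tag. Because all vectors are unit-norm, cosine similarity reduces to a
#' dot product.
#'
#' @param texts Character vector; none may be empty.
#' @param backend A backend object or an encoder from [fit_backend()].
#' @param ids Item identifiers (default `seq_along(texts)` as character).
#' @return An `embedding_matrix` object.
#' @export
embed_texts <- function(texts, backend = hash_ngram_backend(), ids = NULL) {
  if (!length(texts)) {
    stop("no texts to embed", call. = FALSE)
  }
  if (any(is.na(texts) | !nzchar(texts))) {
    stop("empty text at position ",
      which(is.na(texts) | !nzchar(texts))[1],
      call. = FALSE
    )
  }
  ids <- as.character(ids %||% seq_along(texts))
  if (anyDuplicated(ids)) {
    stop("duplicate ids in embedding index", call. = FALSE)
  }
  enc <- if (is.function(backend)) backend else fit_backend(backend, texts)
  m <- enc(texts)
  rownames(m) <- ids
  structure(
    list(
      ids = ids, vectors = m, dim = ncol(m),
      backend_tag = attr(enc, "tag") %||% "custom"
    ),
    class = "embedding_matrix"
  )
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf(
    "<embedding_matrix> %d items x %d dims [%s]\n",
    length(x$ids), x$dim, x$backend_tag
  ))
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' `u . v / (||u|| ||v||)`; symmetric and scale-invariant.
#'
#' @param u,v Numeric vectors of equal length with positive norm.
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' cosine_sim(c(1, 2, 3), c(4, 5, 6)) # 32 / sqrt(14 * 77)
cosine_sim <- function(u, v) {
  if (length(u) != length(v)) {
    stop("dimension mismatch", call. = FALSE)
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine undefined for zero-norm vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

#' Nearest neighbours by cosine similarity
#'
#' Ranks all indexed items against a query vector and returns the top `m`.
#' Ties are broken by ascending id so results are deterministic.
#'
#' @param query Numeric query vector (any positive norm; normalized
#'   internally).
#' @param index An `embedding_matrix`.
#' @param top_m Number of results; if it exceeds the index size the full
#'   ranking is returned with a warning.
#' @return Tibble with `id` and `score`, sorted by descending score.
#' @export
similarity_search <- function(query, index, top_m = 10) {
  stopifnot(inherits(index, "embedding_matrix"), top_m >= 1)
  if (length(query) != index$dim) {
    stop("query dimension ", length(query), " != index dimension ", index$dim,
      call. = FALSE
    )
  }
  nq <- sqrt(sum(query^2))
  if (nq == 0) {
    stop("cosine undefined for zero-norm query", call. = FALSE)
  }
  scores <- as.vector(index$vectors %*% (query / nq))
  if (top_m > length(scores)) {
    warning("top_m exceeds index size; returning full ranking", call. = FALSE)
    top_m <- length(scores)
  }
  ord <- order(-scores, index$ids)[seq_len(top_m)]
  tibble::tibble(id = index$ids[ord], score = scores[ord])
}
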