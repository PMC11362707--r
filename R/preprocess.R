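#' Normalize free text
#'
#' Unicode NFKC normalization (full-width characters become half-width),
#' case folding, collapse of internal whitespace runs to single spaces and
#' stripping of leading/trailing whitespace. Idempotent:
#' `normalize_text(normalize_text(x)) == normalize_text(x)`.
#'
#' @param text Character vector.
#' @return Normalized character vector of the same length.
#' @export
#' @examples
#' normalize_text("  Hello　WORLD ")
normalize_text <- function(text) {
  text[is.na(text)] <- ""
  out <- stringi::stri_trans_nfkc(text)
  out <- stringi::stri_trans_tolower(out)
  out <- stringi::stri_replace_all_regex(out, "\\s+", " ")
  stringi::stri_trim_both(out)
}

#' Tokenize a question text
#'
#' Two modes:
#' * `"word"` splits on whitespace, or through a user-supplied `segmenter`
#'   function for languages without whitespace word boundaries (e.g. a
#'   Chinese segmenter); the segmenter takes one string and returns a
#'   character vector of tokens.
#' * `"chargram"` emits overlapping character n-grams (whitespace removed
#'   first, so tokens never contain spaces), which needs no segmenter at
#'   all. A length-L string yields `max(L - n + 1, 0)` grams.
#'
#' @param text A single string, ideally already passed through
#'   [normalize_text()].
#' @param mode `"word"` or `"chargram"`.
#' @param ngram n-gram size for chargram mode (default 2).
#' @param segmenter Optional function used in word mode in place of
#'   whitespace splitting.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_text <- function(text, mode = c("word", "chargram"), ngram = 2,
                          segmenter = NULL) {
  mode <- match.arg(mode)
  if (is.na(text) || !nzchar(text)) {
    return(character())
  }
  if (mode == "word") {
    if (!is.null(segmenter)) {
      toks <- as.character(segmenter(text))
    } else {
      toks <- stringi::stri_split_regex(text, "\\s+")[[1]]
    }
    return(toks[nzchar(toks)])
  }
  s <- stringi::stri_replace_all_regex(text, "\\s+", "")
  L <- stringi::stri_length(s)
  if (L < ngram) {
    return(if (L > 0) s else character())
  }
  stringi::stri_sub(s, seq_len(L - ngram + 1), length = ngram)
}

#' Remove stop words from a token list
#'
#' Order-preserving filter; idempotent.
#'
#' @param tokens Character vector of tokens.
#' @param stoplist Character vector (or set) of stop words.
#' @return `tokens` without any member of `stoplist`.
#' @export
remove_stopwords <- function(tokens, stoplist) {
  tokens[!(tokens %in% stoplist)]
}

#' Read a stop-word file
#'
#' One token per line, UTF-8; blank lines and lines starting with `#` are
#' ignored. No list ships with the package — stop lists are corpus- and
#' language-specific configuration.
#'
#' @param path File path.
#' @return Character vector of stop words.
#' @export
read_stopwords <- function(path) {
  lines <- stringi::stri_trim_both(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Preprocess a corpus of question texts
#'
#' Runs normalize -> tokenize -> stop-word removal over every record and
#' returns one tokenized question per record. A question whose token list
#' becomes empty after filtering falls back to its normalized raw text as a
#' single token (internal spaces replaced by `_`), so that every record
#' stays embeddable.
#'
#' An optional `pos_filter` hook supports part-of-speech based filtering:
#' it receives the token vector and returns the tokens to keep. The default
#' pipeline does not tag.
#'
#' @param records Record tibble (needs `question_id`, `question_text`).
#' @param mode,ngram,segmenter Passed to [tokenize_text()].
#' @param stoplist Character vector of stop words (default none).
#' @param pos_filter Optional function `tokens -> tokens`.
#' @return Tibble with `question_id` and a `tokens` list-column.
#' @export
preprocess_corpus <- function(records, mode = c("word", "chargram"), ngram = 2,
                              segmenter = NULL, stoplist = character(),
                              pos_filter = NULL) {
  mode <- match.arg(mode)
  norm <- normalize_text(records$question_text)
  toks <- lapply(seq_along(norm), function(i) {
    t <- tokenize_text(norm[i], mode = mode, ngram = ngram, segmenter = segmenter)
    if (!is.null(pos_filter)) t <- pos_filter(t)
    t <- remove_stopwords(t, stoplist)
    if (!length(t)) {
      t <- stringi::stri_replace_all_regex(norm[i], "\\s+", "_")
    }
    t
  })
  tibble::tibble(question_id = records$question_id, tokens = toks)
}
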