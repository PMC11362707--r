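#' The three-step PPHR recommendation engine
#'
#' Given a new question, the engine produces a ranked top-K physician list
#' in three steps:
#'
#' 1. **Candidate generation (patient feature-based, PFB).** The query is
#'    embedded and the `top_m` most similar historical questions are
#'    retrieved. Their physicians become *direct* candidates; a physician's
#'    `init_score` is the maximum cosine similarity among their matched
#'    questions, and `n` counts the matches.
#' 2. **Semantic expansion (patient-physician hybrid, PPH).** For every
#'    direct candidate `i` and every other profiled physician `j`,
#'    `physician_score = init_score_i * sim(i, j)` (the similarity comes
#'    from the TF-IDF profile embeddings). When this product exceeds the
#'    expansion threshold (default 0.7), `j` joins the pool as an
#'    *expanded* candidate. Direct candidates keep `expand_score = 1`, so
#'    their `physician_score` equals their `init_score`.
#' 3. **Response-rate ranking (PPHR).** Candidates are ordered by
#'    `response_rate^e * A`, where `A` aggregates the candidate's matched
#'    occurrences of `physician_score` (default: `n * physician_score`) and
#'    `e` is a configurable exponent (default 1). This skews the list
#'    toward physicians who actually answer.
#'
#' The three ablation modes (`"PFB"`, `"PPH"`, `"PPHR"`) share the same
#' retrieval, so comparisons isolate exactly one mechanism.
#'
#' @name pphr-engine
NULL

#' Default recommender configuration
#'
#' @param top_m Size of the similar-question pool retrieved before grouping
#'   by physician (default 50).
#' @param top_k_physicians Direct candidates kept after grouping (default
#'   `top_m`, i.e. all physicians owning a retrieved question).
#' @param threshold Expansion gate on `physician_score` (default 0.7).
#' @param k List length of the final recommendation (default 14).
#' @param aggregation How a direct candidate's matched occurrences combine
#'   in the ranking score: `"count"` (`n * physician_score`) or
#'   `"sum_sim"` (sum of the matched questions' similarities).
#' @param rate_exponent Exponent on the response rate in the PPHR score
#'   (default 1).
#' @return A named list of settings.
#' @export
recommender_config <- function(top_m = 50, top_k_physicians = top_m,
                               threshold = 0.7, k = 14,
                               aggregation = c("count", "sum_sim"),
                               rate_exponent = 1) {
  list(
    top_m = top_m, top_k_physicians = top_k_physicians,
    threshold = threshold, k = k,
    aggregation = match.arg(aggregation),
    rate_exponent = rate_exponent
  )
}

#' Generate direct candidates from similar questions
#'
#' Retrieves the `top_m` indexed questions most similar to the query,
#' groups them by physician, and keeps the `top_k` physicians by
#' `init_score` (their best matched similarity). All direct candidates
#' carry `expand_score = 1` and `physician_score = init_score`.
#'
#' @param query_vector Numeric query embedding.
#' @param question_index An `embedding_matrix` over historical questions.
#' @param question_to_physician Named character vector mapping question ids
#'   to physician codes.
#' @param top_m Similar-question pool size.
#' @param top_k Maximum number of physicians kept.
#' @return Candidate tibble: `physician_code`, `init_score`,
#'   `expand_score`, `physician_score`, `n`, `sim_sum`, `origin`,
#'   `seed_code`.
#' @export
generate_candidates <- function(query_vector, question_index,
                                question_to_physician,
                                top_m = 50, top_k = top_m) {
  stopifnot(top_m >= 1, top_k >= 1)
  if (!length(question_index$ids)) {
    stop("empty question index", call. = FALSE)
  }
  hits <- suppressWarnings(
    similarity_search(query_vector, question_index, top_m)
  )
  phys <- unname(question_to_physician[hits$id])
  if (anyNA(phys)) {
    stop("retrieved question with no physician mapping: ",
      hits$id[which(is.na(phys))[1]],
      call. = FALSE
    )
  }
  by_phys <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(physician_code = phys, score = hits$score),
      .data$physician_code
    ),
    init_score = max(.data$score),
    n = dplyr::n(),
    sim_sum = sum(.data$score),
    .groups = "drop"
  )
  by_phys <- by_phys[order(-by_phys$init_score, by_phys$physician_code), ]
  by_phys <- utils::head(by_phys, top_k)
  tibble::tibble(
    physician_code = by_phys$physician_code,
    init_score = by_phys$init_score,
    expand_score = 1,
    physician_score = by_phys$init_score,
    n = by_phys$n,
    sim_sum = by_phys$sim_sum,
    origin = "direct",
    seed_code = NA_character_
  )
}

#' Expand the candidate pool through physician similarity
#'
#' For each direct candidate `i` and each other physician `j` in the
#' similarity matrix, the propagated score is
#' `init_score_i * sim(i, j)`. `j` is added as an expanded candidate iff
#' that product exceeds `threshold` and `j` is not already a direct
#' candidate. When several seeds retain the same `j`, the candidate keeps
#' the maximal product as its `physician_score` (its `seed_code` is that
#' seed), `n` counts the retaining seeds and `sim_sum` accumulates the
#' retained products. Direct candidates pass through unchanged.
#'
#' @param direct Candidate tibble from [generate_candidates()].
#' @param similarity Physician-similarity matrix (from [build_profiles()]).
#' @param threshold Expansion gate, in `(0, 1]`, default 0.7.
#' @return Candidate tibble (direct rows first, then expanded).
#' @export
expand_candidates <- function(direct, similarity, threshold = 0.7) {
  stopifnot(threshold > 0, threshold <= 1)
  codes <- rownames(similarity)
  expanded <- list()
  for (i in seq_len(nrow(direct))) {
    seed <- direct$physician_code[i]
    if (!(seed %in% codes)) {
      warning("physician ", seed, " missing from similarity matrix; ",
        "not used as an expansion seed",
        call. = FALSE
      )
      next
    }
    sims <- similarity[seed, ]
    others <- setdiff(codes, direct$physician_code)
    prod <- direct$init_score[i] * sims[others]
    keep <- others[prod > threshold]
    if (length(keep)) {
      expanded[[length(expanded) + 1]] <- tibble::tibble(
        physician_code = keep,
        init_score = direct$init_score[i],
        expand_score = unname(sims[keep]),
        physician_score = unname(prod[keep]),
        n = 1L,
        sim_sum = unname(prod[keep]),
        origin = "expanded",
        seed_code = seed
      )
    }
  }
  if (!length(expanded)) {
    return(direct)
  }
  exp_all <- dplyr::bind_rows(expanded)
  # Several seeds may retain the same physician: keep the maximal product,
  # count retaining seeds, accumulate their contributions.
  exp_best <- dplyr::arrange(
    exp_all, .data$physician_code,
    dplyr::desc(.data$physician_score), .data$seed_code
  )
  agg <- dplyr::summarise(
    dplyr::group_by(exp_best, .data$physician_code),
    init_score = dplyr::first(.data$init_score),
    expand_score = dplyr::first(.data$expand_score),
    physician_score = dplyr::first(.data$physician_score),
    n = dplyr::n(),
    sim_sum = sum(.data$sim_sum),
    origin = "expanded",
    seed_code = dplyr::first(.data$seed_code),
    .groups = "drop"
  )
  dplyr::bind_rows(direct, agg)
}

#' Rank candidates into a top-K recommendation
#'
#' Applies the mode's scoring rule and returns the top `k` candidates:
#' * `"PFB"` ranks direct candidates by `init_score` alone.
#' * `"PPH"` ranks the expanded pool by the aggregate similarity `A`
#'   (see below) without response rates.
#' * `"PPHR"` ranks by `response_rate^e * A`.
#'
#' `A` for a direct candidate is `n * physician_score` under the default
#' `"count"` aggregation, or the sum of its matched question similarities
#' under `"sum_sim"`; for an expanded candidate it is the sum of the
#' retained seed products. Candidates without stats are scored with
#' response rate 0 (reported via a message). Ties break by descending
#' `physician_score`, then ascending code.
#'
#' @param candidates Candidate tibble.
#' @param stats Physician stats tibble from [compute_physician_stats()].
#' @param k List length (>= 1).
#' @param mode `"PFB"`, `"PPH"` or `"PPHR"`.
#' @param config Settings from [recommender_config()].
#' @param query_id Optional identifier stored on the result.
#' @return A `pphr_recommendation`: list with `query_id`, `mode`, `k`,
#'   `ranked` (tibble: `rank`, `physician_code`, `score`,
#'   `physician_score`, `origin`) and `pool` (all scored candidates).
#' @export
rank_candidates <- function(candidates, stats, k,
                            mode = c("PPHR", "PFB", "PPH"),
                            config = recommender_config(),
                            query_id = NA_character_) {
  mode <- match.arg(mode)
  if (k < 1) {
    stop("k must be >= 1", call. = FALSE)
  }
  cand <- candidates
  agg <- ifelse(
    cand$origin == "direct",
    if (config$aggregation == "count") cand$n * cand$physician_score else cand$sim_sum,
    cand$sim_sum
  )
  if (mode == "PFB") {
    score <- cand$init_score
  } else if (mode == "PPH") {
    score <- agg
  } else {
    rate <- stats$response_rate[match(cand$physician_code, stats$physician_code)]
    if (anyNA(rate)) {
      message(
        "no stats for physician(s) ",
        paste(cand$physician_code[is.na(rate)], collapse = ", "),
        "; using response rate 0"
      )
      rate[is.na(rate)] <- 0
    }
    score <- rate^config$rate_exponent * agg
  }
  cand$score <- score
  ord <- order(-cand$score, -cand$physician_score, cand$physician_code)
  cand <- cand[ord, ]
  top <- utils::head(cand, k)
  structure(
    list(
      query_id = query_id,
      mode = mode,
      k = k,
      ranked = tibble::tibble(
        rank = seq_len(nrow(top)),
        physician_code = top$physician_code,
        score = top$score,
        physician_score = top$physician_score,
        origin = top$origin
      ),
      pool = cand
    ),
    class = "pphr_recommendation"
  )
}

#' @export
print.pphr_recommendation <- function(x, ...) {
  cat(sprintf(
    "<pphr_recommendation> query %s, mode %s, top-%d of %d candidates\n",
    x$query_id, x$mode, x$k, nrow(x$pool)
  ))
  print(x$ranked, n = min(nrow(x$ranked), 10))
  invisible(x)
}

#' Truncate a recommendation to a smaller K
#'
#' Used by K sweeps so every K shares one retrieval and scoring pass.
#'
#' @param rec A `pphr_recommendation`.
#' @param k New list length (<= current pool size).
#' @return A `pphr_recommendation` with the shorter list and the same pool.
#' @export
truncate_recommendation <- function(rec, k) {
  stopifnot(inherits(rec, "pphr_recommendation"), k >= 1)
  top <- utils::head(rec$pool, k)
  rec$k <- k
  rec$ranked <- tibble::tibble(
    rank = seq_len(nrow(top)),
    physician_code = top$physician_code,
    score = top$score,
    physician_score = top$physician_score,
    origin = top$origin
  )
  rec
}
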