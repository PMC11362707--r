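#' Hit ratio and mean rank per labeled physician
#'
#' A recommendation for a labeled test query is a *hit* when the physician
#' who tagged the question as within their expertise appears in the top-K
#' list. The hit ratio is hits / queries per labeled physician; the mean
#' rank is the average 1-based position of that physician over hit queries
#' only (rank is undefined for misses, so they are excluded).
#'
#' @param recs Named list of `pphr_recommendation`s, keyed (or labelled via
#'   `query_id`) by query id.
#' @param truth Named character vector: query id -> correct physician code.
#' @return Tibble: `physician_code`, `n_queries`, `hits`, `hit_ratio`,
#'   `mean_rank` (`NA` when there is no hit).
#' @export
hit_ratio_and_rank <- function(recs, truth) {
  ids <- names(recs) %||% vapply(recs, function(r) r$query_id, character(1))
  missing_truth <- setdiff(ids, names(truth))
  if (length(missing_truth)) {
    stop("no truth label for query ", missing_truth[1], call. = FALSE)
  }
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    code <- unname(truth[ids[i]])
    pos <- match(code, r$ranked$physician_code)
    tibble::tibble(physician_code = code, hit = !is.na(pos), rank = pos)
  })
  df <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$physician_code),
    n_queries = dplyr::n(),
    hits = sum(.data$hit),
    hit_ratio = mean(.data$hit),
    mean_rank = if (any(.data$hit)) mean(.data$rank[.data$hit]) else NA_real_,
    .groups = "drop"
  )
  out
}

#' Precision, recall and F1 under the physician-score relevance rule
#'
#' A recommended physician counts as a true positive when their (maximum)
#' `physician_score` for the query exceeds `threshold`; otherwise it is a
#' false positive. The relevant set for a query is every scored candidate
#' — before top-K truncation — whose `physician_score` exceeds the
#' threshold, so false negatives are relevant physicians the top-K list
#' left out. Counts are pooled over queries (micro-averaged):
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`. A
#' zero denominator yields 0 with a warning.
#'
#' @param recs List of `pphr_recommendation`s (each carries its full scored
#'   pool).
#' @param threshold Relevance gate on `physician_score`, default 0.7.
#' @return Tibble with one row: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
precision_recall_f1 <- function(recs, threshold = 0.7) {
  tp <- fp <- fn <- 0L
  for (r in recs) {
    rec_rel <- r$ranked$physician_score > threshold
    tp <- tp + sum(rec_rel)
    fp <- fp + sum(!rec_rel)
    relevant <- r$pool$physician_code[r$pool$physician_score > threshold]
    fn <- fn + length(setdiff(relevant, r$ranked$physician_code))
  }
  f1_score(tp, fp, fn)
}

#' Precision, recall and F1 from confusion counts
#'
#' @param tp,fp,fn True-positive, false-positive and false-negative counts
#'   (or already-computed precision and recall via `precision=` /
#'   `recall=`, in which case counts are ignored).
#' @param precision,recall Optional direct inputs; when both are given the
#'   F1 is their harmonic mean.
#' @return Tibble with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
f1_score <- function(tp = NA, fp = NA, fn = NA,
                     precision = NULL, recall = NULL) {
  if (is.null(precision)) {
    precision <- if (tp + fp > 0) {
      tp / (tp + fp)
    } else {
      warning("no recommended physicians; precision set to 0", call. = FALSE)
      0
    }
  }
  if (is.null(recall)) {
    recall <- if (tp + fn > 0) {
      tp / (tp + fn)
    } else {
      warning("no relevant physicians; recall set to 0", call. = FALSE)
      0
    }
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1
  )
}

#' High-quality-service proportion
#'
#' Over all recommended slots (pooled across queries), the fraction whose
#' physician's mean response time beats (is strictly below) the corpus
#' average response time. Physicians with no answered requests have no
#' mean response time and count as not-fast.
#'
#' @param recs List of `pphr_recommendation`s.
#' @param stats Physician stats tibble from [compute_physician_stats()].
#' @param global_mean_rt Corpus-level mean response time in minutes (see
#'   [global_mean_response_time()]).
#' @return Proportion in `[0, 1]`.
#' @export
hqos_prop <- function(recs, stats, global_mean_rt) {
  stopifnot(global_mean_rt > 0)
  codes <- unlist(
    lapply(recs, function(r) r$ranked$physician_code),
    use.names = FALSE
  )
  if (!length(codes)) {
    stop("no recommended physicians (N = 0)", call. = FALSE)
  }
  mrt <- stats$mean_response_time_min[match(codes, stats$physician_code)]
  fast <- !is.na(mrt) & mrt < global_mean_rt
  sum(fast) / length(codes)
}

#' Metric grid over K values and ablation modes
#'
#' For each mode, the engine scores every query once at the largest K (one
#' shared retrieval pool); each smaller K is a truncation of that ranking,
#' so curves across K are comparable. Per (mode, K) cell the grid reports
#' precision/recall/F1 under the relevance rule and the high-quality
#' service proportion; when `truth` labels are supplied, hit ratio and mean
#' rank (averaged over labeled physicians) are added.
#'
#' @param engine A `pphr_engine`.
#' @param queries Tibble with `question_id` and `question_text`.
#' @param truth Optional named character vector: query id -> correct
#'   physician code.
#' @param k_values Integer vector of list lengths (default `seq(2, 20, 2)`).
#' @param modes Character vector among `"PFB"`, `"PPH"`, `"PPHR"`.
#' @param threshold Relevance gate for precision/recall (default the
#'   engine's expansion threshold).
#' @return A `pphr_eval_report`: list with `per_k` (tibble: `mode`, `k`,
#'   `precision`, `recall`, `f1`, `hqos_prop`, and `hit_ratio`/`mean_rank`
#'   when truth is given), plus the `recommendations` at max K.
#' @export
k_sweep <- function(engine, queries, truth = NULL,
                    k_values = seq(2, 20, 2),
                    modes = c("PFB", "PPH", "PPHR"),
                    threshold = engine$config$threshold) {
  modes <- match.arg(modes, c("PFB", "PPH", "PPHR"), several.ok = TRUE)
  k_max <- max(k_values)
  base <- list()
  for (mode in modes) {
    base[[mode]] <- lapply(seq_len(nrow(queries)), function(i) {
      recommend(engine, queries$question_text[i],
        k = k_max, mode = mode,
        query_id = queries$question_id[i]
      )
    })
    names(base[[mode]]) <- queries$question_id
  }
  cells <- list()
  for (mode in modes) {
    for (k in k_values) {
      recs_k <- lapply(base[[mode]], truncate_recommendation, k = k)
      prf <- precision_recall_f1(recs_k, threshold)
      row <- tibble::tibble(
        mode = mode, k = k,
        precision = prf$precision, recall = prf$recall, f1 = prf$f1,
        hqos_prop = hqos_prop(recs_k, engine$stats, engine$global_mean_rt)
      )
      if (!is.null(truth)) {
        hr <- hit_ratio_and_rank(recs_k, truth)
        row$hit_ratio <- mean(hr$hit_ratio)
        row$mean_rank <- mean(hr$mean_rank, na.rm = TRUE)
      }
      cells[[length(cells) + 1]] <- row
    }
  }
  structure(
    list(per_k = dplyr::bind_rows(cells), recommendations = base),
    class = "pphr_eval_report"
  )
}

#' @export
print.pphr_eval_report <- function(x, ...) {
  cat("<pphr_eval_report>\n")
  print(x$per_k, n = nrow(x$per_k))
  invisible(x)
}

#' Write an evaluation report as CSV (grid) and JSON (aggregates)
#'
#' @param report A `pphr_eval_report`.
#' @param csv_path Path for the per-(mode, K) metric grid.
#' @param json_path Optional path for per-mode aggregate means/SDs.
#' @return `csv_path`, invisibly.
#' @export
write_eval_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report$per_k, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    metrics <- setdiff(names(report$per_k), c("mode", "k"))
    agg <- lapply(split(report$per_k, report$per_k$mode), function(d) {
      lapply(stats::setNames(metrics, metrics), function(m) {
        s <- aggregate_stats(d[[m]][!is.na(d[[m]])])
        list(mean = s$mean, sd = s$sd)
      })
    })
    jsonlite::write_json(agg, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Mean and sample standard deviation
#'
#' The "combined" rows of results tables: arithmetic mean and the
#' (n - 1)-denominator SD, at full precision (round only at presentation).
#'
#' @param values Numeric vector (>= 1 value; SD needs >= 2, else `NA`).
#' @return List with `mean`, `sd`, `n`.
#' @export
aggregate_stats <- function(values) {
  if (!length(values)) {
    stop("no values to aggregate", call. = FALSE)
  }
  list(
    mean = mean(values),
    sd = if (length(values) > 1) stats::sd(values) else NA_real_,
    n = length(values)
  )
}

#' Relative improvement of one metric over another
#'
#' @param a New value.
#' @param b Baseline value (non-zero).
#' @return `100 * (a - b) / b`, in percent.
#' @export
#' @examples
#' relative_improvement(0.886, 0.534) # about 65.92
relative_improvement <- function(a, b) {
  if (b == 0) {
    stop("baseline is zero; relative improvement undefined", call. = FALSE)
  }
  100 * (a - b) / b
}

#' Compare two rating samples (Mann-Whitney U)
#'
#' Summarises two Likert-scale rating vectors (e.g. physician ratings of
#' two recommender variants) and tests for a location difference with the
#' Mann-Whitney U (Wilcoxon rank-sum) test, exact where sample sizes
#' permit and tie-corrected otherwise.
#'
#' @param x,y Numeric rating vectors.
#' @return Tibble: `mean_x`, `sd_x`, `mean_y`, `sd_y`, `statistic` (U),
#'   `p_value`.
#' @export
compare_ratings <- function(x, y) {
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  tibble::tibble(
    mean_x = mean(x), sd_x = stats::sd(x),
    mean_y = mean(y), sd_y = stats::sd(y),
    statistic = unname(ht$statistic),
    p_value = ht$p.value
  )
}
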