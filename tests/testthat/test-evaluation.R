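# Minimal recommendation stub for metric tests.
stub_rec <- function(query_id, codes, scores, pool_codes = codes,
                     pool_scores = scores) {
  ranked <- tibble::tibble(
    rank = seq_along(codes), physician_code = codes,
    score = scores, physician_score = scores,
    origin = "direct"
  )
  pool <- tibble::tibble(
    physician_code = pool_codes, init_score = pool_scores,
    expand_score = 1, physician_score = pool_scores,
    n = 1L, sim_sum = pool_scores, origin = "direct",
    seed_code = NA_character_, score = pool_scores
  )
  structure(
    list(
      query_id = query_id, mode = "PPHR", k = length(codes),
      ranked = ranked, pool = pool
    ),
    class = "pphr_recommendation"
  )
}

test_that("hit ratio and mean rank follow the hit-only convention", {
  # physician X: 3 queries, hit at ranks 1 and 3, one miss
  recs <- list(
    a = stub_rec("a", c("X", "Y"), c(0.9, 0.8)),
    b = stub_rec("b", c("Y", "Z"), c(0.9, 0.8)),
    c = stub_rec("c", c("W", "Y", "X"), c(0.9, 0.8, 0.7)),
    d = stub_rec("d", c("Y", "Z"), c(0.9, 0.8))
  )
  truth <- c(a = "X", b = "X", c = "X", d = "Y")
  hr <- hit_ratio_and_rank(recs, truth)
  x <- hr[hr$physician_code == "X", ]
  expect_equal(x$n_queries, 3L)
  expect_equal(x$hit_ratio, 2 / 3)
  expect_equal(x$mean_rank, (1 + 3) / 2)
  y <- hr[hr$physician_code == "Y", ]
  expect_equal(y$hit_ratio, 1)
  expect_equal(y$mean_rank, 1)
  # all-miss physician: ratio 0, rank absent
  hr0 <- hit_ratio_and_rank(list(z = stub_rec("z", "Q", 0.5)), c(z = "X"))
  expect_equal(hr0$hit_ratio, 0)
  expect_true(is.na(hr0$mean_rank))
  expect_error(
    hit_ratio_and_rank(list(q = stub_rec("q", "A", 1)), c(other = "A")),
    "no truth label"
  )
})

test_that("precision/recall/F1 follow their confusion-count definitions", {
  expect_equal(
    f1_score(tp = 3, fp = 1, fn = 2)[, c("precision", "recall", "f1")],
    tibble::tibble(precision = 0.75, recall = 0.6, f1 = 2 * 0.45 / 1.35)
  )
  perfect <- f1_score(tp = 5, fp = 0, fn = 0)
  expect_equal(unlist(perfect[, c("precision", "recall", "f1")]),
    c(precision = 1, recall = 1, f1 = 1)
  )
  # harmonic mean from already-computed precision and recall
  f <- f1_score(precision = 0.7126, recall = 0.8202)
  expect_equal(round(f$f1, 4), 0.7626)
  expect_warning(f1_score(tp = 0, fp = 0, fn = 2), "precision set to 0")
})

test_that("relevance rule splits recommended and pool candidates at 0.7", {
  # pool has 4 relevant (>0.7); top-2 recommends one relevant, one not
  rec <- stub_rec(
    "q1", c("A", "E"), c(0.95, 0.5),
    pool_codes = c("A", "B", "C", "D", "E"),
    pool_scores = c(0.95, 0.9, 0.8, 0.75, 0.5)
  )
  out <- precision_recall_f1(list(rec), threshold = 0.7)
  expect_equal(out$tp, 1L)
  expect_equal(out$fp, 1L)
  expect_equal(out$fn, 3L) # B, C, D relevant but not recommended
  expect_equal(out$precision, 0.5)
  expect_equal(out$recall, 0.25)
})

test_that("hqos counts recommended slots faster than the corpus mean", {
  st <- tibble::tibble(
    physician_code = c("A", "B", "C", "D", "E"),
    mean_response_time_min = c(10, 50, 300, NA, 100)
  )
  recs <- list(stub_rec("q", c("A", "B", "C", "D", "E"), seq(0.9, 0.5, -0.1)))
  # threshold 120: A, B, E fast; C slow; D no responses -> not fast
  expect_equal(hqos_prop(recs, st, 120), 3 / 5)
  expect_equal(hqos_prop(recs, st, 5), 0)
  expect_equal(
    hqos_prop(list(stub_rec("q", c("A", "B"), c(0.9, 0.8))), st, 120), 1
  )
  expect_error(hqos_prop(list(), st, 120), "N = 0")
})

test_that("aggregate stats reproduce published combined rows", {
  s <- aggregate_stats(c(0.850, 0.915, 0.800, 0.940, 0.925))
  expect_equal(round(s$mean, 3), 0.886)
  expect_equal(round(s$sd, 3), 0.059)
  s2 <- aggregate_stats(c(0.485, 0.555, 0.430, 0.505, 0.695))
  expect_equal(round(s2$mean, 3), 0.534)
  expect_equal(round(s2$sd, 3), 0.101)
  expect_equal(aggregate_stats(rep(3, 4))$sd, 0)
  expect_true(is.na(aggregate_stats(1)$sd))
  # matches a high-precision two-pass oracle on random inputs
  for (trial in 1:10) {
    x <- withr::with_seed(trial, stats::runif(50))
    m <- sum(x) / length(x)
    sd_oracle <- sqrt(sum((x - m)^2) / (length(x) - 1))
    s3 <- aggregate_stats(x)
    expect_equal(s3$mean, m, tolerance = 1e-12)
    expect_equal(s3$sd, sd_oracle, tolerance = 1e-12)
  }
})

test_that("relative improvement is a percentage of the baseline", {
  expect_equal(round(relative_improvement(0.886, 0.534), 2), 65.92)
  expect_equal(round(relative_improvement(0.886, 0.867), 2), 2.19)
  expect_equal(relative_improvement(0.4, 0.4), 0)
  expect_error(relative_improvement(1, 0), "zero")
})

test_that("rating comparison reports group summaries and a rank-sum test", {
  x <- c(5, 4, 4, 5, 3, 4, 5, 4)
  y <- c(3, 3, 2, 4, 3, 2, 3, 3)
  out <- compare_ratings(x, y)
  expect_equal(out$mean_x, mean(x))
  expect_equal(out$sd_y, stats::sd(y))
  ref <- suppressWarnings(stats::wilcox.test(x, y))
  expect_equal(out$p_value, ref$p.value)
  expect_lt(out$p_value, 0.05)
})

test_that("the K sweep shares one retrieval pool per mode", {
  fix <- small_engine(seed = 8, n_questions = 250, n_physicians = 10)
  queries <- tibble::tibble(
    question_id = paste0("query", 1:6),
    question_text = vapply(
      1:6, function(i) topic_query(paste0("topic", (i %% 5) + 1), seed = i),
      character(1)
    )
  )
  truth <- stats::setNames(
    vapply(1:6, function(i) {
      topic <- paste0("topic", (i %% 5) + 1)
      specialists <- fix$corpus$truth$physicians$physician_code[vapply(
        fix$corpus$truth$physicians$topics,
        function(ts) topic %in% ts, logical(1)
      )]
      specialists[1]
    }, character(1)),
    queries$question_id
  )
  rep1 <- k_sweep(fix$engine, queries,
    truth = truth, k_values = c(2, 4, 6),
    modes = c("PFB", "PPHR")
  )
  grid <- rep1$per_k
  expect_equal(nrow(grid), 6)
  expect_true(all(grid$precision >= 0 & grid$precision <= 1))
  expect_true(all(grid$recall >= 0 & grid$recall <= 1))
  expect_true(all(grid$hqos_prop >= 0 & grid$hqos_prop <= 1))
  # f1 between min and max of precision/recall when positive
  pos <- grid$precision > 0 & grid$recall > 0
  expect_true(all(
    grid$f1[pos] <= pmax(grid$precision[pos], grid$recall[pos]) + 1e-12
  ))
  expect_true(all(
    grid$f1[pos] >= pmin(grid$precision[pos], grid$recall[pos]) - 1e-12
  ))
  # recall and hit ratio are non-decreasing in K for a fixed ranking
  for (m in unique(grid$mode)) {
    g <- grid[grid$mode == m, ]
    g <- g[order(g$k), ]
    expect_true(all(diff(g$recall) >= -1e-12))
    expect_true(all(diff(g$hit_ratio) >= -1e-12))
  }
  # determinism across repeated sweeps
  rep2 <- k_sweep(fix$engine, queries,
    truth = truth, k_values = c(2, 4, 6),
    modes = c("PFB", "PPHR")
  )
  expect_identical(rep1$per_k, rep2$per_k)
  # K beyond the candidate pool computes on the full ranking
  rep3 <- k_sweep(fix$engine, queries[1, ],
    k_values = c(500), modes = "PFB"
  )
  expect_equal(nrow(rep3$per_k), 1)
})

test_that("evaluation reports export as CSV plus JSON aggregates", {
  fix <- small_engine(seed = 12, n_questions = 150, n_physicians = 8)
  queries <- tibble::tibble(
    question_id = "q1", question_text = topic_query("topic1")
  )
  rep <- k_sweep(fix$engine, queries, k_values = c(2, 4), modes = "PPHR")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 2)
  agg <- jsonlite::fromJSON(js)
  expect_true("PPHR" %in% names(agg))
  expect_equal(agg$PPHR$f1$mean, mean(rep$per_k$f1))
})
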