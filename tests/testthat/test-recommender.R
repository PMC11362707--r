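# The worked retrieval example: ten historical questions with known
# cosine similarities to the query, one physician each.
worked_pool <- function() {
  list(
    cosines = c(
      0.9766, 0.9765, 0.9618, 0.9419, 0.9214,
      0.9004, 0.8990, 0.8976, 0.8906, 0.8861
    ),
    qids = c(
      "394946", "559249", "317643", "409326", "238700",
      "2416", "173519", "551580", "466072", "93556"
    ),
    phys = c(
      "178", "423", "141", "164", "456",
      "707", "304", "330", "632", "391"
    )
  )
}

test_that("direct candidates carry their best similarity as init_score", {
  wp <- worked_pool()
  idx <- index_with_cosines(wp$cosines, wp$qids)
  q2p <- stats::setNames(wp$phys, wp$qids)
  cand <- generate_candidates(unit_query(idx$dim), idx, q2p,
    top_m = 10, top_k = 10
  )
  expect_equal(nrow(cand), 10)
  expect_equal(
    cand$init_score[cand$physician_code == "141"], 0.9618,
    tolerance = 1e-9
  )
  expect_equal(
    cand$init_score[cand$physician_code == "423"], 0.9765,
    tolerance = 1e-9
  )
  expect_true(all(cand$expand_score == 1))
  expect_identical(cand$physician_score, cand$init_score)
  expect_true(all(cand$n == 1))
})

test_that("a physician's matches aggregate as max similarity and count", {
  idx <- index_with_cosines(c(0.9, 0.8, 0.75, 0.5), paste0("q", 1:4))
  q2p <- c(q1 = "X", q2 = "X", q3 = "X", q4 = "Y")
  cand <- generate_candidates(unit_query(5), idx, q2p, top_m = 4, top_k = 4)
  x <- cand[cand$physician_code == "X", ]
  expect_equal(x$n, 3L)
  expect_equal(x$init_score, 0.9, tolerance = 1e-9)
  expect_equal(x$sim_sum, 0.9 + 0.8 + 0.75, tolerance = 1e-9)
  # single indexed question degenerate case
  idx1 <- index_with_cosines(0.42, "only")
  c1 <- generate_candidates(unit_query(2), idx1, c(only = "Z"),
    top_m = 1, top_k = 1
  )
  expect_equal(c1$n, 1L)
  expect_equal(c1$init_score, 0.42, tolerance = 1e-9)
})

test_that("expansion multiplies init by profile similarity and gates at 0.7", {
  direct <- tibble::tibble(
    physician_code = "141", init_score = 0.9618, expand_score = 1,
    physician_score = 0.9618, n = 1L, sim_sum = 0.9618,
    origin = "direct", seed_code = NA_character_
  )
  sim <- matrix(
    c(
      1, 0.9335, 0.6,
      0.9335, 1, 0.2,
      0.6, 0.2, 1
    ),
    nrow = 3, dimnames = list(c("141", "166", "999"), c("141", "166", "999"))
  )
  out <- expand_candidates(direct, sim, threshold = 0.7)
  e <- out[out$origin == "expanded", ]
  expect_equal(e$physician_code, "166")
  expect_equal(e$physician_score, 0.9618 * 0.9335) # 0.8978
  expect_equal(round(e$physician_score, 4), 0.8978)
  # 999: product 0.9618 * 0.6 = 0.577 < 0.7, not added
  expect_false("999" %in% out$physician_code)
  # sim = 1 propagates the seed's init_score exactly
  sim2 <- sim
  sim2["141", "166"] <- sim2["166", "141"] <- 1
  out2 <- expand_candidates(direct, sim2)
  expect_identical(
    out2$physician_score[out2$physician_code == "166"], 0.9618
  )
  # direct candidates pass through untouched
  expect_identical(out[out$origin == "direct", ], direct)
})

test_that("expansion matches the brute-force oracle with exact products", {
  for (trial in 1:20) {
    n_phys <- 8
    codes <- sprintf("P%02d", 1:n_phys)
    sim <- withr::with_seed(trial, {
      m <- matrix(stats::runif(n_phys^2, 0, 1), n_phys)
      m <- (m + t(m)) / 2
      diag(m) <- 1
      dimnames(m) <- list(codes, codes)
      m
    })
    n_direct <- withr::with_seed(100 + trial, sample(1:4, 1))
    init <- withr::with_seed(200 + trial, stats::runif(n_direct, 0.6, 1))
    direct <- tibble::tibble(
      physician_code = codes[seq_len(n_direct)],
      init_score = init, expand_score = 1, physician_score = init,
      n = 1L, sim_sum = init, origin = "direct",
      seed_code = NA_character_
    )
    got <- expand_candidates(direct, sim, threshold = 0.7)
    got_e <- got[got$origin == "expanded", ]
    got_e <- got_e[order(got_e$physician_code), ]
    want <- oracle_expand(direct, sim, threshold = 0.7)
    expect_equal(got_e$physician_code, want$physician_code)
    expect_equal(got_e$physician_score, want$physician_score,
      tolerance = 1e-15
    )
    expect_equal(got_e$n, want$n)
    # bit-exact product identity on every emitted candidate
    expect_identical(got$physician_score, got$init_score * got$expand_score)
    # the gate is strict
    expect_true(all(got_e$physician_score > 0.7))
    # expansion never removes or rescores a direct candidate
    expect_identical(got[got$origin == "direct", ], direct)
  }
})

test_that("ranking weights aggregate similarity by the response rate", {
  # one direct candidate with 10 equal matches at 0.9618 and rate 0.747
  cand <- tibble::tibble(
    physician_code = c("141", "slow"),
    init_score = c(0.9618, 0.9),
    expand_score = 1,
    physician_score = c(0.9618, 0.9),
    n = c(10L, 1L),
    sim_sum = c(9.618, 0.9),
    origin = "direct",
    seed_code = NA_character_
  )
  stats_tb <- tibble::tibble(
    physician_code = c("141", "slow"),
    response_rate = c(0.747, 0)
  )
  rec <- rank_candidates(cand, stats_tb, k = 2, mode = "PPHR")
  expect_equal(
    rec$ranked$score[rec$ranked$physician_code == "141"],
    0.747 * 10 * 0.9618 # 7.1846
  )
  # zero response rate zeroes the final score and sinks the candidate
  expect_equal(rec$ranked$score[rec$ranked$physician_code == "slow"], 0)
  expect_equal(rec$ranked$physician_code[1], "141")
  # equal aggregate similarity: the higher rate wins
  cand2 <- cand
  cand2$n <- c(1L, 1L)
  cand2$sim_sum <- cand2$physician_score
  cand2$physician_score <- c(0.9, 0.9)
  cand2$init_score <- c(0.9, 0.9)
  st2 <- tibble::tibble(
    physician_code = c("141", "slow"), response_rate = c(0.3, 0.9)
  )
  rec2 <- rank_candidates(cand2, st2, k = 2, mode = "PPHR")
  expect_equal(rec2$ranked$physician_code[1], "slow")
  expect_error(rank_candidates(cand, stats_tb, k = 0), "k must be")
})

test_that("missing stats score as rate zero with a message", {
  cand <- tibble::tibble(
    physician_code = "ghost", init_score = 0.9, expand_score = 1,
    physician_score = 0.9, n = 1L, sim_sum = 0.9, origin = "direct",
    seed_code = NA_character_
  )
  st <- tibble::tibble(physician_code = "other", response_rate = 0.5)
  expect_message(
    rec <- rank_candidates(cand, st, k = 1, mode = "PPHR"),
    "ghost"
  )
  expect_equal(rec$ranked$score, 0)
})

test_that("ablation modes share retrieval and differ only as designed", {
  # one question per physician, identity profile similarity, equal rates:
  # PFB and PPHR must produce identical rankings
  wp <- worked_pool()
  idx <- index_with_cosines(wp$cosines, wp$qids)
  q2p <- stats::setNames(wp$phys, wp$qids)
  sim <- diag(10)
  dimnames(sim) <- list(wp$phys, wp$phys)
  st <- tibble::tibble(physician_code = wp$phys, response_rate = 0.8)
  direct <- generate_candidates(unit_query(idx$dim), idx, q2p, 10, 10)
  pfb <- rank_candidates(direct, st, k = 5, mode = "PFB")
  pphr <- rank_candidates(
    expand_candidates(direct, sim), st,
    k = 5, mode = "PPHR"
  )
  expect_identical(pfb$ranked$physician_code, pphr$ranked$physician_code)

  # ranking is invariant under strictly increasing transforms of the score
  cfg <- recommender_config(aggregation = "sum_sim")
  pph <- rank_candidates(expand_candidates(direct, sim), st,
    k = 5, mode = "PPH", config = cfg
  )
  cand_t <- expand_candidates(direct, sim)
  cand_t$sim_sum <- cand_t$sim_sum * 3 + 1 # increasing transform of scores
  pph_t <- rank_candidates(cand_t, st, k = 5, mode = "PPH", config = cfg)
  expect_identical(pph$ranked$physician_code, pph_t$ranked$physician_code)
})

test_that("end-to-end recommendation finds specialists and is deterministic", {
  fix <- small_engine(seed = 21, n_questions = 400, n_physicians = 15)
  eng <- fix$engine
  truth <- fix$corpus$truth
  hits <- 0
  n_q <- 20
  for (i in seq_len(n_q)) {
    topic <- truth$physicians$topics[[(i %% 15) + 1]][1]
    q <- topic_query(topic, seed = i)
    rec <- recommend(eng, q, k = 5, mode = "PPHR")
    specialists <- truth$physicians$physician_code[vapply(
      truth$physicians$topics, function(ts) topic %in% ts, logical(1)
    )]
    if (any(rec$ranked$physician_code %in% specialists)) hits <- hits + 1
  }
  expect_gt(hits / n_q, 0.9)
  # determinism: identical engine + query -> identical recommendation
  r1 <- recommend(eng, topic_query("topic1"), k = 8)
  r2 <- recommend(eng, topic_query("topic1"), k = 8)
  expect_identical(r1$ranked, r2$ranked)
  # raising a physician's response rate never lowers their rank
  r_before <- recommend(eng, topic_query("topic2"), k = 14)
  eng2 <- eng
  code <- r_before$ranked$physician_code[5]
  i <- match(code, eng2$stats$physician_code)
  eng2$stats$response_rate[i] <- min(1, eng2$stats$response_rate[i] * 1.5)
  r_after <- recommend(eng2, topic_query("topic2"), k = 14)
  expect_lte(
    match(code, r_after$ranked$physician_code),
    match(code, r_before$ranked$physician_code)
  )
})

test_that("recommendations truncate consistently for K sweeps", {
  fix <- small_engine(seed = 4, n_questions = 200, n_physicians = 10)
  full <- recommend(fix$engine, topic_query("topic3"), k = 10)
  short <- truncate_recommendation(full, 4)
  expect_equal(nrow(short$ranked), 4)
  expect_identical(short$ranked, full$ranked[1:4, ])
  expect_identical(short$pool, full$pool)
})
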