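#' Configuration for the synthetic consultation-corpus generator
#'
#' The generator emulates the structure of a web-based consultation corpus
#' with known ground truth: question texts cluster into topics (one topic
#' vocabulary per medical specialty, plus a shared everyday vocabulary),
#' each physician specialises in 1-2 topics, response status is Bernoulli
#' with a per-physician rate, and response times are right-skewed
#' (lognormal).
#'
#' Defaults emulate the corpus the recommender targets: 5 topics (as many
#' as the evaluation's labeled departments), a per-physician response-rate
#' range of (0.4, 0.9) whose midpoint gives a pooled rate near 65%, and
#' lognormal response times with meanlog `log(80)` and sdlog 1.1, whose
#' 5th/95th percentiles (about 13 and 490 minutes) bracket typical
#' winsorization bounds of such corpora.
#'
#' @param n_topics Number of topics (default 5).
#' @param vocab_per_topic Topic-specific vocabulary size (default 40).
#' @param shared_vocab Shared vocabulary size (default 30).
#' @param n_physicians Number of physicians (default 25).
#' @param topics_per_physician 1 or 2 topics per physician; each physician
#'   draws uniformly from this vector (default `c(1, 2)`).
#' @param n_questions Number of consultation records (default 2000).
#' @param tokens_per_question Range `c(min, max)` of tokens per question
#'   (default `c(6, 14)`).
#' @param noise_rate Fraction of tokens drawn off-topic (from the shared or
#'   other-topic vocabulary) instead of from the physician's topic
#'   vocabulary; in `[0, 1)` (default 0.05).
#' @param response_rate_range Per-physician response rates are drawn
#'   uniformly from this interval (default `c(0.4, 0.9)`).
#' @param response_time_meanlog,response_time_sdlog Lognormal parameters of
#'   response times in log-minutes (defaults `log(80)` and 1.1).
#' @param rate_time_link Slope tying a physician's response-time location
#'   to their response rate: physician `i` draws times with meanlog
#'   `response_time_meanlog + rate_time_link * (true_rate_i - mid_rate)`.
#'   The default -2 makes high-rate physicians respond faster, emulating
#'   the empirical correlation between willingness to answer and speed of
#'   answering on consultation platforms; set 0 for independence.
#' @param seed Integer seed; the whole corpus is reproducible from it
#'   (default 2023).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_topics = 5, vocab_per_topic = 40,
                             shared_vocab = 30, n_physicians = 25,
                             topics_per_physician = c(1, 2),
                             n_questions = 2000,
                             tokens_per_question = c(6, 14),
                             noise_rate = 0.05,
                             response_rate_range = c(0.4, 0.9),
                             response_time_meanlog = log(80),
                             response_time_sdlog = 1.1,
                             rate_time_link = -2,
                             seed = 2023) {
  cfg <- list(
    n_topics = n_topics, vocab_per_topic = vocab_per_topic,
    shared_vocab = shared_vocab, n_physicians = n_physicians,
    topics_per_physician = topics_per_physician,
    n_questions = n_questions,
    tokens_per_question = tokens_per_question,
    noise_rate = noise_rate,
    response_rate_range = response_rate_range,
    response_time_meanlog = response_time_meanlog,
    response_time_sdlog = response_time_sdlog,
    rate_time_link = rate_time_link,
    seed = seed
  )
  stopifnot(
    n_topics >= 1, vocab_per_topic >= 1, shared_vocab >= 0,
    n_physicians >= 1, n_questions >= 1,
    all(topics_per_physician %in% 1:2),
    noise_rate >= 0, noise_rate < 1,
    response_rate_range[1] <= response_rate_range[2],
    response_rate_range[1] >= 0, response_rate_range[2] <= 1
  )
  if (max(topics_per_physician) > n_topics) {
    stop("topics_per_physician exceeds n_topics", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic consultation corpus with ground truth
#'
#' Each physician draws its topic set, then each question draws a
#' physician (uniformly), one of that physician's topics, and its tokens:
#' with probability `1 - noise_rate` from the topic vocabulary, otherwise
#' from the shared and other-topic vocabulary. Response status is
#' Bernoulli with the physician's true rate; answered records get a
#' lognormal response time. Fully reproducible from the config seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (a validated record tibble) and `truth`, a
#'   list of `questions` (tibble: `question_id`, `topic`,
#'   `physician_code`), `physicians` (tibble: `physician_code`, `topics`
#'   list-column, `true_rate`) and the `config`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    topics <- paste0("topic", seq_len(config$n_topics))
    vocab <- lapply(stats::setNames(topics, topics), function(t) {
      sprintf("%s_w%02d", t, seq_len(config$vocab_per_topic))
    })
    shared <- if (config$shared_vocab > 0) {
      sprintf("common_w%02d", seq_len(config$shared_vocab))
    } else {
      character()
    }

    phys_codes <- sprintf("dr%03d", seq_len(config$n_physicians))
    phys_topics <- lapply(seq_len(config$n_physicians), function(i) {
      n_t <- if (length(config$topics_per_physician) == 1) {
        config$topics_per_physician
      } else {
        sample(config$topics_per_physician, 1)
      }
      sample(topics, n_t)
    })
    true_rate <- stats::runif(
      config$n_physicians,
      config$response_rate_range[1], config$response_rate_range[2]
    )

    n <- config$n_questions
    phys_idx <- sample.int(config$n_physicians, n, replace = TRUE)
    q_topic <- vapply(phys_idx, function(i) {
      ts <- phys_topics[[i]]
      if (length(ts) == 1) ts else sample(ts, 1)
    }, character(1))
    len <- sample(
      config$tokens_per_question[1]:config$tokens_per_question[2],
      n,
      replace = TRUE
    )
    off_vocab <- function(topic) c(shared, unlist(vocab[setdiff(topics, topic)]))
    texts <- vapply(seq_len(n), function(i) {
      on_topic <- stats::runif(len[i]) >= config$noise_rate
      pool_on <- vocab[[q_topic[i]]]
      toks <- character(len[i])
      toks[on_topic] <- sample(pool_on, sum(on_topic), replace = TRUE)
      if (any(!on_topic)) {
        pool_off <- off_vocab(q_topic[i])
        if (!length(pool_off)) pool_off <- pool_on
        toks[!on_topic] <- sample(pool_off, sum(!on_topic), replace = TRUE)
      }
      paste(toks, collapse = " ")
    }, character(1))

    responded <- stats::runif(n) < true_rate[phys_idx]
    mid_rate <- mean(config$response_rate_range)
    meanlog_i <- config$response_time_meanlog +
      config$rate_time_link * (true_rate - mid_rate)
    rt <- rep(NA_real_, n)
    rt[responded] <- round(stats::rlnorm(
      sum(responded),
      meanlog_i[phys_idx[responded]], config$response_time_sdlog
    ), 1)

    records <- as_records(
      tibble::tibble(
        question_id = sprintf("q%06d", seq_len(n)),
        patient_code = sprintf("p%05d", sample.int(max(n %/% 2, 1), n, replace = TRUE)),
        physician_code = phys_codes[phys_idx],
        department = paste0("dept_", vapply(
          phys_idx, function(i) phys_topics[[i]][1], character(1)
        )),
        question_text = texts,
        response_status = responded,
        response_time_min = rt,
        created_hour = sample(0:23, n, replace = TRUE),
        patient_sex = sample(c("Male", "Female"), n,
          replace = TRUE, prob = c(0.33, 0.67)
        ),
        patient_age = pmax(0, round(stats::rnorm(n, 35, 15))),
        physician_title = NA_character_
      ),
      source = "synthetic"
    )

    truth <- list(
      questions = tibble::tibble(
        question_id = records$question_id,
        topic = q_topic,
        physician_code = records$physician_code
      ),
      physicians = tibble::tibble(
        physician_code = phys_codes,
        topics = phys_topics,
        true_rate = true_rate
      ),
      config = config
    )
    list(records = records, truth = truth)
  })
}

#' Ground-truth relevant physicians for a synthetic query
#'
#' The oracle relevant set: all physicians sharing at least one topic with
#' the query's topic. With a single-topic configuration this degenerates to
#' every physician (flagged with a warning).
#'
#' @param truth Ground-truth list from [generate_corpus()].
#' @param query_id A question id present in the truth tables.
#' @return Character vector of physician codes.
#' @export
ground_truth_relevance <- function(truth, query_id) {
  i <- match(query_id, truth$questions$question_id)
  if (is.na(i)) {
    stop("unknown query: ", query_id, call. = FALSE)
  }
  topic <- truth$questions$topic[i]
  if (truth$config$n_topics == 1) {
    warning("single-topic configuration: every physician is relevant",
      call. = FALSE
    )
  }
  keep <- vapply(
    truth$physicians$topics, function(ts) topic %in% ts, logical(1)
  )
  truth$physicians$physician_code[keep]
}

#' Write a synthetic corpus and its ground truth to a directory
#'
#' @param corpus List from [generate_corpus()].
#' @param dir Output directory; writes `records.jsonl`,
#'   `truth_questions.jsonl`, `truth_physicians.jsonl` and `config.yaml`.
#' @return `dir`, invisibly.
#' @export
write_synthetic_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_records(corpus$records, file.path(dir, "records.jsonl"),
    format = "jsonl"
  )
  con <- file(file.path(dir, "truth_questions.jsonl"), "w", encoding = "UTF-8")
  q <- corpus$truth$questions
  for (i in seq_len(nrow(q))) {
    writeLines(jsonlite::toJSON(as.list(q[i, ]), auto_unbox = TRUE), con)
  }
  close(con)
  con <- file(file.path(dir, "truth_physicians.jsonl"), "w", encoding = "UTF-8")
  p <- corpus$truth$physicians
  for (i in seq_len(nrow(p))) {
    writeLines(jsonlite::toJSON(
      list(
        physician_code = p$physician_code[i],
        topics = p$topics[[i]],
        true_rate = p$true_rate[i]
      ),
      auto_unbox = TRUE, digits = NA
    ), con)
  }
  close(con)
  cfg <- unclass(corpus$truth$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
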