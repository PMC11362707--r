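# Shared fixture builders; everything is generated in code at test time.

# A minimal hand-written corpus: 3 physicians, 6 questions, mixed response
# outcomes. Question texts are small bags of words with clear topics.
tiny_records <- function() {
  as_records(tibble::tibble(
    question_id = paste0("q", 1:6),
    patient_code = paste0("p", c(1, 2, 3, 1, 2, 3)),
    physician_code = c("A", "A", "B", "B", "C", "C"),
    department = c(
      "cardio", "cardio", "derma", "derma", "pedia", "pedia"
    ),
    question_text = c(
      "chest pain and palpitations",
      "heart rhythm feels irregular",
      "itchy red rash on the arm",
      "red skin rash spreading",
      "child fever and cough",
      "toddler cough at night"
    ),
    response_status = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    response_time_min = c(10, 20, 30, NA, 40, NA),
    created_hour = c(9, 13, 20, 2, 7, 23),
    patient_sex = c("Female", "Female", "Male", "Female", "Male", "Female"),
    patient_age = c(34, 55, 23, 41, 4, 3),
    physician_title = c(
      "Senior", "Senior", "Junior", "Junior", "Senior", "Senior"
    )
  ))
}

# Write a CSV version of a record tibble to a temp file.
write_tmp_csv <- function(records, ...) {
  path <- withr::local_tempfile(fileext = ".csv", ...)
  write_records(records, path, format = "csv")
  path
}

# An embedding index with prescribed cosine similarities to the unit query
# e1. Vector i is c * e1 + sqrt(1 - c^2) * e_(i+1), so all cross terms live
# in distinct orthogonal directions.
index_with_cosines <- function(cosines, ids) {
  d <- length(cosines) + 1
  m <- t(vapply(seq_along(cosines), function(i) {
    v <- numeric(d)
    v[1] <- cosines[i]
    v[i + 1] <- sqrt(1 - cosines[i]^2)
    v
  }, numeric(d)))
  rownames(m) <- ids
  structure(
    list(ids = ids, vectors = m, dim = d, backend_tag = "fixture"),
    class = "embedding_matrix"
  )
}

unit_query <- function(dim) {
  q <- numeric(dim)
  q[1] <- 1
  q
}

# Brute-force expansion oracle: enumerate every (seed, other) pair, apply
# the gate to the product, dedup by maximal product. Independent of the
# implementation's grouping strategy.
oracle_expand <- function(direct, similarity, threshold = 0.7) {
  rows <- list()
  for (i in seq_len(nrow(direct))) {
    seed <- direct$physician_code[i]
    for (j in rownames(similarity)) {
      if (j %in% direct$physician_code) next
      p <- direct$init_score[i] * similarity[seed, j]
      if (p > threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          physician_code = j, physician_score = p,
          seed_code = seed, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(
      physician_code = character(), physician_score = numeric(),
      n = integer()
    ))
  }
  df <- do.call(rbind, rows)
  best <- stats::aggregate(physician_score ~ physician_code, df, max)
  best$n <- as.integer(table(df$physician_code)[best$physician_code])
  best[order(best$physician_code), ]
}

# Small engine over a synthetic corpus, shared by recommender/evaluation
# tests.
small_engine <- function(seed = 11, n_questions = 300, n_physicians = 12,
                         ...) {
  corpus <- generate_corpus(synthetic_config(
    n_questions = n_questions, n_physicians = n_physicians, seed = seed, ...
  ))
  list(
    corpus = corpus,
    engine = build_engine(corpus$records)
  )
}

# Topic-pure query text for a synthetic corpus topic.
topic_query <- function(topic, n_tokens = 8, seed = 1) {
  withr::with_seed(seed, paste(
    sprintf("%s_w%02d", topic, sample(1:20, n_tokens, replace = TRUE)),
    collapse = " "
  ))
}
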