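# Independent naive re-implementations used as oracles. These deliberately
# avoid the package's vectorised code paths: per-pair scalar arithmetic,
# explicit loops, data-frame sorts.

oracle_rmsd <- function(a, b) sqrt(sum((a - b)^2) / length(a))

# ordered most-similar-first list per query, ties by id (byte order)
oracle_rankings <- function(scores) {
  ids <- rownames(scores)
  out <- list()
  for (q in ids) {
    others <- setdiff(ids, q)
    df <- data.frame(
      other = others,
      rmsd = vapply(others, function(o) oracle_rmsd(scores[q, ], scores[o, ]),
                    numeric(1)),
      stringsAsFactors = FALSE
    )
    df <- df[order(df$rmsd, df$other, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    out[[q]] <- df
  }
  out
}

oracle_rank_of <- function(rankings, query, other) {
  match(other, rankings[[query]]$other)
}

# per-indication leave-one-out (c, d, accuracy) at cutoff k
oracle_indication_accuracy <- function(rankings, drugs, k) {
  drugs <- unique(drugs)
  d <- length(drugs)
  cc <- 0L
  for (g in drugs) {
    co_ranks <- vapply(setdiff(drugs, g), function(o) {
      oracle_rank_of(rankings, g, o)
    }, numeric(1))
    if (min(co_ranks) <= k) cc <- cc + 1L
  }
  list(c = cc, d = d, accuracy = cc / d * 100)
}

# full benchmark: per-indication records and the three aggregates per cutoff
oracle_benchmark <- function(scores, mapping_df, ks) {
  rankings <- oracle_rankings(scores)
  inds <- sort(unique(mapping_df$indication_id))
  records <- list()
  for (ind in inds) {
    drugs <- unique(mapping_df$compound_id[mapping_df$indication_id == ind])
    for (k in ks) {
      r <- oracle_indication_accuracy(rankings, drugs, k)
      records[[length(records) + 1L]] <- data.frame(
        indication_id = ind, d = r$d, cutoff = k, c = r$c,
        accuracy = r$accuracy, stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, records)
  aggregates <- do.call(rbind, lapply(ks, function(k) {
    rec <- records[records$cutoff == k, , drop = FALSE]
    data.frame(
      cutoff = k,
      average_indication_accuracy = sum(rec$accuracy) / nrow(rec),
      pairwise_accuracy = sum(rec$accuracy * rec$d) / sum(rec$d),
      coverage_count = sum(rec$accuracy > 0),
      coverage_percent = sum(rec$accuracy > 0) / nrow(rec) * 100
    )
  }))
  list(rankings = rankings, records = records, aggregates = aggregates)
}

# random small instance; discrete score levels induce genuine RMSD ties
random_instance <- function(seed, max_n = 12, max_p = 5, discrete = TRUE) {
  withr::with_seed(seed, {
    n <- sample(4:max_n, 1)
    p <- sample(1:max_p, 1)
    vals <- if (discrete) sample(0:3, n * p, replace = TRUE) else rnorm(n * p)
    scores <- matrix(as.numeric(vals), n, p,
                     dimnames = list(sprintf("D%02d", 1:n), sprintf("P%d", 1:p)))
    n_ind <- sample(1:3, 1)
    rows <- list()
    for (i in seq_len(n_ind)) {
      size <- sample(2:min(4, n), 1)
      rows[[i]] <- data.frame(
        indication_id = sprintf("I%d", i),
        compound_id = sample(rownames(scores), size),
        stringsAsFactors = FALSE
      )
    }
    list(scores = scores, mapping = do.call(rbind, rows))
  })
}

# build a similarity_ranking with explicitly chosen ordered lists, for the
# toy cases where the ordered lists themselves are the fixture
make_ranking_table <- function(lists) {
  ids <- names(lists)
  n <- length(ids)
  rank_index <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  rows <- list()
  for (q in ids) {
    stopifnot(setequal(lists[[q]], setdiff(ids, q)))
    rank_index[q, lists[[q]]] <- seq_len(n - 1L)
    rows[[q]] <- tibble::tibble(
      query_id = q, rank = seq_len(n - 1L), other_id = lists[[q]],
      rmsd = as.numeric(seq_len(n - 1L))
    )
  }
  structure(
    list(
      compound_ids = ids,
      ranking = dplyr::bind_rows(rows),
      rank_index = rank_index,
      rmsd = NULL
    ),
    class = "similarity_ranking"
  )
}

# uniformly random ranking table over n compounds (true permutations)
random_ranking_table <- function(n) {
  ids <- sprintf("D%02d", seq_len(n))
  lists <- lapply(ids, function(q) sample(setdiff(ids, q)))
  names(lists) <- ids
  make_ranking_table(lists)
}

toy_mapping <- function(...) {
  sets <- list(...)
  dplyr::bind_rows(lapply(seq_along(sets), function(i) {
    tibble::tibble(indication_id = sprintf("I%d", i), compound_id = sets[[i]])
  }))
}
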