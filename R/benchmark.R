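#' Leave-one-out recovery accuracy for one indication
#'
#' For every approved drug `g` of an indication, hold `g` out and ask
#' whether at least one co-approved drug appears within the top `k` of
#' `g`'s similarity list. With `c` the number of held-out drugs recovering
#' a co-drug and `d` the indication's approved-drug count, the indication
#' accuracy is `c / d * 100`.
#'
#' @param table A `similarity_ranking`.
#' @param drugs Character vector (>= 2) of approved compound ids.
#' @param k Rank cutoff, `1 <= k <= N - 1`.
#' @return A one-row tibble with columns `c`, `d`, `accuracy`.
#' @examples
#' m <- interaction_matrix(matrix(c(0, 0.1, 9, 0, 0, 9), 3, 2,
#'   dimnames = list(c("A", "B", "C"), c("P1", "P2"))))
#' indication_accuracy(compute_rankings(m), c("A", "B"), k = 1)
#' @export
indication_accuracy <- function(table, drugs, k) {
  stopifnot(inherits(table, "similarity_ranking"))
  drugs <- unique(as.character(drugs))
  if (length(drugs) < 2) abort("an indication needs >= 2 drugs for leave-one-out")
  unknown <- setdiff(drugs, table$compound_ids)
  if (length(unknown) > 0) {
    abort(paste0("unknown drug(s): ", paste(unknown, collapse = ", ")))
  }
  n <- length(table$compound_ids)
  if (k < 1 || k > n - 1) abort(paste0("cutoff k must lie in [1, ", n - 1, "]"))
  best <- best_corank(table, drugs)
  cc <- sum(best <= k)
  tibble(c = cc, d = length(drugs), accuracy = cc / length(drugs) * 100)
}

# min rank, per held-out drug, at which any co-approved drug appears
best_corank <- function(table, drugs) {
  sub <- table$rank_index[drugs, drugs, drop = FALSE]
  diag(sub) <- NA_integer_
  apply(sub, 1L, min, na.rm = TRUE)
}

#' Benchmark a pipeline by leave-one-out indication recovery
#'
#' Runs `indication_accuracy()` for every benchmarkable indication at every
#' resolved cutoff and aggregates three pipeline-level metrics per cutoff:
#' average indication accuracy (the mean of per-indication accuracies),
#' pairwise accuracy (the weighted mean, weights `d`), and coverage (the
#' number — and percentage — of indications with nonzero accuracy).
#'
#' @param table A `similarity_ranking`.
#' @param mapping An `indication_mapping`, pre-filtered so every indication
#'   has at least two drugs (see [filter_benchmarkable()]).
#' @param cutoffs A `cutoff_spec` (default [default_cutoffs()]) or an
#'   integer vector of ranks; resolved against the compound library size.
#' @param pipeline_label Label attached to the result.
#' @return A `benchmark_result`. `tidy()` returns the long per-indication
#'   record table (`indication_id`, `d`, `cutoff`, `c`, `accuracy`);
#'   `glance()` the per-cutoff aggregates.
#' @export
benchmark_pipeline <- function(table, mapping, cutoffs = default_cutoffs(),
                               pipeline_label = "pipeline") {
  stopifnot(inherits(table, "similarity_ranking"))
  mapping <- filter_benchmarkable(indication_mapping(mapping))
  if (nrow(mapping) == 0) abort("no benchmarkable indication (all have < 2 drugs)")
  unknown <- setdiff(unique(mapping$compound_id), table$compound_ids)
  if (length(unknown) > 0) {
    abort(paste0(
      "mapping drug(s) absent from ranking table: ",
      paste(utils::head(unknown, 5), collapse = ", "),
      "; align the mapping first (align_mapping)"
    ))
  }
  n <- length(table$compound_ids)
  ks <- resolve_cutoffs(cutoffs, n)
  sets <- split(mapping$compound_id, mapping$indication_id)
  records <- purrr::imap(sets, function(drugs, ind) {
    best <- best_corank(table, unique(drugs))
    d <- length(best)
    cc <- vapply(ks, function(k) sum(best <= k), integer(1))
    tibble(
      indication_id = ind, d = d, cutoff = ks,
      c = cc, accuracy = cc / d * 100
    )
  }) %>%
    bind_rows() %>%
    arrange(.data$indication_id, .data$cutoff)
  new_benchmark_result(pipeline_label, ks, records)
}

new_benchmark_result <- function(pipeline_label, cutoffs, records) {
  aggregates <- records %>%
    group_by(cutoff = .data$cutoff) %>%
    summarise(
      average_indication_accuracy = mean(.data$accuracy),
      pairwise_accuracy = sum(.data$accuracy * .data$d) / sum(.data$d),
      coverage_count = sum(.data$accuracy > 0),
      coverage_percent = mean(.data$accuracy > 0) * 100,
      .groups = "drop"
    )
  structure(
    list(
      pipeline_label = pipeline_label,
      cutoffs = as.integer(cutoffs),
      records = records,
      aggregates = aggregates
    ),
    class = "benchmark_result"
  )
}

#' Aggregate metrics over per-indication records at one cutoff
#'
#' @param records A record tibble as returned by `tidy()` on a
#'   `benchmark_result` (columns `indication_id`, `d`, `cutoff`, `c`,
#'   `accuracy`).
#' @param k The cutoff to aggregate at.
#' @return A one-row tibble: `cutoff`, `average_indication_accuracy`,
#'   `pairwise_accuracy`, `coverage_count`, `coverage_percent`.
#' @export
aggregate_metrics <- function(records, k) {
  if (inherits(records, "benchmark_result")) records <- records$records
  rec <- records %>% filter(.data$cutoff == k)
  if (nrow(rec) == 0) abort(paste0("no records at cutoff ", k))
  tibble(
    cutoff = as.integer(k),
    average_indication_accuracy = mean(rec$accuracy),
    pairwise_accuracy = sum(rec$accuracy * rec$d) / sum(rec$d),
    coverage_count = sum(rec$accuracy > 0),
    coverage_percent = mean(rec$accuracy > 0) * 100
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("# Benchmark result for pipeline '", x$pipeline_label, "': ",
      dplyr::n_distinct(x$records$indication_id), " indications, cutoffs [",
      paste(x$cutoffs, collapse = ", "), "]\n", sep = "")
  print(x$aggregates, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.benchmark_result <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.benchmark_result <- function(x, ...) {
  x$aggregates %>% mutate(pipeline_label = x$pipeline_label, .before = 1)
}

#' Write / read a benchmark result
#'
#' The per-indication table is written as TSV with one accuracy column per
#' cutoff (`indication_id<TAB>d<TAB>acc@k1<TAB>acc@k2...`); the aggregate
#' summary as JSON keyed by cutoff.
#'
#' @param x A `benchmark_result`.
#' @param path Output TSV path; `write_benchmark_result()` also writes
#'   `<path>.summary.json` unless `summary_path` overrides it.
#' @param summary_path Optional path for the aggregate JSON.
#' @export
write_benchmark_result <- function(x, path, summary_path = NULL) {
  stopifnot(inherits(x, "benchmark_result"))
  wide <- x$records %>%
    select("indication_id", "d", "cutoff", "accuracy") %>%
    mutate(cutoff = sprintf("acc@%d", .data$cutoff)) %>%
    tidyr::pivot_wider(names_from = "cutoff", values_from = "accuracy") %>%
    arrange(.data$indication_id)
  write.table(as.data.frame(wide), path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8"
  )
  if (is.null(summary_path)) summary_path <- paste0(path, ".summary.json")
  agg <- split(
    x$aggregates %>% select(-"cutoff"),
    sprintf("top%d", x$aggregates$cutoff)
  )
  agg <- purrr::map(agg, ~ as.list(.x))
  jsonlite::write_json(
    list(pipeline_label = x$pipeline_label, aggregates = agg),
    summary_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_benchmark_result
#' @param pipeline_label Label for the reconstructed result (defaults to the
#'   file base name).
#' @export
read_benchmark_result <- function(path, pipeline_label = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(pipeline_label)) {
    pipeline_label <- sub("\\.tsv$", "", basename(path))
  }
  wide <- as_tibble(read.delim(path,
    header = TRUE, sep = "\t", check.names = FALSE, fileEncoding = "UTF-8"
  ))
  acc_cols <- grep("^acc@", names(wide), value = TRUE)
  if (length(acc_cols) == 0 || !all(c("indication_id", "d") %in% names(wide))) {
    abort(paste0("not a benchmark result TSV: ", path))
  }
  records <- wide %>%
    tidyr::pivot_longer(dplyr::all_of(acc_cols),
      names_to = "cutoff", values_to = "accuracy"
    ) %>%
    mutate(
      indication_id = as.character(.data$indication_id),
      cutoff = as.integer(sub("^acc@", "", .data$cutoff)),
      c = as.integer(round(.data$accuracy * .data$d / 100))
    ) %>%
    select("indication_id", "d", "cutoff", "c", "accuracy") %>%
    arrange(.data$indication_id, .data$cutoff)
  new_benchmark_result(pipeline_label, sort(unique(records$cutoff)), records)
}
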