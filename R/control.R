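#' Expected indication accuracy under random ranking
#'
#' Under the null, every compound's similarity list is an independent
#' uniform permutation of the other `N - 1` compounds. For a held-out drug
#' of an indication with `d` approved drugs, the number of its `d - 1`
#' co-approved drugs landing in the top `k` is hypergeometric, so the
#' chance of recovering at least one is
#' `1 - choose(N - 1 - (d - 1), k) / choose(N - 1, k)`.
#' Because each held-out drug's list is independent, this single-drug
#' probability is also the expected value of the indication accuracy
#' `c / d * 100`.
#'
#' @param N Compound library size.
#' @param d Indication approved-drug count, `2 <= d <= N`.
#' @param k Rank cutoff, `1 <= k <= N - 1`. `N`, `d`, `k` may be vectors
#'   (recycled).
#' @return Expected accuracy in percent. Closed forms: `d = 2` gives
#'   `100 * k / (N - 1)`; `k = N - 1` gives 100.
#' @examples
#' hypergeometric_indication_accuracy(N = 11, d = 3, k = 2) # ~37.78
#' @export
hypergeometric_indication_accuracy <- function(N, d, k) {
  r <- vctrs_recycle(N = as.numeric(N), d = as.numeric(d), k = as.numeric(k))
  N <- r$N; d <- r$d; k <- r$k
  if (any(d < 2 | d > N)) abort("need 2 <= d <= N")
  if (any(k < 1 | k > N - 1)) abort("need 1 <= k <= N - 1")
  # log-scale ratio of binomial coefficients; choose() underflow-safe
  p_none <- exp(lchoose(N - 1 - (d - 1), k) - lchoose(N - 1, k))
  100 * (1 - p_none)
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' Analytic random-control benchmark
#'
#' The reference pipeline every real pipeline is compared against: for each
#' benchmarkable indication the expected leave-one-out accuracy under
#' uniformly random rankings, computed from the hypergeometric distribution.
#' Aggregates follow the benchmark module; expected coverage uses the
#' per-indication probability of nonzero accuracy, which for this null is
#' the same recovery probability.
#'
#' @param mapping An `indication_mapping` (filtered to `d >= 2`; filtering
#'   is applied if needed).
#' @param N Compound library size.
#' @param cutoffs A `cutoff_spec` or integer rank vector.
#' @return A `benchmark_result` with `pipeline_label = "random-control"`;
#'   its `c` column holds expected (real-valued) counts `d * p`.
#' @export
random_control_benchmark <- function(mapping, N, cutoffs = default_cutoffs()) {
  mapping <- filter_benchmarkable(indication_mapping(mapping))
  if (nrow(mapping) == 0) abort("no benchmarkable indication (all have < 2 drugs)")
  N <- as.integer(N)
  sizes <- indication_sizes(mapping)
  if (any(sizes$d > N)) abort("an indication has more drugs than the library size N")
  ks <- resolve_cutoffs(cutoffs, N)
  records <- tidyr::crossing(
    sizes %>% select("indication_id", "d"),
    cutoff = ks
  ) %>%
    mutate(
      accuracy = hypergeometric_indication_accuracy(N, .data$d, .data$cutoff),
      c = .data$d * .data$accuracy / 100
    ) %>%
    select("indication_id", "d", "cutoff", "c", "accuracy") %>%
    arrange(.data$indication_id, .data$cutoff)
  res <- new_benchmark_result("random-control", ks, records)
  # coverage under the null is an expectation, not a count of realised > 0
  res$aggregates <- res$aggregates %>%
    mutate(
      coverage_percent = purrr::map_dbl(.data$cutoff, function(k) {
        rec <- records %>% filter(.data$cutoff == k)
        mean(rec$accuracy)
      }),
      coverage_count = .data$coverage_percent / 100 *
        dplyr::n_distinct(records$indication_id)
    )
  res
}

#' Monte Carlo estimate of the random-control accuracy
#'
#' Simulates the null directly: in a random ranking table every query's
#' list is an independent uniform permutation, so each held-out drug
#' recovers a co-drug iff at least one of `d - 1` uniformly sampled
#' distinct ranks falls within the top `k` — a hypergeometric-count event,
#' sampled here per drug and replicate. Each replicate yields an average
#' indication accuracy over the mapping; the replicate mean and its
#' standard error are returned. Serves as the independent oracle for
#' [hypergeometric_indication_accuracy()].
#'
#' @param mapping An `indication_mapping` (filtered to `d >= 2` if needed).
#' @param N Compound library size.
#' @param k Rank cutoff.
#' @param replicates Number of simulated ranking tables (>= 100).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A one-row tibble: `mean_accuracy`, `se`, `replicates`.
#' @export
monte_carlo_control <- function(mapping, N, k, replicates = 1e5, seed = 1L) {
  mapping <- filter_benchmarkable(indication_mapping(mapping))
  if (nrow(mapping) == 0) abort("no benchmarkable indication (all have < 2 drugs)")
  if (replicates < 100) abort("need >= 100 replicates")
  N <- as.integer(N)
  if (k < 1 || k > N - 1) abort(paste0("cutoff k must lie in [1, ", N - 1, "]"))
  sizes <- indication_sizes(mapping)
  if (any(sizes$d > N)) abort("an indication has more drugs than the library size N")
  withr::with_seed(seed, {
    per_ind <- purrr::map(sizes$d, function(d) {
      # co-drugs in the top k of each held-out drug's random list
      hits <- stats::rhyper(replicates * d, m = d - 1, n = N - d, k = k) > 0
      rowSums(matrix(hits, nrow = replicates, ncol = d)) / d * 100
    })
    acc <- Reduce(`+`, per_ind) / length(per_ind) # replicate-wise average
    tibble(
      mean_accuracy = mean(acc),
      se = stats::sd(acc) / sqrt(replicates),
      replicates = as.integer(replicates)
    )
  })
}
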