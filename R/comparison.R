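#' Win/tie counts between two pipelines at a cutoff
#'
#' Partitions the shared indication set by strict comparison of
#' per-indication accuracies: indications where pipeline A outperforms B,
#' where B outperforms A, and where both are equal — with the subcount of
#' ties at exactly zero accuracy reported separately, since at stringent
#' cutoffs most ties are double misses.
#'
#' @param res_a,res_b `benchmark_result` objects over identical indication
#'   sets.
#' @param k Cutoff present in both grids.
#' @return A one-row tibble: `cutoff`, `a_wins`, `b_wins`, `equal`,
#'   `equal_both_zero`. The first three always sum to the number of shared
#'   indications.
#' @export
venn_counts <- function(res_a, res_b, k) {
  paired <- paired_accuracies(res_a, res_b, k)
  tibble(
    cutoff = as.integer(k),
    a_wins = sum(paired$acc_a > paired$acc_b),
    b_wins = sum(paired$acc_b > paired$acc_a),
    equal = sum(paired$acc_a == paired$acc_b),
    equal_both_zero = sum(paired$acc_a == 0 & paired$acc_b == 0)
  )
}

paired_accuracies <- function(res_a, res_b, k) {
  stopifnot(inherits(res_a, "benchmark_result"), inherits(res_b, "benchmark_result"))
  a <- res_a$records %>% filter(.data$cutoff == k)
  b <- res_b$records %>% filter(.data$cutoff == k)
  if (nrow(a) == 0 || nrow(b) == 0) abort(paste0("no records at cutoff ", k))
  if (!setequal(a$indication_id, b$indication_id)) {
    diff <- c(setdiff(a$indication_id, b$indication_id),
              setdiff(b$indication_id, a$indication_id))
    abort(paste0("indication sets differ; symmetric difference: ",
                 paste(utils::head(diff, 10), collapse = ", ")))
  }
  left_join(
    a %>% select("indication_id", "d", acc_a = "accuracy", c_a = "c"),
    b %>% select("indication_id", acc_b = "accuracy", c_b = "c"),
    by = "indication_id"
  )
}

#' Per-indication net accuracy differences
#'
#' One record per indication with the signed accuracy difference
#' `acc_A - acc_B` at cutoff `k` and the number of drugs the winning
#' pipeline recovered, sorted by descending approved-drug count `d`.
#'
#' @inheritParams venn_counts
#' @return A tibble: `indication_id`, `d`, `diff` (in [-100, 100]),
#'   `drugs_recovered_by_winner`.
#' @export
net_difference_table <- function(res_a, res_b, k) {
  paired_accuracies(res_a, res_b, k) %>%
    mutate(
      diff = .data$acc_a - .data$acc_b,
      drugs_recovered_by_winner = ifelse(.data$acc_a >= .data$acc_b,
                                         .data$c_a, .data$c_b)
    ) %>%
    select("indication_id", "d", "diff", "drugs_recovered_by_winner") %>%
    arrange(desc(.data$d), .data$indication_id)
}

#' Two-sample Kolmogorov-Smirnov comparison of accuracy distributions
#'
#' Compares the distributions of per-indication accuracies of two pipelines:
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic two-sided Kolmogorov distribution at effective
#' sample size `n_a * n_b / (n_a + n_b)`. Accuracy vectors are heavily tied
#' (many indications at 0 or 100), so the p-value is an approximation,
#' adequate at the ~1000-indication scale this is meant for.
#'
#' @param acc_a,acc_b Non-empty numeric vectors of per-indication accuracies
#'   (or two `benchmark_result`s plus a cutoff `k`).
#' @param k Cutoff; required iff benchmark results are passed.
#' @return A one-row tibble: `statistic` (D, in [0, 1]) and `p_value`.
#' @export
ks_compare <- function(acc_a, acc_b, k = NULL) {
  if (inherits(acc_a, "benchmark_result")) {
    if (is.null(k)) abort("supply a cutoff k when passing benchmark results")
    paired <- paired_accuracies(acc_a, acc_b, k)
    acc_a <- paired$acc_a
    acc_b <- paired$acc_b
  }
  if (length(acc_a) == 0 || length(acc_b) == 0) abort("empty accuracy vector")
  # sup |ECDF_A - ECDF_B| over the pooled support
  pooled <- sort(unique(c(acc_a, acc_b)))
  d_stat <- max(abs(stats::ecdf(acc_a)(pooled) - stats::ecdf(acc_b)(pooled)))
  p <- suppressWarnings(
    stats::ks.test(acc_a, acc_b, exact = FALSE)$p.value
  )
  tibble(statistic = d_stat, p_value = p)
}

#' Drug-indication pair rank consensus across two pipelines
#'
#' For every (drug, indication) association in the benchmarkable mapping,
#' the pair's rank under a pipeline is the best (minimum) rank at which any
#' co-approved drug appears in that drug's similarity list. Plotting
#' `rank_a` against `rank_b` shows where two pipelines agree and where one
#' ranks an association far higher than the other.
#'
#' @param table_a,table_b `similarity_ranking` objects over the same
#'   compound library.
#' @param mapping An `indication_mapping` (filtered to `d >= 2` if needed).
#' @return A tibble: `compound_id`, `indication_id`, `rank_a`, `rank_b`;
#'   one row per association, `sum(d)` rows in total.
#' @export
pair_rank_consensus <- function(table_a, table_b, mapping) {
  stopifnot(inherits(table_a, "similarity_ranking"),
            inherits(table_b, "similarity_ranking"))
  if (!setequal(table_a$compound_ids, table_b$compound_ids)) {
    abort("the two ranking tables cover different compound libraries")
  }
  mapping <- filter_benchmarkable(indication_mapping(mapping))
  if (nrow(mapping) == 0) abort("no benchmarkable indication (all have < 2 drugs)")
  sets <- split(mapping$compound_id, mapping$indication_id)
  purrr::imap(sets, function(drugs, ind) {
    drugs <- unique(drugs)
    tibble(
      compound_id = drugs,
      indication_id = ind,
      rank_a = unname(best_corank(table_a, drugs)),
      rank_b = unname(best_corank(table_b, drugs))
    )
  }) %>%
    bind_rows() %>%
    arrange(.data$indication_id, .data$compound_id)
}

#' Indication-indication association network from shared top-k compounds
#'
#' Indications sharing highly ranked compounds are related: each
#' indication's candidate set is the union, over its approved drugs, of the
#' top-`k` most-similar compounds of each drug; an edge connects two
#' indications with weight equal to the size of the intersection of their
#' candidate sets. Zero-weight edges are omitted.
#'
#' @param table A `similarity_ranking`.
#' @param mapping An `indication_mapping` (filtered to `d >= 2` if needed).
#' @param k Rank cutoff defining "highly ranked".
#' @return A weighted edge list tibble: `indication_a`, `indication_b`
#'   (with `indication_a < indication_b`), `shared`. Importable by any
#'   graph tool.
#' @export
indication_association_network <- function(table, mapping, k) {
  stopifnot(inherits(table, "similarity_ranking"))
  mapping <- filter_benchmarkable(indication_mapping(mapping))
  if (nrow(mapping) == 0) abort("no benchmarkable indication (all have < 2 drugs)")
  n <- length(table$compound_ids)
  if (k < 1 || k > n - 1) abort(paste0("cutoff k must lie in [1, ", n - 1, "]"))
  top <- table$ranking %>% filter(.data$rank <= k)
  topsets <- split(top$other_id, top$query_id)
  sets <- split(mapping$compound_id, mapping$indication_id)
  cand <- purrr::map(sets, function(drugs) {
    unique(unlist(topsets[unique(drugs)], use.names = FALSE))
  })
  inds <- names(cand)
  if (length(inds) < 2) {
    return(tibble(indication_a = character(), indication_b = character(),
                  shared = integer()))
  }
  pairs <- utils::combn(inds, 2)
  edges <- tibble(
    indication_a = pairs[1, ],
    indication_b = pairs[2, ],
    shared = purrr::map2_int(pairs[1, ], pairs[2, ], function(i, j) {
      length(intersect(cand[[i]], cand[[j]]))
    })
  )
  edges %>% filter(.data$shared > 0) %>%
    arrange(.data$indication_a, .data$indication_b)
}

#' Full two-pipeline comparison report
#'
#' Bundles every cross-pipeline divergence analytic at one cutoff: the
#' win/tie partition, the per-indication net differences, the KS
#' distribution comparison, and the paired accuracy scatter points.
#'
#' @inheritParams venn_counts
#' @return A `comparison_report` list with elements `venn`,
#'   `net_differences`, `ks`, `consensus_points`, plus the two labels and
#'   the cutoff.
#' @export
compare_pipelines <- function(res_a, res_b, k) {
  paired <- paired_accuracies(res_a, res_b, k)
  structure(
    list(
      label_a = res_a$pipeline_label,
      label_b = res_b$pipeline_label,
      cutoff = as.integer(k),
      venn = venn_counts(res_a, res_b, k),
      net_differences = net_difference_table(res_a, res_b, k),
      ks = ks_compare(paired$acc_a, paired$acc_b),
      consensus_points = paired %>%
        select("indication_id", "d", "acc_a", "acc_b")
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("# Pipeline comparison '", x$label_a, "' vs '", x$label_b,
      "' at top", x$cutoff, "\n", sep = "")
  print(x$venn)
  cat("KS: D = ", format(x$ks$statistic, digits = 4),
      ", p = ", format(x$ks$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
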