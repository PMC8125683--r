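fixed_result <- function(label, acc, d = NULL, k = 1L) {
  n <- length(acc)
  if (is.null(d)) d <- rep(2L, n)
  recs <- tibble::tibble(
    indication_id = sprintf("I%02d", seq_len(n)),
    d = as.integer(d), cutoff = as.integer(k),
    c = as.integer(round(acc * d / 100)), accuracy = acc
  )
  res <- benchmark_pipeline(
    make_ranking_table(list(A = "B", B = "A")), toy_mapping(c("A", "B")), 1, label
  )
  res$records <- recs
  res$cutoffs <- as.integer(k)
  res$aggregates <- aggregate_metrics(recs, k)
  res
}

test_that("venn counts partition the indication set with the both-zero subcount", {
  a <- fixed_result("a", c(50, 0, 0))
  b <- fixed_result("b", c(0, 0, 0))
  v <- venn_counts(a, b, 1)
  expect_equal(v$a_wins, 1)
  expect_equal(v$b_wins, 0)
  expect_equal(v$equal, 2)
  expect_equal(v$equal_both_zero, 2)
  expect_equal(v$a_wins + v$b_wins + v$equal, 3)

  v_same <- venn_counts(a, a, 1)
  expect_equal(v_same$a_wins, 0)
  expect_equal(v_same$equal, 3)
  expect_equal(v_same$equal_both_zero, 2)
})

test_that("venn counts partition randomly generated comparisons at every cutoff", {
  withr::with_seed(606, {
    for (rep in 1:5) {
      acc_a <- sample(c(0, 25, 50, 100), 8, replace = TRUE)
      acc_b <- sample(c(0, 25, 50, 100), 8, replace = TRUE)
      v <- venn_counts(fixed_result("a", acc_a), fixed_result("b", acc_b), 1)
      expect_equal(v$a_wins + v$b_wins + v$equal, 8)
      expect_lte(v$equal_both_zero, v$equal)
    }
  })
})

test_that("net differences subtract accuracies and are antisymmetric", {
  a <- fixed_result("a", c(100, 40), d = c(4, 8))
  b <- fixed_result("b", c(25, 40), d = c(4, 8))
  tab <- net_difference_table(a, b, 1)
  expect_identical(tab$indication_id, c("I02", "I01")) # descending d
  expect_equal(tab$diff[tab$indication_id == "I01"], 75)
  expect_equal(tab$drugs_recovered_by_winner[tab$indication_id == "I01"], 4)
  rev_tab <- net_difference_table(b, a, 1)
  expect_equal(tab$diff, -rev_tab$diff)
  expect_true(all(abs(tab$diff) <= 100))
  same <- net_difference_table(a, a, 1)
  expect_true(all(same$diff == 0))
})

test_that("KS comparison matches ECDF enumeration and is symmetric", {
  same <- ks_compare(c(0, 50, 100), c(0, 50, 100))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  disjoint <- ks_compare(rep(0, 40), rep(100, 40))
  expect_equal(disjoint$statistic, 1)
  expect_lt(disjoint$p_value, 1e-6)

  # ECDF_A jumps to 1 at 50, ECDF_B still 0 there
  expect_equal(ks_compare(c(0, 50), c(100, 100))$statistic, 1)

  withr::with_seed(17, {
    x <- sample(seq(0, 100, 25), 30, replace = TRUE)
    y <- sample(seq(0, 100, 25), 20, replace = TRUE)
  })
  expect_equal(ks_compare(x, y)$statistic, ks_compare(y, x)$statistic)
  # agrees with the standard two-sample implementation
  expect_equal(
    ks_compare(x, y)$statistic,
    unname(suppressWarnings(stats::ks.test(x, y))$statistic)
  )
  expect_error(ks_compare(numeric(), 1), "empty")
})

test_that("pair rank consensus lies on the diagonal when matrices coincide", {
  withr::with_seed(19, {
    inst <- random_instance(seed = 777, discrete = FALSE)
  })
  map <- filter_benchmarkable(indication_mapping(inst$mapping))
  rk <- compute_rankings(interaction_matrix(inst$scores))
  cons <- pair_rank_consensus(rk, rk, map)
  expect_equal(cons$rank_a, cons$rank_b)
  expect_equal(nrow(cons), sum(indication_sizes(map)$d)) # one row per pair
})

test_that("pair rank consensus recovers the toy best co-drug ranks", {
  tab_a <- make_ranking_table(list(
    A = c("B", "C", "D"), B = c("C", "A", "D"),
    C = c("A", "B", "D"), D = c("A", "C", "B")
  ))
  tab_b <- make_ranking_table(list(
    A = c("D", "C", "B"), B = c("A", "C", "D"),
    C = c("A", "B", "D"), D = c("A", "C", "B")
  ))
  cons <- pair_rank_consensus(tab_a, tab_b, toy_mapping(c("A", "B")))
  expect_equal(cons$rank_a[cons$compound_id == "A"], 1) # B at rank 1 in A's list
  expect_equal(cons$rank_a[cons$compound_id == "B"], 2)
  expect_equal(cons$rank_b[cons$compound_id == "A"], 3)
  expect_equal(cons$rank_b[cons$compound_id == "B"], 1)
  bad <- make_ranking_table(list(X = "Y", Y = "X"))
  expect_error(pair_rank_consensus(tab_a, bad, toy_mapping(c("A", "B"))),
               "different compound libraries")
})

test_that("association network links indications sharing top-k compounds", {
  # two tight clusters far apart plus shared-drug indications
  withr::with_seed(23, {
    scores <- rbind(
      matrix(rnorm(6 * 2, 0, 0.1), 6, 2),
      matrix(rnorm(6 * 2, 100, 0.1), 6, 2)
    )
  })
  dimnames(scores) <- list(sprintf("D%02d", 1:12), c("P1", "P2"))
  rk <- compute_rankings(interaction_matrix(scores))
  # I1, I2 inside cluster one; I3 inside cluster two
  map <- toy_mapping(c("D01", "D02"), c("D03", "D04"), c("D07", "D08"))
  net <- indication_association_network(rk, map, k = 3)
  pair <- function(i, j) net$shared[net$indication_a == i & net$indication_b == j]
  expect_gt(pair("I1", "I2"), 0)
  expect_length(pair("I1", "I3"), 0) # cross-cluster edge omitted at small k
  expect_length(pair("I2", "I3"), 0)

  # identical drug sets give full overlap: weight = |candidate set|
  map_same <- toy_mapping(c("D01", "D02"), c("D01", "D02"))
  net_same <- indication_association_network(rk, map_same, k = 3)
  top <- tidy(rk) %>%
    dplyr::filter(rank <= 3, query_id %in% c("D01", "D02"))
  expect_equal(net_same$shared, dplyr::n_distinct(top$other_id))

  # weights are bounded by the smaller candidate set
  full_net <- indication_association_network(rk, map, k = 11)
  expect_true(all(full_net$shared <= 12))
})

test_that("compare_pipelines bundles the divergence analytics coherently", {
  a <- fixed_result("a", c(50, 0, 100), d = c(2, 3, 4))
  b <- fixed_result("b", c(50, 25, 0), d = c(2, 3, 4))
  rep <- compare_pipelines(a, b, 1)
  expect_s3_class(rep, "comparison_report")
  expect_equal(rep$venn$a_wins + rep$venn$b_wins + rep$venn$equal, 3)
  expect_equal(nrow(rep$consensus_points), 3)
  expect_equal(sort(rep$net_differences$diff), c(-25, 0, 100))
  expect_gte(rep$ks$statistic, 0)
  expect_lte(rep$ks$statistic, 1)
})
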