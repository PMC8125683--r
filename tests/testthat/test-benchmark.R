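# a toy with explicit similarity lists for compounds A-D
toy_table <- function() {
  make_ranking_table(list(
    A = c("B", "C", "D"),
    B = c("C", "A", "D"),
    C = c("A", "B", "D"),
    D = c("A", "C", "B")
  ))
}

test_that("leave-one-out accuracy counts held-out drugs recovering a co-drug", {
  tab <- toy_table()
  # A finds B at rank 1; B finds A only at rank 2
  r1 <- indication_accuracy(tab, c("A", "B"), k = 1)
  expect_equal(r1$c, 1)
  expect_equal(r1$d, 2)
  expect_equal(r1$accuracy, 50)
  r2 <- indication_accuracy(tab, c("A", "B"), k = 2)
  expect_equal(r2$accuracy, 100)
  # at k = N - 1 every co-drug is inside the list
  expect_equal(indication_accuracy(tab, c("A", "B"), k = 3)$accuracy, 100)
  expect_equal(indication_accuracy(tab, c("C", "D"), k = 3)$accuracy, 100)
  expect_error(indication_accuracy(tab, c("A", "Z"), 1), "unknown")
  expect_error(indication_accuracy(tab, "A", 1), ">= 2 drugs")
  expect_error(indication_accuracy(tab, c("A", "B"), 4), "\\[1, 3\\]")
})

test_that("benchmark_pipeline reproduces the toy per-cutoff accuracies", {
  res <- benchmark_pipeline(toy_table(), toy_mapping(c("A", "B")), 1:3, "toy")
  expect_s3_class(res, "benchmark_result")
  expect_equal(tidy(res)$accuracy, c(50, 100, 100))
  expect_equal(tidy(res)$c, c(1L, 2L, 2L))
  agg <- glance(res)
  expect_equal(agg$average_indication_accuracy, c(50, 100, 100))
  expect_equal(agg$pipeline_label, rep("toy", 3))
  expect_error(
    benchmark_pipeline(toy_table(), toy_mapping(c("A", "Z")), 1),
    "absent"
  )
  expect_warning(
    expect_error(
      benchmark_pipeline(toy_table(), toy_mapping("A", "B"), 1),
      "benchmarkable"
    ),
    "no indication"
  )
})

test_that("perfectly clustered disjoint indications all reach 100%", {
  block <- function(center) matrix(rnorm(4 * 3, center, 0.01), 4, 3)
  withr::with_seed(7, {
    scores <- rbind(block(0), block(50))
  })
  dimnames(scores) <- list(sprintf("D%d", 1:8), sprintf("P%d", 1:3))
  res <- benchmark_pipeline(
    compute_rankings(interaction_matrix(scores)),
    toy_mapping(sprintf("D%d", 1:4), sprintf("D%d", 5:8)),
    7, "clustered"
  )
  expect_equal(tidy(res)$accuracy, c(100, 100))
  expect_equal(glance(res)$average_indication_accuracy, 100)
})

test_that("aggregate metrics match hand arithmetic and collapse when d equal", {
  recs <- tibble::tibble(
    indication_id = c("I1", "I2"), d = c(2L, 8L), cutoff = 5L,
    c = c(2L, 0L), accuracy = c(100, 0)
  )
  agg <- aggregate_metrics(recs, 5)
  expect_equal(agg$average_indication_accuracy, 50)
  expect_equal(agg$pairwise_accuracy, 20) # (100*2 + 0*8) / 10
  expect_equal(agg$coverage_count, 1L)
  expect_equal(agg$coverage_percent, 50)

  zero <- recs %>% dplyr::mutate(c = 0L, accuracy = 0)
  agg0 <- aggregate_metrics(zero, 5)
  expect_equal(agg0$average_indication_accuracy, 0)
  expect_equal(agg0$pairwise_accuracy, 0)
  expect_equal(agg0$coverage_count, 0L)

  equal_d <- recs %>% dplyr::mutate(d = 3L)
  agg_eq <- aggregate_metrics(equal_d, 5)
  expect_equal(agg_eq$pairwise_accuracy, agg_eq$average_indication_accuracy)
})

test_that("per-indication accuracy and aggregates are non-decreasing in k", {
  withr::with_seed(97, {
    for (rep in 1:5) {
      inst <- random_instance(seed = 7000 + rep)
      map <- indication_mapping(inst$mapping)
      if (nrow(filter_benchmarkable(map)) == 0) next
      ks <- seq_len(nrow(inst$scores) - 1)
      res <- benchmark_pipeline(
        compute_rankings(interaction_matrix(inst$scores)), map, ks
      )
      tidy(res) %>%
        dplyr::group_by(indication_id) %>%
        dplyr::summarise(mono = !is.unsorted(accuracy), .groups = "drop") %>%
        dplyr::pull(mono) %>%
        all() %>%
        expect_true()
      agg <- glance(res)
      expect_false(is.unsorted(agg$average_indication_accuracy))
      expect_false(is.unsorted(agg$pairwise_accuracy))
      expect_false(is.unsorted(agg$coverage_percent))
      # weighted mean bounded by the accuracy range
      for (k in ks) {
        rec <- tidy(res) %>% dplyr::filter(cutoff == k)
        expect_gte(agg$pairwise_accuracy[agg$cutoff == k], min(rec$accuracy))
        expect_lte(agg$pairwise_accuracy[agg$cutoff == k], max(rec$accuracy))
      }
    }
  })
})

test_that("relabeling compounds permutes records but preserves aggregates", {
  withr::with_seed(55, {
    scores <- matrix(rnorm(9 * 4), 9, 4,
      dimnames = list(sprintf("D%02d", 1:9), sprintf("P%d", 1:4))
    )
    map <- toy_mapping(c("D01", "D03", "D05"), c("D02", "D09"))
    perm <- sample(sprintf("X%02d", 1:9))
  })
  res1 <- benchmark_pipeline(
    compute_rankings(interaction_matrix(scores)), map, c(2, 5)
  )
  relabel <- stats::setNames(perm, rownames(scores))
  scores2 <- scores
  rownames(scores2) <- relabel[rownames(scores)]
  map2 <- map %>% dplyr::mutate(compound_id = unname(relabel[compound_id]))
  res2 <- benchmark_pipeline(
    compute_rankings(interaction_matrix(scores2)), map2, c(2, 5)
  )
  expect_equal(res1$aggregates, res2$aggregates)
})

test_that("benchmark result TSV + JSON round-trips records and aggregates", {
  withr::with_seed(77, {
    inst <- random_instance(seed = 123)
  })
  map <- filter_benchmarkable(indication_mapping(inst$mapping))
  res <- benchmark_pipeline(
    compute_rankings(interaction_matrix(inst$scores)), map, c(1, 3), "rt"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark_result(res, path)
  back <- read_benchmark_result(path, "rt")
  expect_equal(as.data.frame(tidy(back)), as.data.frame(tidy(res)))
  expect_equal(back$aggregates, res$aggregates)
  js <- jsonlite::read_json(paste0(path, ".summary.json"))
  expect_equal(js$pipeline_label, "rt")
  expect_equal(
    js$aggregates$top1$average_indication_accuracy,
    res$aggregates$average_indication_accuracy[res$aggregates$cutoff == 1]
  )
})
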