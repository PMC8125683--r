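#' Build a per-indication decision tree over pipelines
#'
#' Several pipelines benchmarked on the same indication set can be combined
#' by letting each indication adopt whichever pipeline scores it best. The
#' choice is made once, at a single selection cutoff (by default the most
#' stringent rank in the shared grid, conventionally top10), and carried to
#' all other cutoffs; `reselect_per_cutoff = TRUE` instead re-selects at
#' every cutoff. Ties — including the all-zero case — go to the earliest
#' pipeline in `priority`.
#'
#' @param results A list of two or more `benchmark_result` objects with
#'   identical indication sets and cutoff grids and distinct labels.
#' @param selection_cutoff Rank at which performance is compared; must be in
#'   the shared cutoff grid. Defaults to the smallest cutoff.
#' @param priority Character vector of pipeline labels, highest priority
#'   first; defaults to the order of `results`.
#' @param reselect_per_cutoff Re-run the selection at every cutoff instead
#'   of carrying the selection-cutoff choice (default `FALSE`).
#' @return A `hybrid_assignment`: a tibble (`indication_id`, `cutoff`,
#'   `pipeline_label`) with the selection parameters as attributes. With
#'   carry-over selection every indication has one label across cutoffs.
#' @examples
#' # see ?hybrid_benchmark
#' @export
build_decision_tree <- function(results, selection_cutoff = NULL,
                                priority = NULL, reselect_per_cutoff = FALSE) {
  check_result_list(results)
  labels <- purrr::map_chr(results, "pipeline_label")
  ks <- results[[1]]$cutoffs
  if (is.null(selection_cutoff)) selection_cutoff <- min(ks)
  if (!selection_cutoff %in% ks) {
    abort(paste0("selection_cutoff ", selection_cutoff,
                 " is not in the shared cutoff grid"))
  }
  if (is.null(priority)) priority <- labels
  if (!setequal(priority, labels) || anyDuplicated(priority)) {
    abort("priority must order the pipeline labels exactly")
  }
  acc <- purrr::map(results, function(r) {
    r$records %>%
      select("indication_id", "cutoff", "accuracy") %>%
      mutate(pipeline_label = r$pipeline_label)
  }) %>% bind_rows()
  pick_at <- function(k) {
    acc %>%
      filter(.data$cutoff == k) %>%
      mutate(prio = match(.data$pipeline_label, priority)) %>%
      group_by(.data$indication_id) %>%
      arrange(desc(.data$accuracy), .data$prio, .by_group = TRUE) %>%
      dplyr::slice(1L) %>%
      ungroup() %>%
      select("indication_id", "pipeline_label")
  }
  assignment <- if (reselect_per_cutoff) {
    purrr::map(ks, function(k) pick_at(k) %>% mutate(cutoff = k, .after = 1)) %>%
      bind_rows()
  } else {
    tidyr::crossing(pick_at(selection_cutoff), cutoff = ks) %>%
      select("indication_id", "cutoff", "pipeline_label")
  }
  structure(
    assignment %>% arrange(.data$indication_id, .data$cutoff),
    selection_cutoff = as.integer(selection_cutoff),
    pipeline_priority = priority,
    reselect_per_cutoff = reselect_per_cutoff,
    class = c("hybrid_assignment", class(tibble()))
  )
}

check_result_list <- function(results) {
  if (length(results) < 2) abort("a hybrid needs >= 2 constituent results")
  purrr::walk(results, function(r) {
    if (!inherits(r, "benchmark_result")) abort("results must be benchmark_result objects")
  })
  labels <- purrr::map_chr(results, "pipeline_label")
  if (anyDuplicated(labels)) abort("pipeline labels must be distinct")
  ref_inds <- sort(unique(results[[1]]$records$indication_id))
  ref_ks <- results[[1]]$cutoffs
  for (r in results[-1]) {
    inds <- sort(unique(r$records$indication_id))
    if (!identical(inds, ref_inds)) {
      diff <- c(setdiff(inds, ref_inds), setdiff(ref_inds, inds))
      abort(paste0(
        "indication sets differ between pipelines; symmetric difference: ",
        paste(utils::head(diff, 10), collapse = ", ")
      ))
    }
    if (!identical(r$cutoffs, ref_ks)) abort("cutoff grids differ between pipelines")
  }
  invisible(results)
}

#' Benchmark the hybrid decision-tree pipeline
#'
#' Assembles the hybrid's per-indication records by copying, at every
#' cutoff, the record of the pipeline assigned to that indication, then
#' recomputes all aggregates. At the selection cutoff the hybrid's
#' per-indication accuracy equals the maximum over constituents by
#' construction, so its average indication accuracy is at least that of
#' every constituent.
#'
#' @param assignment A `hybrid_assignment` from [build_decision_tree()].
#' @param results The same list of `benchmark_result` objects the
#'   assignment was built from.
#' @param pipeline_label Label for the hybrid result (default `"hybrid"`).
#' @return A `benchmark_result`.
#' @examples
#' m1 <- interaction_matrix(matrix(c(0, 0.1, 9, 5, 0, 0.1, 9, 5), 4, 2,
#'   dimnames = list(c("A", "B", "C", "E"), c("P1", "P2"))))
#' m2 <- interaction_matrix(matrix(c(9, 0.1, 0, 5, 9, 0.1, 0, 5), 4, 2,
#'   dimnames = list(c("A", "B", "C", "E"), c("P1", "P2"))))
#' map <- indication_mapping(tibble::tibble(
#'   indication_id = c("I1", "I1", "I2", "I2"),
#'   compound_id = c("A", "B", "B", "C")
#' ))
#' r1 <- benchmark_pipeline(compute_rankings(m1), map, 1, "one")
#' r2 <- benchmark_pipeline(compute_rankings(m2), map, 1, "two")
#' hybrid_benchmark(build_decision_tree(list(r1, r2)), list(r1, r2))
#' @export
hybrid_benchmark <- function(assignment, results, pipeline_label = "hybrid") {
  stopifnot(inherits(assignment, "hybrid_assignment"))
  check_result_list(results)
  labels <- purrr::map_chr(results, "pipeline_label")
  unknown <- setdiff(unique(assignment$pipeline_label), labels)
  if (length(unknown) > 0) {
    abort(paste0("assignment references unknown pipeline(s): ",
                 paste(unknown, collapse = ", ")))
  }
  all_records <- purrr::map(results, function(r) {
    r$records %>% mutate(pipeline_label = r$pipeline_label)
  }) %>% bind_rows()
  plain <- tibble(
    indication_id = assignment$indication_id,
    cutoff = assignment$cutoff,
    pipeline_label = assignment$pipeline_label
  )
  records <- plain %>%
    left_join(all_records, by = c("indication_id", "cutoff", "pipeline_label")) %>%
    select("indication_id", "d", "cutoff", "c", "accuracy") %>%
    arrange(.data$indication_id, .data$cutoff)
  if (anyNA(records$accuracy)) {
    abort("assignment refers to (indication, cutoff) pairs absent from the results")
  }
  new_benchmark_result(pipeline_label, results[[1]]$cutoffs, records)
}

#' Write a hybrid assignment as TSV
#'
#' Columns `indication_id<TAB>chosen_pipeline` (the assignment at the
#' selection cutoff).
#'
#' @param assignment A `hybrid_assignment`.
#' @param path Output path.
#' @export
write_hybrid_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "hybrid_assignment"))
  sel <- attr(assignment, "selection_cutoff")
  out <- as_tibble(assignment) %>%
    filter(.data$cutoff == sel) %>%
    select("indication_id", chosen_pipeline = "pipeline_label") %>%
    arrange(.data$indication_id)
  write.table(as.data.frame(out), path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
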