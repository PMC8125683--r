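#' Construct a drug-indication mapping
#'
#' A mapping associates clinical indications with their approved compounds.
#' It is stored long: one row per (indication, compound) association, as a
#' tibble with columns `indication_id`, `indication_name`, `compound_id`.
#' Duplicate associations are collapsed to set semantics with a warning.
#'
#' @param x A data frame with columns `indication_id`, `indication_name`
#'   (optional; defaults to the id) and `compound_id`.
#' @return An `indication_mapping` tibble.
#' @examples
#' indication_mapping(tibble::tibble(
#'   indication_id = c("I1", "I1", "I2"),
#'   compound_id = c("D1", "D2", "D1")
#' ))
#' @export
indication_mapping <- function(x) {
  x <- as_tibble(x)
  if (!all(c("indication_id", "compound_id") %in% names(x))) {
    abort("mapping needs columns indication_id and compound_id")
  }
  if (nrow(x) == 0) abort("empty indication mapping")
  if (!"indication_name" %in% names(x)) x$indication_name <- x$indication_id
  x <- x[, c("indication_id", "indication_name", "compound_id")]
  x$indication_id <- as.character(x$indication_id)
  x$indication_name <- as.character(x$indication_name)
  x$compound_id <- as.character(x$compound_id)
  dup <- duplicated(x[, c("indication_id", "compound_id")])
  if (any(dup)) {
    warn(paste0("collapsed ", sum(dup), " duplicate drug-indication association(s)"))
    x <- x[!dup, , drop = FALSE]
  }
  class(x) <- c("indication_mapping", class(tibble()))
  x
}

#' Read / write a drug-indication mapping TSV
#'
#' Tab-separated, UTF-8, header `indication_id<TAB>indication_name<TAB>compound_id`,
#' one association per row.
#'
#' @param path Path to a TSV file.
#' @return `read_indication_mapping()` returns an `indication_mapping`;
#'   `write_indication_mapping()` returns `path` invisibly.
#' @export
read_indication_mapping <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- read.delim(path,
    header = TRUE, sep = "\t", quote = "", comment.char = "",
    colClasses = "character", check.names = FALSE, fileEncoding = "UTF-8"
  )
  need <- c("indication_id", "indication_name", "compound_id")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("mapping TSV missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort(paste0("empty mapping file: ", path))
  indication_mapping(as_tibble(raw))
}

#' @rdname read_indication_mapping
#' @param x An `indication_mapping`.
#' @export
write_indication_mapping <- function(x, path) {
  x <- indication_mapping(x)
  write.table(as.data.frame(x), path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Per-indication approved-drug counts
#'
#' @param mapping An `indication_mapping`.
#' @return A tibble with columns `indication_id`, `indication_name`, `d`
#'   (number of distinct associated compounds).
#' @export
indication_sizes <- function(mapping) {
  mapping <- indication_mapping(mapping)
  mapping %>%
    group_by(.data$indication_id, .data$indication_name) %>%
    summarise(d = dplyr::n_distinct(.data$compound_id), .groups = "drop") %>%
    arrange(.data$indication_id)
}

#' Restrict a mapping to benchmarkable indications
#'
#' Leave-one-out recovery is only defined for indications with at least two
#' approved drugs (holding out the single drug of a singleton indication
#' leaves nothing to recover), so benchmarking is restricted to indications
#' with `d >= min_drugs`.
#'
#' @param mapping An `indication_mapping`.
#' @param min_drugs Minimum number of associated compounds (default 2).
#' @return A filtered `indication_mapping`; the input is unmodified. An empty
#'   result is permitted and triggers a warning.
#' @export
filter_benchmarkable <- function(mapping, min_drugs = 2L) {
  mapping <- indication_mapping(mapping)
  if (min_drugs < 2) abort("min_drugs must be >= 2")
  keep <- indication_sizes(mapping) %>% filter(.data$d >= min_drugs)
  out <- mapping %>% semi_join(keep, by = "indication_id")
  if (nrow(out) == 0) {
    warn(paste0("no indication has >= ", min_drugs, " associated drugs"))
    class(out) <- c("indication_mapping", class(tibble()))
    return(out)
  }
  indication_mapping(out)
}

#' Drop mapping drugs absent from a companion interaction matrix
#'
#' Public drug and indication libraries drift out of sync across versions;
#' associations whose compound is not in the score matrix are dropped with a
#' warning rather than treated as errors. An indication may thereby fall
#' below the benchmarkable threshold downstream.
#'
#' @param mapping An `indication_mapping`.
#' @param matrix An `interaction_matrix`.
#' @return The mapping restricted to compounds present in `matrix`.
#' @export
align_mapping <- function(mapping, matrix) {
  mapping <- indication_mapping(mapping)
  ids <- compound_ids(matrix)
  missing <- setdiff(unique(mapping$compound_id), ids)
  if (length(missing) > 0) {
    warn(paste0(
      "dropped ", length(missing), " mapped drug(s) absent from the matrix: ",
      paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..." else ""
    ))
    mapping <- mapping %>% filter(.data$compound_id %in% ids)
    if (nrow(mapping) == 0) abort("no mapped drug is present in the matrix")
  }
  indication_mapping(mapping)
}

#' @export
print.indication_mapping <- function(x, ...) {
  cat("# Indication mapping: ", dplyr::n_distinct(x$indication_id),
      " indications, ", nrow(x), " associations\n", sep = "")
  NextMethod()
}
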