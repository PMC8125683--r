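#' Construct an interaction matrix
#'
#' An interaction matrix holds one proteome interaction signature per
#' compound: a real-valued score for every (compound, protein) pair, as
#' produced by any docking or virtual-screening method. Scores are
#' unit-agnostic within a single matrix (binding-energy magnitudes,
#' similarity scores, ...); the framework only ever compares signatures
#' within one matrix, never raw scores across matrices.
#'
#' The object is a tibble with a `compound_id` character column followed by
#' one numeric column per protein, carrying class `interaction_matrix` so
#' that it prints and pipes like any other tibble.
#'
#' @param x A data frame whose first column holds unique compound identifiers
#'   and whose remaining columns are numeric protein scores, or a numeric
#'   matrix with compound row names and protein column names.
#' @return An `interaction_matrix` tibble.
#' @examples
#' m <- interaction_matrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("D1", "D2", "D3"), c("P1", "P2"))))
#' compound_ids(m)
#' @export
interaction_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs compound row names and protein column names")
    }
    x <- tibble(compound_id = rownames(x)) %>%
      dplyr::bind_cols(as_tibble(x, .name_repair = "minimal"))
  }
  x <- as_tibble(x, .name_repair = "minimal")
  if (ncol(x) < 2) abort("an interaction matrix needs at least one protein column")
  names(x)[1] <- "compound_id"
  x$compound_id <- as.character(x$compound_id)
  validate_interaction_matrix(x)
  class(x) <- c("interaction_matrix", class(tibble()))
  x
}

validate_interaction_matrix <- function(x) {
  ids <- x$compound_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate compound id(s): ", paste(dup, collapse = ", ")))
  }
  prots <- names(x)[-1]
  dup <- unique(prots[duplicated(prots)])
  if (length(dup) > 0) {
    abort(paste0("duplicate protein id(s): ", paste(dup, collapse = ", ")))
  }
  for (j in seq_along(prots)) {
    col <- x[[j + 1L]]
    if (!is.numeric(col)) {
      abort(paste0("non-numeric scores in protein column '", prots[j], "'"))
    }
    bad <- which(!is.finite(col))
    if (length(bad) > 0) {
      abort(paste0(
        "non-finite score at compound '", ids[bad[1]],
        "', protein '", prots[j], "'"
      ))
    }
  }
  invisible(x)
}

#' @rdname interaction_matrix
#' @export
compound_ids <- function(x) {
  stopifnot(is.data.frame(x))
  as.character(x[[1]])
}

#' @rdname interaction_matrix
#' @export
protein_ids <- function(x) {
  stopifnot(is.data.frame(x))
  names(x)[-1]
}

#' Extract the dense score matrix from an interaction matrix
#'
#' @param x An `interaction_matrix` (or compatible data frame).
#' @return A numeric matrix, compounds in rows (row names = compound ids),
#'   proteins in columns.
#' @export
as_score_matrix <- function(x) {
  x <- interaction_matrix(x)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$compound_id
  m
}

#' Extract one compound's proteome signature
#'
#' @param x An `interaction_matrix`.
#' @param compound A compound id present in `x`.
#' @return A named numeric vector of length `length(protein_ids(x))`.
#' @export
proteome_signature <- function(x, compound) {
  x <- interaction_matrix(x)
  i <- match(compound, x$compound_id)
  if (is.na(i)) abort(paste0("unknown compound id: ", compound))
  v <- as.numeric(unlist(x[i, -1]))
  names(v) <- protein_ids(x)
  v
}

#' Read / write an interaction matrix TSV
#'
#' The on-disk format is a UTF-8 tab-separated table: a header row whose
#' first cell is a label (conventionally `compound_id`) followed by protein
#' ids, then one row per compound holding its id and one numeric score per
#' protein. Scores are written with enough digits to round-trip doubles
#' exactly.
#'
#' @param path Path to a TSV file.
#' @return `read_interaction_matrix()` returns a validated
#'   `interaction_matrix` preserving the file order of compounds and
#'   proteins; `write_interaction_matrix()` returns `path` invisibly.
#' @export
read_interaction_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) < 2) abort(paste0("no data rows in ", path))
  width <- nf[1]
  ragged <- which(nf != width)
  if (length(ragged) > 0) {
    abort(paste0(
      "ragged row ", ragged[1], " in ", path, ": expected ",
      width - 1L, " scores, found ", nf[ragged[1]] - 1L
    ))
  }
  raw <- read.delim(path,
    header = TRUE, sep = "\t", quote = "", comment.char = "",
    colClasses = "character", check.names = FALSE, fileEncoding = "UTF-8"
  )
  ids <- raw[[1]]
  prots <- names(raw)[-1]
  out <- tibble(compound_id = ids)
  for (j in seq_along(prots)) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell))
    if (length(bad) > 0) {
      abort(paste0(
        "non-numeric score '", cell[bad[1]], "' at row ", bad[1] + 1L,
        " (compound '", ids[bad[1]], "'), column '", prots[j], "'"
      ))
    }
    out[[prots[j]]] <- num
  }
  interaction_matrix(out)
}

#' @rdname read_interaction_matrix
#' @param x An `interaction_matrix`.
#' @export
write_interaction_matrix <- function(x, path) {
  x <- interaction_matrix(x)
  out <- data.frame(compound_id = x$compound_id, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (p in protein_ids(x)) out[[p]] <- sprintf("%.17g", x[[p]])
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("# Interaction matrix: ", nrow(x), " compounds x ",
      ncol(x) - 1L, " proteins\n", sep = "")
  NextMethod()
}
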