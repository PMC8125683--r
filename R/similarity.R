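#' Root-mean-square deviation between two proteome signatures
#'
#' The similarity measure underlying all rankings: for signatures `a` and
#' `b` over the same `P` proteins, `sqrt(mean((a - b)^2))`. Symmetric, zero
#' iff the signatures are identical. RMSD is computed on raw scores — no
#' normalization — because signatures are only ever compared within one
#' matrix, where all scores share a scale.
#'
#' @param a,b Numeric vectors of equal positive length.
#' @return A single non-negative number.
#' @examples
#' rmsd_similarity(c(0, 0), c(3, 4)) # sqrt(12.5)
#' @export
rmsd_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    abort(paste0("signature length mismatch: ", length(a), " vs ", length(b)))
  }
  if (length(a) == 0) abort("signatures need at least one protein")
  sqrt(mean((as.numeric(a) - as.numeric(b))^2))
}

#' Compute every compound's full similarity ranking
#'
#' Every signature is compared with every other signature by RMSD; for each
#' compound the remaining `N - 1` compounds are sorted most-similar first
#' (ascending RMSD). Ties are broken by compound id in C-locale byte order,
#' making the ranking deterministic across runs and platforms. The query
#' compound never appears in its own list: leave-one-out benchmarking ranks
#' each drug against the *other* compounds.
#'
#' @param x An `interaction_matrix` (or compatible data frame) with at least
#'   two compounds.
#' @return A `similarity_ranking` object. `tidy()` returns the long ranking
#'   table (`query_id`, `rank`, `other_id`, `rmsd`, with `rank` 1-based and
#'   `rmsd` non-decreasing within each query).
#' @examples
#' m <- interaction_matrix(matrix(c(0, 0, 5, 0, 1, 5), 3, 2,
#'   dimnames = list(c("D1", "D2", "D3"), c("P1", "P2"))))
#' rk <- compute_rankings(m)
#' rank_of(rk, "D1", "D2")
#' @export
compute_rankings <- function(x) {
  m <- as_score_matrix(x)
  n <- nrow(m)
  if (n < 2) abort("ranking needs at least two compounds")
  ids <- rownames(m)
  # Euclidean distance over proteins, rescaled to RMSD
  dmat <- as.matrix(dist(m, method = "euclidean")) / sqrt(ncol(m))
  rank_index <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  order_index <- matrix(NA_integer_, n, n - 1L)
  for (i in seq_len(n)) {
    others <- seq_len(n)[-i]
    o <- others[order(dmat[i, others], ids[others], method = "radix")]
    order_index[i, ] <- o
    rank_index[i, o] <- seq_len(n - 1L)
  }
  ranking <- tibble(
    query_id = rep(ids, each = n - 1L),
    rank = rep(seq_len(n - 1L), times = n),
    other_id = ids[as.vector(t(order_index))],
    rmsd = dmat[cbind(rep(seq_len(n), each = n - 1L), as.vector(t(order_index)))]
  )
  structure(
    list(
      compound_ids = ids,
      ranking = ranking,
      rank_index = rank_index,
      rmsd = dmat
    ),
    class = "similarity_ranking"
  )
}

#' @export
print.similarity_ranking <- function(x, ...) {
  cat("# Similarity ranking over ", length(x$compound_ids),
      " compounds (", nrow(x$ranking), " ordered pairs)\n", sep = "")
  print(x$ranking, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.similarity_ranking <- function(x, ...) x$ranking

#' Rank of one compound in another's similarity list
#'
#' @param table A `similarity_ranking`.
#' @param query,other Distinct compound ids present in the table.
#' @return Integer rank in `1..N-1`: the 1-based position of `other` in
#'   `query`'s most-similar-first list.
#' @export
rank_of <- function(table, query, other) {
  stopifnot(inherits(table, "similarity_ranking"))
  for (id in c(query, other)) {
    if (!id %in% table$compound_ids) abort(paste0("unknown compound id: ", id))
  }
  if (query == other) abort("a compound has no rank in its own list")
  table$rank_index[query, other]
}

#' Write a ranking table as TSV
#'
#' Columns `query_id<TAB>rank<TAB>other_id<TAB>rmsd`, one row per ordered
#' pair.
#'
#' @param table A `similarity_ranking`.
#' @param path Output path.
#' @export
write_rankings <- function(table, path) {
  stopifnot(inherits(table, "similarity_ranking"))
  out <- as.data.frame(table$ranking)
  out$rmsd <- sprintf("%.17g", out$rmsd)
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
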