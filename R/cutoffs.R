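#' Rank cutoff specifications
#'
#' Benchmark accuracy is evaluated at a grid of rank cutoffs: a co-approved
#' drug must appear within the top `k` most-similar compounds to count as
#' recovered. Cutoffs may be absolute ranks (top10, top25, ...) or fractions
#' of the compound library (top 1%, 5%, ...). Fractions resolve as
#' `floor(fraction * n_compounds)` — 1% of a 3733-compound library is rank
#' 37 — and every cutoff is clamped to `n_compounds - 1`, the length of a
#' compound's similarity list.
#'
#' @param absolute Integer vector of absolute rank cutoffs.
#' @param fractional Numeric vector of fractions in (0, 1].
#' @return A `cutoff_spec` object.
#' @examples
#' resolve_cutoffs(default_cutoffs(), 3733)
#' @export
cutoff_spec <- function(absolute = integer(), fractional = numeric()) {
  absolute <- as.integer(absolute)
  if (length(absolute) > 0 && any(absolute < 1)) {
    abort("absolute cutoffs must be positive integers")
  }
  fractional <- as.numeric(fractional)
  if (length(fractional) > 0 && any(fractional <= 0 | fractional > 1)) {
    abort("fractional cutoffs must lie in (0, 1]")
  }
  if (length(absolute) + length(fractional) == 0) {
    abort("at least one cutoff is required")
  }
  structure(list(absolute = absolute, fractional = fractional),
            class = "cutoff_spec")
}

#' @rdname cutoff_spec
#' @export
default_cutoffs <- function() {
  cutoff_spec(
    absolute = c(10L, 25L, 50L, 100L),
    fractional = c(0.01, 0.05, 0.10, 0.50)
  )
}

#' @rdname cutoff_spec
#' @param spec A `cutoff_spec`, or a vector of absolute ranks.
#' @param n_compounds Total size of the compound library.
#' @return `resolve_cutoffs()` returns a strictly positive, ascending,
#'   de-duplicated integer vector of ranks, each at most `n_compounds - 1`.
#' @export
resolve_cutoffs <- function(spec, n_compounds) {
  if (!inherits(spec, "cutoff_spec")) spec <- cutoff_spec(absolute = spec)
  n_compounds <- as.integer(n_compounds)
  if (n_compounds < 2) abort("n_compounds must be >= 2")
  k <- c(spec$absolute, as.integer(floor(spec$fractional * n_compounds)))
  if (any(k < 1)) {
    abort(paste0(
      "cutoff resolves below rank 1 for a library of ", n_compounds,
      " compounds"
    ))
  }
  k <- pmin(k, n_compounds - 1L)
  sort(unique(k))
}

#' Parse a cutoff grid from its command-line dialect
#'
#' A comma-separated list where a trailing `%` marks a fraction of the
#' library, e.g. `"10,25,1%,50,100,5%,10%,50%"`.
#'
#' @param text Cutoff string.
#' @return A `cutoff_spec`.
#' @export
parse_cutoffs <- function(text) {
  parts <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) abort("empty cutoff specification")
  frac <- grepl("%$", parts)
  abs_num <- suppressWarnings(as.numeric(parts[!frac]))
  frac_num <- suppressWarnings(as.numeric(sub("%$", "", parts[frac]))) / 100
  if (any(is.na(abs_num)) || any(is.na(frac_num))) {
    abort(paste0("unparseable cutoff in: ", text))
  }
  cutoff_spec(absolute = abs_num, fractional = frac_num)
}

#' @export
print.cutoff_spec <- function(x, ...) {
  cat("Cutoff spec: absolute [", paste(x$absolute, collapse = ", "),
      "], fractional [", paste(x$fractional, collapse = ", "), "]\n", sep = "")
  invisible(x)
}
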