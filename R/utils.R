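#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Canonical mutation identity keys
#'
#' Mutations are identified by the tuple (chrom, pos, ref, alt); gene and
#' effect annotations are carried alongside but never enter set algebra.
#'
#' @param calls data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return character vector of keys, one per row.
#' @export
mutation_key <- function(calls) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(calls)))
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Convert between 1-based variant and 0-based half-open interval coordinates
#'
#' Variant positions follow the VCF convention (1-based); copy-number segment
#' intervals follow the BED convention (0-based, half-open). These helpers make
#' the conversion explicit at module boundaries.
#'
#' @param pos 1-based position(s).
#' @param start0 0-based half-open interval start(s).
#' @return `pos_to_interval()` returns a data frame with `start` and `end`
#'   (0-based half-open, length 1); `interval_start_to_pos()` returns 1-based
#'   positions.
#' @export
pos_to_interval <- function(pos) {
  stopifnot(is.numeric(pos), all(pos >= 1))
  data.frame(start = pos - 1, end = pos)
}

#' @rdname pos_to_interval
#' @export
interval_start_to_pos <- function(start0) {
  stopifnot(is.numeric(start0), all(start0 >= 0))
  start0 + 1
}

# Sample an integer from a scalar or an inclusive (min, max) range.
draw_count <- function(x, n = 1L) {
  if (length(x) == 1L) rep(as.integer(x), n)
  else sample(seq.int(x[1], x[2]), n, replace = TRUE)
}

# semicolon-joined rule list -> character scalar ("" when retained)
join_rules <- function(rules) {
  if (length(rules) == 0L) "" else paste(rules, collapse = ";")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
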