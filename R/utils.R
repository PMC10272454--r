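# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' seeded operations do not perturb the global random stream.
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Column medians of a matrix with few rows
#'
#' Vectorised median over the first margin: one radix sort of the whole
#' matrix instead of one `median()` call per column. Intended for the
#' trials-by-cells matrices of the robust normalisation, where the number of
#' rows (trials) is small and the number of columns is in the millions.
#' NAs are not handled; callers must mask them first.
#' @param m numeric matrix.
#' @return numeric vector of length `ncol(m)`.
#' @keywords internal
col_medians <- function(m) {
  n <- nrow(m)
  p <- ncol(m)
  if (n == 1L) return(as.vector(m))
  h <- (n + 1L) %/% 2L
  if (n <= 64L) {
    # wide-and-short: one radix sort of the whole matrix
    o <- order(rep.int(seq_len(p), rep.int(n, p)), m, method = "radix")
    s <- matrix(m[o], n, p)
    if (n %% 2L == 1L) return(s[h, ])
    return((s[h, ] + s[h + 1L, ]) / 2)
  }
  # tall: partial sort per column
  vapply(seq_len(p), function(j) {
    x <- sort(m[, j], partial = c(h, h + 1L))
    if (n %% 2L == 1L) x[h] else (x[h] + x[h + 1L]) / 2
  }, 1)
}

# Symmetric Hann taper of length n (same convention as signal::hanning).
hann_taper <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tex <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "texchange_error")))
}
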