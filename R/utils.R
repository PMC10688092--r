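# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded operations do not perturb the global random stream. With
#' `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(eval.parent(substitute(expr)))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# stopifnot with a readable message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_autosome <- function(chrom) {
  !sub("^chr", "", chrom) %in% c("X", "Y", "M", "MT")
}

# lower median: for even n returns the n/2-th order statistic, keeping
# integer-valued inputs integral
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

# length-weighted median of per-interval values
weighted_median <- function(x, w) {
  ok <- !is.na(x) & w > 0
  x <- x[ok]
  w <- w[ok]
  if (length(x) == 0L) return(NA_real_)
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

# total base-pair overlap of [s1,e1) with [s2,e2)
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
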