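#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the previous RNG state afterwards so that seeded package
#' functions do not disturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# sign with sgn(0) = +1, so square waves are two-valued even at
# sampling boundaries
sgn <- function(x) ifelse(x >= 0, 1, -1)

#' Median absolute deviation without consistency scaling
#'
#' Raw MAD (`median(|x - median(x)|)`), used throughout the response
#' detection rules. No normal-consistency factor is applied: thresholds
#' are expressed as multiples of the raw MAD.
#'
#' @param x Numeric vector.
#' @return Scalar raw MAD.
#' @export
mad_raw <- function(x) stats::median(abs(x - stats::median(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
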