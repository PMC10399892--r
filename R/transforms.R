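#' Standard normal CDF (probit squashing function)
#'
#' The squashing function used to map unbounded sampled parameters into their
#' natural bounds. This is the cumulative distribution function of the
#' standard normal.
#'
#' @param x numeric vector of unbounded values.
#' @return values in (0, 1).
#' @export
#' @examples
#' phi(0)            # 0.5
#' phi(1.959964)     # ~0.975
phi <- function(x) pnorm(x)

#' Map an unbounded parameter to a bounded natural scale
#'
#' Computes `lo + phi(raw) * (hi - lo)`: the probit transform used for every
#' bounded model parameter (learning rates on \[0, 1\], inverse temperature on
#' \[0, 20\], initial expectation Q0 on the condition's outcome range).
#'
#' @param raw unbounded numeric vector.
#' @param lo,hi bounds, `lo < hi`.
#' @return values in (lo, hi).
#' @seealso [to_raw()] for the inverse.
#' @export
to_natural <- function(raw, lo, hi) {
  if (any(lo >= hi)) stop("`lo` must be strictly below `hi`")
  lo + phi(raw) * (hi - lo)
}

#' Inverse of [to_natural()]
#'
#' @param x values in (lo, hi).
#' @inheritParams to_natural
#' @return unbounded values mapping back to `x` under [to_natural()].
#' @export
to_raw <- function(x, lo, hi) {
  if (any(lo >= hi)) stop("`lo` must be strictly below `hi`")
  qnorm((x - lo) / (hi - lo))
}

#' Negative learning rate from the asymmetry offset
#'
#' The negative learning rate is parameterized as
#' `alpha_n = phi(alpha_p_raw + offset)`, so that the offset directly encodes
#' the learning asymmetry on the transformed scale: offset 0 recovers the
#' symmetric model, a positive offset means `alpha_n > alpha_p`.
#'
#' @param alpha_p_raw unbounded positive-learning-rate parameter.
#' @param offset unbounded asymmetry offset.
#' @return negative learning rate in (0, 1).
#' @export
neg_lr_from_offset <- function(alpha_p_raw, offset) phi(alpha_p_raw + offset)

#' Trimmed mean point estimate
#'
#' Drops `floor(trim * n)` smallest and largest values and averages the rest;
#' the robust point estimate used to summarize posterior draws (default 10%
#' from each tail).
#'
#' @param x numeric vector of draws.
#' @param trim fraction in \[0, 0.5) to drop from each side.
#' @return the trimmed mean.
#' @export
#' @examples
#' trimmed_mean(1:10, 0.10)  # mean of 2:9 = 5.5
trimmed_mean <- function(x, trim = 0.10) {
  if (length(x) == 0) stop("empty sample")
  if (trim < 0 || trim >= 0.5) stop("`trim` must lie in [0, 0.5)")
  n <- length(x)
  k <- floor(trim * n)
  if (k == 0) return(mean(x))
  xs <- sort(x)
  mean(xs[(k + 1):(n - k)])
}
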