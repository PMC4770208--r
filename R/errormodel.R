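#' Convert Phred scores to error probabilities
#'
#' A Phred score `q` encodes a base-call error probability
#' `p = 10^(-q/10)`: q = 20 means 1 error in 100 calls.
#'
#' @param q Integer Phred score(s), `>= 0`.
#' @return Numeric vector of error probabilities.
#' @examples
#' phred_to_prob(c(0, 20, 30))  # 1, 0.01, 0.001
#' @export
phred_to_prob <- function(q) {
  if (length(q) && (anyNA(q) || any(q < 0)))
    stop("Phred scores must be non-negative")
  10^(-as.numeric(q) / 10)
}

.check_probs <- function(probs) {
  probs <- as.numeric(probs)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("per-base error probabilities must lie in [0, 1]")
  probs
}

.new_error_distribution <- function(probs, n_bases) {
  structure(list(probs = probs,
                 cumulative = cumsum(probs),
                 j_cap = length(probs) - 1L,
                 n_bases = n_bases),
            class = "error_distribution")
}

#' Exact error-count distribution of a read
#'
#' The number of wrong bases in a read of length `N` is the sum of `N`
#' independent Bernoulli variables with success probabilities
#' `p_1, ..., p_N` -- a Poisson binomial variable `S_N`.  Its pmf is
#' computed exactly by iterated convolution; since each Bernoulli variable
#' takes only the values 0 and 1, each convolution step is
#' `new[j] = old[j] * (1 - p_i) + old[j - 1] * p_i`.  Terms above `j_cap`
#' are never computed, so the cost is `O(N * j_cap)`.
#'
#' @param probs Per-base error probabilities in `[0, 1]` (see
#'   [phred_to_prob()]).
#' @param j_cap Largest error count to compute; defaults to the full
#'   support `length(probs)`.
#' @return An object of class `error_distribution` with fields `probs`
#'   (`P(S_N = j)` for `j = 0..j_cap`), `cumulative`, `j_cap` and `n_bases`.
#' @examples
#' d <- error_distribution(c(0.1, 0.2, 0.3))
#' d$probs  # 0.504 0.398 0.092 0.006
#' @export
error_distribution <- function(probs, j_cap = length(probs)) {
  probs <- .check_probs(probs)
  j_cap <- as.integer(j_cap)
  if (j_cap < 0L || j_cap > length(probs))
    stop("j_cap must lie in [0, length(probs)]")
  .new_error_distribution(.pbf_distribution(probs, j_cap), length(probs))
}

#' @export
print.error_distribution <- function(x, digits = 4, ...) {
  cat("<error_distribution> read of ", x$n_bases, " bases, terms j = 0..",
      x$j_cap, "\n", sep = "")
  m <- rbind(`P(S_N = j)` = x$probs, cumulative = x$cumulative)
  colnames(m) <- seq_len(x$j_cap + 1L) - 1L
  print(round(m, digits), ...)
  invisible(x)
}

#' Predicted maximum errors of a read
#'
#' Grows the exact error-count distribution term by term,
#' `j = 0, 1, 2, ...`, and stops at the first `j_max` whose cumulative
#' probability reaches the confidence level `xi`; terms beyond `j_max` are
#' never computed.  The quantile is then linearly interpolated between the
#' last two accumulated values,
#' \deqn{j_\xi = j_{max} - 1 + \frac{\xi - \sum_{r < j_{max}} P(S_N = r)}
#'       {P(S_N = j_{max})},}
#' and clamped below at 0 (a negative predicted error count, possible when
#' `P(S_N = 0) >= xi`, is meaningless).  The stopping rule is inclusive: a
#' cumulative sum exactly equal to `xi` stops at that `j`.
#'
#' `j_xi` is the read's "predicted maximum number of errors": on the
#' interpolated cumulative curve the read has probability `xi` of carrying
#' fewer errors.  Note that for integer-valued true error counts the strict
#' guarantee holds at the integer stopping point, `P(true > j_max) <= 1 -
#' xi`, not at the interpolated value; see the package vignette.
#'
#' @param probs Per-base error probabilities.
#' @param xi Confidence level in (0, 1); the filter default is 0.995,
#'   i.e. alpha = 1 - xi = 0.005.
#' @return A single number `j_xi >= 0`.
#' @examples
#' predicted_max_errors(c(0.1, 0.2, 0.3), 0.995)  # 2.1667
#' @export
predicted_max_errors <- function(probs, xi = 0.995) {
  probs <- .check_probs(probs)
  if (length(probs) == 0L) stop("probs must be non-empty")
  .pbf_jxi(probs, xi)$jxi
}

#' Expected error count of a read
#'
#' The sum of the per-base error probabilities, `lambda = sum(p_i)`.  This
#' is both the expected number of errors and the rate of the Poisson
#' approximation to the error-count distribution.
#'
#' @inheritParams predicted_max_errors
#' @return A single non-negative number.
#' @examples
#' poisson_lambda(rep(0.01, 250))  # 2.5
#' @export
poisson_lambda <- function(probs) {
  sum(.check_probs(probs))
}

#' Poisson-approximated predicted maximum errors
#'
#' Same stopping-and-interpolation rule as [predicted_max_errors()] but
#' with Poisson pmf terms `P(S_N = j) = lambda^j exp(-lambda) / j!`,
#' `lambda = sum(p_i)`.  The approximation is accurate when `N` is large
#' and every `p_i` is small; it can fail even for high-quality reads that
#' contain one or more low-quality bases, because a single large `p_i`
#' breaks the small-probability assumption.
#'
#' @inheritParams predicted_max_errors
#' @return A single number `j_xi >= 0`.
#' @export
poisson_predicted_max_errors <- function(probs, xi = 0.995) {
  probs <- .check_probs(probs)
  if (length(probs) == 0L) stop("probs must be non-empty")
  if (!(xi > 0 && xi < 1)) stop("xi must lie in (0, 1)")
  lambda <- sum(probs)
  if (exp(-lambda) > 0) {
    # grow Poisson pmf terms by the recurrence P(j) = P(j-1) * lambda / j
    pj <- exp(-lambda)
    cum <- pj
    j <- 0L
    while (cum < xi) {
      j <- j + 1L
      pj <- pj * lambda / j
      cum <- cum + pj
    }
  } else {
    # extreme lambda: P(0) underflows, so evaluate each term in log space;
    # early terms contribute nothing and the cumulative fills in near the mode
    j <- 0L
    pj <- 0
    cum <- 0
    while (cum < xi) {
      pj <- exp(j * log(lambda) - lambda - lgamma(j + 1))
      cum <- cum + pj
      if (cum >= xi) break
      j <- j + 1L
    }
  }
  if (pj <= 0) return(as.numeric(j))
  max(0, j - 1 + (xi - (cum - pj)) / pj)
}

#' Brute-force error-count distribution (test oracle)
#'
#' Enumerates all `2^N` error patterns of a read and accumulates the exact
#' probability of each, giving the Poisson binomial pmf with no recursion.
#' Exponential cost restricts it to `N <= 15`; it exists as an independent
#' oracle against which the convolution is verified.
#'
#' @inheritParams predicted_max_errors
#' @return An `error_distribution` over the full support `0..N`.
#' @export
brute_force_distribution <- function(probs) {
  probs <- .check_probs(probs)
  n <- length(probs)
  if (n > 15L) stop("brute-force enumeration refuses N > 15")
  out <- numeric(n + 1L)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask)[seq_len(max(n, 1L))])
    if (n == 0L) bits <- integer(0)
    pr <- prod(ifelse(bits == 1L, probs, 1 - probs))
    j <- sum(bits)
    out[j + 1L] <- out[j + 1L] + pr
  }
  .new_error_distribution(out, n)
}
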