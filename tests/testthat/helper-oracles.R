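# Independent oracles used across the suite.  None of these share code with
# the implementation paths they check.

# random per-base error probability vector, mixing clean and noisy bases
random_probs <- function(n) {
  p <- 10^runif(n, -5, 0)
  noisy <- runif(n) < 0.2
  p[noisy] <- runif(sum(noisy))
  p
}

# Poisson-side quantile oracle built on R's closed-form Poisson cdf/pmf,
# independent of the package's term-by-term recurrence
poisson_jxi_oracle <- function(lambda, xi = 0.995) {
  j_max <- 0
  while (ppois(j_max, lambda) < xi) j_max <- j_max + 1
  if (j_max == 0) {
    return(max(0, -1 + xi / dpois(0, lambda)))
  }
  max(0, j_max - 1 + (xi - ppois(j_max - 1, lambda)) / dpois(j_max, lambda))
}

# Exhaustive free-end-gap alignment oracle.  Every global alignment with
# linear gap costs corresponds to a monotone matching between positions of
# the two sequences.  Unmatched characters strictly between the first and
# last matched pair (in each sequence's own coordinates) are interior gaps
# and are penalised.  At each alignment end only one sequence's overhang can
# sit at the boundary (free); the other end-run is a penalised gap run, so
# the cheaper assignment is min(len1, len2) penalised gap columns per end.
# The optimum is the maximum over all matchings, including the empty one
# (the two sequences slide past each other, score 0).
overlap_score_oracle <- function(s1, s2, match = 1, mismatch = -1, gap = -2) {
  c1 <- strsplit(s1, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  m <- length(c1); n <- length(c2)
  best <- 0  # empty matching: everything end-gapped
  for (k in seq_len(min(m, n))) {
    I <- utils::combn(m, k)
    J <- utils::combn(n, k)
    for (a in seq_len(ncol(I))) {
      ii <- I[, a]
      subs_i <- c1[ii]
      for (b in seq_len(ncol(J))) {
        jj <- J[, b]
        interior <- (ii[k] - ii[1] + 1 - k) + (jj[k] - jj[1] + 1 - k)
        ends <- min(ii[1] - 1, jj[1] - 1) + min(m - ii[k], n - jj[k])
        sc <- sum(ifelse(subs_i == c2[jj], match, mismatch)) +
          gap * (interior + ends)
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# convenience builders
make_read <- function(id, seq, q) quality_read(id, seq, rep_len(q, nchar(seq)))

random_read <- function(id, len, qmin = 10, qmax = 40) {
  quality_read(id,
               paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
               sample(qmin:qmax, len, TRUE))
}
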