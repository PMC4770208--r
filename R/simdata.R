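# Calibrated read simulator: emitted quality strings are, by construction,
# exact descriptions of the substitution process that generated the read,
# which is what makes the alpha-calibration of j_xi testable without any
# reference dataset.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

.BASES <- c("A", "C", "G", "T")

#' Random reference templates
#'
#' Uniform random sequences over `{A,C,G,T}`, used as the "true" biological
#' sequences a simulated community is read from.
#'
#' @param k Number of templates.
#' @param len Template length(s); recycled to `k`.
#' @param seed Integer seed.
#' @return Named character vector (`t1`, `t2`, ...).
#' @export
random_templates <- function(k, len, seed = 1) {
  len <- rep_len(as.integer(len), k)
  .with_seed(seed, {
    setNames(vapply(seq_len(k), function(i)
      paste(sample(.BASES, len[i], replace = TRUE), collapse = ""),
      character(1)), paste0("t", seq_len(k)))
  })
}

#' Quality profiles
#'
#' A quality profile is a function `f(len)` returning one integer Phred
#' vector of that length per call.  Two shapes are provided:
#' `qprofile_constant` emits a flat score, and `qprofile_decay` emits a
#' linear 5'-to-3' decline (the classic 454/IonTorrent shape) with optional
#' Gaussian jitter per base and an optional Gaussian offset drawn once per
#' read (whole reads genuinely differ in quality on real machines), rounded
#' and clipped to `[0, 93]`.
#'
#' @param q Constant Phred score.
#' @param q5,q3 Scores at the 5' and 3' ends of the decay profile.
#' @param jitter_sd Standard deviation of per-base jitter (0 for none).
#' @param shift_sd Standard deviation of the per-read offset (0 for none).
#' @return A function of class `qprofile`.
#' @examples
#' prof <- qprofile_decay(38, 15)
#' prof(10)
#' @export
qprofile_constant <- function(q) {
  q <- as.integer(q)
  stopifnot(q >= 0L, q <= 93L)
  structure(function(len) rep(q, len), class = "qprofile")
}

#' @rdname qprofile_constant
#' @export
qprofile_decay <- function(q5 = 38, q3 = 15, jitter_sd = 0, shift_sd = 0) {
  stopifnot(q5 >= 0, q5 <= 93, q3 >= 0, q3 <= 93,
            jitter_sd >= 0, shift_sd >= 0)
  structure(function(len) {
    base <- if (len == 1L) q5 else seq(q5, q3, length.out = len)
    if (shift_sd > 0) base <- base + rnorm(1, 0, shift_sd)
    if (jitter_sd > 0) base <- base + rnorm(len, 0, jitter_sd)
    pmin(93L, pmax(0L, as.integer(round(base))))
  }, class = "qprofile")
}

.simulate_one <- function(template, qs) {
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  p <- phred_to_prob(qs)
  err <- which(runif(length(p)) < p)
  for (i in err) {
    chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  }
  list(chars = chars, err = err)
}

#' Simulate calibrated reads
#'
#' For each read: a template is drawn uniformly, a quality string is drawn
#' from the profile, and every base is then flipped -- independently, to a
#' uniformly chosen different base -- with probability
#' `phred_to_prob(q_i)`.  The emitted quality scores therefore describe the
#' true error process exactly, so downstream calibration checks of the
#' error model are checks of the model alone, not of the data.  Errors are
#' substitutions only; indel realism belongs to platform simulators.
#'
#' @param templates Character vector of template sequences (named or not).
#' @param n Number of reads.
#' @param profile A [qprofile_constant()] / [qprofile_decay()] function.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return List of `simulated_read` objects: `read` (a [quality_read()]),
#'   `template_id`, `true_errors` and `error_positions` (1-based).
#' @export
simulate_reads <- function(templates, n, profile, seed = 1) {
  stopifnot(length(templates) > 0L, n > 0L, is.function(profile))
  if (is.null(names(templates)))
    names(templates) <- paste0("t", seq_along(templates))
  .with_seed(seed, {
    tpl_idx <- sample.int(length(templates), n, replace = TRUE)
    lapply(seq_len(n), function(k) {
      tpl <- templates[[tpl_idx[k]]]
      qs <- profile(nchar(tpl))
      if (length(qs) != nchar(tpl) || anyNA(qs) || any(qs < 0L | qs > 93L))
        stop("invalid quality profile output for length ", nchar(tpl))
      sim <- .simulate_one(tpl, qs)
      structure(list(
        read = quality_read(sprintf("sim%06d", k),
                            paste(sim$chars, collapse = ""), qs),
        template_id = names(templates)[tpl_idx[k]],
        true_errors = length(sim$err),
        error_positions = sim$err
      ), class = "simulated_read")
    })
  })
}

#' Simulate a mate pair with known truth
#'
#' Emits a forward read covering the first `read_len` template bases and a
#' reverse-strand mate whose reverse complement covers a window overlapping
#' the forward read by exactly `overlap` bases; the error process is the
#' one in [simulate_reads()].  The merged span covers
#' `2 * read_len - overlap` template bases.
#'
#' @param template Template sequence.
#' @param read_len Length of each mate.
#' @param overlap Overlap between the forward read and the
#'   reverse-complemented mate, `0 < overlap <= read_len`.
#' @param profile Quality profile.
#' @param seed Integer seed.
#' @return A list: `fwd` and `rev` ([quality_read()]s as they would come
#'   off the machine), `span` (the true merged template region), and
#'   `truth` (per-mate error counts/positions in template coordinates).
#' @export
simulate_pair <- function(template, read_len, overlap, profile, seed = 1) {
  L <- nchar(template)
  stopifnot(overlap > 0L, overlap <= read_len)
  span_len <- 2L * read_len - overlap
  if (read_len > L || span_len > L)
    stop("template too short: need ", span_len, " bases, have ", L)
  .with_seed(seed, {
    fwd_tpl <- substr(template, 1L, read_len)
    rev_start <- read_len - overlap + 1L
    rev_tpl <- substr(template, rev_start, rev_start + read_len - 1L)

    qs_f <- profile(read_len)
    sim_f <- .simulate_one(fwd_tpl, qs_f)
    qs_r <- profile(read_len)
    sim_r <- .simulate_one(rev_tpl, qs_r)

    fwd <- quality_read("pair/1", paste(sim_f$chars, collapse = ""), qs_f)
    plus <- quality_read("pair/2", paste(sim_r$chars, collapse = ""), qs_r)
    list(fwd = fwd,
         rev = reverse_complement(plus),
         span = substr(template, 1L, span_len),
         truth = list(fwd_errors = sim_f$err,
                      rev_errors = sim_r$err + rev_start - 1L))
  })
}

#' Simulate a two-taxon community with taxon-correlated quality
#'
#' Reads from two templates ("taxa") are generated with different quality
#' profiles, reproducing the situation where sequence composition and
#' read quality are correlated.  Naive per-read filtering then discards
#' taxa unevenly; collapsing identical reads first and filtering by the
#' best member mitigates that bias.
#'
#' @param n_per_taxon Reads per taxon.
#' @param len Template length.
#' @param profile_a,profile_b Quality profile for each taxon.
#' @param seed Integer seed.
#' @return List of `simulated_read` objects (taxa interleaved by
#'   concatenation; `template_id` is `"taxonA"` or `"taxonB"`).
#' @export
simulate_two_taxon <- function(n_per_taxon, len = 250,
                               profile_a = qprofile_constant(38),
                               profile_b = qprofile_decay(35, 18, shift_sd = 6),
                               seed = 1) {
  tpl <- random_templates(2, len, seed = seed)
  names(tpl) <- c("taxonA", "taxonB")
  a <- simulate_reads(tpl["taxonA"], n_per_taxon, profile_a, seed = seed + 1L)
  b <- simulate_reads(tpl["taxonB"], n_per_taxon, profile_b, seed = seed + 2L)
  for (k in seq_along(b))
    b[[k]]$read$id <- sprintf("simB%05d", k)
  c(a, b)
}

#' Write the truth table of a simulation
#'
#' Tab-separated companion to the simulated FASTQ: id, template id, true
#' error count, and comma-separated 1-based error positions.
#'
#' @param sims List of `simulated_read` objects.
#' @param path Output file.
#' @export
write_truth <- function(sims, path) {
  df <- data.frame(
    id = vapply(sims, function(s) s$read$id, character(1)),
    template_id = vapply(sims, `[[`, character(1), "template_id"),
    true_errors = vapply(sims, `[[`, integer(1), "true_errors"),
    positions = vapply(sims, function(s)
      paste(s$error_positions, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
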