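#' Filtering parameters
#'
#' Collects the tunable parameters of the filtering pipeline.
#'
#' @param alpha Accepted probability of underestimating a read's errors;
#'   the confidence level of the quantile is `xi = 1 - alpha`.  Default
#'   0.005 (`xi = 0.995`).
#' @param uncert Tolerated errors per nucleotide; the per-read tolerance is
#'   `j_tol = uncert * L` with `L` the trimmed read length.  Default 0.01.
#' @param trunc_len Fixed truncation length in nucleotides, or `NULL` to
#'   skip truncation (the tolerance then uses each read's own length).
#' @param paired If `TRUE`, input is a mate pair of FASTQ files and contigs
#'   are assembled first.
#' @param collapse If `TRUE` (default), identical sequences are collapsed
#'   before filtering and judged by their best member.
#' @param use_poisson_approx If `TRUE`, the Poisson approximation replaces
#'   the exact Poisson binomial quantile.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(alpha = 0.005, uncert = 0.01, trunc_len = NULL,
                          paired = FALSE, collapse = TRUE,
                          use_poisson_approx = FALSE) {
  stopifnot(alpha > 0, alpha < 1, uncert >= 0, uncert <= 1)
  if (!is.null(trunc_len)) {
    trunc_len <- as.integer(trunc_len)
    stopifnot(trunc_len > 0L)
  }
  structure(list(alpha = alpha, xi = 1 - alpha, uncert = uncert,
                 trunc_len = trunc_len, paired = isTRUE(paired),
                 collapse = isTRUE(collapse),
                 use_poisson_approx = isTRUE(use_poisson_approx)),
            class = "filter_params")
}

#' Truncate a read to a fixed length
#'
#' Reads of length at least `L` are cut to their first `L` bases; shorter
#' reads are signalled as discarded by returning `NULL`.
#'
#' @param read A [quality_read()].
#' @param L Truncation length, `> 0`.
#' @return A `quality_read` of length `L`, or `NULL` when the read is
#'   shorter than `L`.
#' @export
truncate_read <- function(read, L) {
  stopifnot(inherits(read, "quality_read"), L > 0)
  n <- nchar(read$sequence)
  if (n < L) return(NULL)
  if (n == L) return(read)
  quality_read(read$id, substr(read$sequence, 1L, L), read$quals[seq_len(L)])
}

#' Per-read error tolerance
#'
#' The maximum tolerable number of errors per read, `j_tol = uncert * L`,
#' kept as a real number (not rounded).  With the default `uncert = 0.01`
#' this is 1 percent of the trimmed length: 2.5 errors at `L = 250`, 2 at
#' `L = 200`.
#'
#' @param L Trimmed read length, `> 0`.
#' @param uncert Tolerated errors per nucleotide in `[0, 1]`.
#' @return A non-negative number.
#' @examples
#' compute_jtol(250, 0.01)  # 2.5
#' @export
compute_jtol <- function(L, uncert) {
  stopifnot(L > 0, uncert >= 0, uncert <= 1)
  uncert * L
}

#' Collapse identical sequences
#'
#' Dereplication by exact string identity.  Within each group the member
#' with the smallest predicted maximum errors becomes the representative
#' (ties broken by input order), so a group is later judged by its best
#' evidence: identical sequences almost surely share a biological origin,
#' and one high-quality observation vouches for the rest.  Groups are
#' ordered by descending multiplicity, then lexicographically by sequence.
#'
#' @param reads List of [quality_read()] objects.
#' @param jxi Numeric vector of predicted maximum errors, parallel to
#'   `reads` (see [predicted_max_errors()]).
#' @return List of `collapsed_group` objects with fields `sequence`,
#'   `members` (ids in input order), `representative` and `rep_jxi`.
#' @export
collapse_reads <- function(reads, jxi) {
  stopifnot(length(reads) == length(jxi))
  if (length(reads) == 0L) return(list())
  seqs <- vapply(reads, `[[`, character(1), "sequence")
  ids <- vapply(reads, `[[`, character(1), "id")
  idx <- split(seq_along(reads), factor(seqs, levels = unique(seqs)))
  groups <- lapply(idx, function(ii) {
    best <- ii[which.min(jxi[ii])]
    structure(list(sequence = seqs[[ii[1L]]],
                   members = ids[ii],
                   representative = ids[[best]],
                   rep_jxi = jxi[[best]]),
              class = "collapsed_group")
  })
  groups <- unname(groups)
  sizes <- vapply(groups, function(g) length(g$members), integer(1))
  keys <- vapply(groups, `[[`, character(1), "sequence")
  groups[order(-sizes, keys, method = "radix")]
}

#' Filter collapsed groups against the error tolerance
#'
#' A group -- and with it every member read -- is kept when the predicted
#' maximum errors of its representative do not exceed the tolerance:
#' `rep_jxi <= j_tol`.  The discard rule is strict (`rep_jxi > j_tol`
#' discards), so a group sitting exactly on the tolerance is kept.
#'
#' @param groups List of groups from [collapse_reads()].
#' @param j_tol Tolerance, a non-negative number; recycled if a vector of
#'   per-group tolerances is given.
#' @return A list with components `kept` and `discarded`, each a list of
#'   groups.
#' @export
filter_reads <- function(groups, j_tol) {
  stopifnot(all(j_tol >= 0))
  j_tol <- rep_len(j_tol, length(groups))
  keep <- vapply(seq_along(groups), function(k) groups[[k]]$rep_jxi <= j_tol[k],
                 logical(1))
  list(kept = groups[keep], discarded = groups[!keep])
}

#' Run the filtering pipeline
#'
#' Executes the stages in fixed order: (1) contig assembly when `paired`,
#' (2) fixed-length truncation, (3) per-read predicted maximum errors at
#' confidence `1 - alpha`, (4) collapsing of identical sequences, then
#' filtering of the (collapsed) reads against `j_tol = uncert * L`.
#' Collapsing before filtering is deliberate: it lets one good copy rescue
#' lower-quality duplicates, which mitigates taxon-correlated quality bias.
#'
#' @param input Path to a FASTQ file (single mode), the forward FASTQ
#'   (paired mode), or a FASTA file (with `qual`).
#' @param input2 Reverse-mate FASTQ in paired mode; mates are matched by
#'   file order.
#' @param qual Companion `.qual` file when `input` is FASTA.
#' @param params A [filter_params()] object.
#' @param assembly An [assembly_params()] object (paired mode).
#' @param output_prefix Prefix for output files; `NULL` suppresses file
#'   output.  Written artifacts: `<prefix>.good.fastq`,
#'   `<prefix>.bad.fastq` (discard reason appended to the header),
#'   `<prefix>.names` (collapse mode) and `<prefix>.report.tsv`.
#' @param offset FASTQ quality offset (33 or 64).
#' @param verbose Print stage-by-stage counts.
#' @return An object of class `pbf_report`: `reads` (per-read data frame
#'   with id, length, expected errors `lambda`, `jxi`, representative,
#'   decision and reason) and `summary` (input / short / kept / discarded
#'   counts, plus the parameters used).
#' @examples
#' fq <- system.file("extdata", "synthetic_mix.fastq", package = "pbfilter")
#' rep <- run_pipeline(fq, params = filter_params(trunc_len = 80),
#'                     verbose = FALSE)
#' rep
#' @export
run_pipeline <- function(input, input2 = NULL, qual = NULL,
                         params = filter_params(),
                         assembly = assembly_params(),
                         output_prefix = NULL, offset = 33,
                         verbose = TRUE) {
  stopifnot(inherits(params, "filter_params"))
  say <- function(...) if (verbose) message(...)

  # stage 1: input (+ assembly)
  if (params$paired) {
    if (is.null(input2)) stop("assembly stage: paired mode needs two mate files")
    fwd <- read_fastq(input, offset)
    rev <- read_fastq(input2, offset)
    if (length(fwd) != length(rev))
      stop("assembly stage: mate files differ in read count (",
           length(fwd), " vs ", length(rev), ")")
    reads <- lapply(seq_along(fwd), function(k)
      make_contig(fwd[[k]], rev[[k]], assembly)$read)
    say("assembled ", length(reads), " contigs")
  } else if (!is.null(qual)) {
    reads <- read_fasta_qual(input, qual)
    say("read ", length(reads), " reads (FASTA + qual)")
  } else {
    reads <- read_fastq(input, offset)
    say("read ", length(reads), " reads")
  }
  n_input <- length(reads)

  # stage 2: truncation
  short <- list()
  if (!is.null(params$trunc_len)) {
    trunc <- lapply(reads, truncate_read, L = params$trunc_len)
    is_short <- vapply(trunc, is.null, logical(1))
    short <- reads[is_short]
    reads <- trunc[!is_short]
    say("truncated to ", params$trunc_len, " nt; ", length(short),
        " reads too short")
  }

  # stage 3: predicted maximum errors
  jxi_fun <- if (params$use_poisson_approx) poisson_predicted_max_errors
             else predicted_max_errors
  lambda <- numeric(length(reads))
  jxi <- numeric(length(reads))
  for (k in seq_along(reads)) {
    p <- phred_to_prob(reads[[k]]$quals)
    lambda[k] <- sum(p)
    jxi[k] <- jxi_fun(p, params$xi)
  }

  # stage 4: collapsing, then filtering
  if (params$collapse) {
    groups <- collapse_reads(reads, jxi)
  } else {
    # no collapsing: one group per read, original order
    groups <- lapply(seq_along(reads), function(k)
      structure(list(sequence = reads[[k]]$sequence,
                     members = reads[[k]]$id,
                     representative = reads[[k]]$id,
                     rep_jxi = jxi[k]),
                class = "collapsed_group"))
  }
  say(length(groups), " groups after ",
      if (params$collapse) "collapsing" else "no collapsing")
  jtol <- vapply(groups, function(g)
    compute_jtol(nchar(g$sequence), params$uncert), numeric(1))
  split_groups <- filter_reads(groups, jtol)

  kept_ids <- unlist(lapply(split_groups$kept, `[[`, "members"),
                     use.names = FALSE)
  ids <- vapply(reads, `[[`, character(1), "id")
  rep_of <- character(length(reads))
  names(rep_of) <- ids
  for (g in groups) rep_of[g$members] <- g$representative
  kept <- ids %in% kept_ids

  report <- data.frame(
    id = c(ids, vapply(short, `[[`, character(1), "id")),
    length = c(vapply(reads, function(r) nchar(r$sequence), integer(1)),
               vapply(short, function(r) nchar(r$sequence), integer(1))),
    lambda = c(lambda, rep(NA_real_, length(short))),
    jxi = c(jxi, rep(NA_real_, length(short))),
    representative = c(unname(rep_of), rep(NA_character_, length(short))),
    kept = c(kept, rep(FALSE, length(short))),
    reason = c(ifelse(kept, "", "quality"), rep("short", length(short))),
    stringsAsFactors = FALSE
  )
  summary <- list(input = n_input, short = length(short),
                  kept = sum(kept), discarded = sum(!kept),
                  params = params)
  stopifnot(summary$input == summary$kept + summary$discarded + summary$short)
  say("kept ", summary$kept, " / ", n_input, " reads")
  if (summary$kept == 0L && n_input > 0L)
    warning("no reads survived filtering")

  if (!is.null(output_prefix)) {
    by_id <- setNames(reads, ids)
    write_fastq(by_id[ids[kept]], paste0(output_prefix, ".good.fastq"), offset)
    bad <- c(lapply(by_id[ids[!kept]], function(r)
               quality_read(paste0(r$id, "|quality"), r$sequence, r$quals)),
             lapply(short, function(r)
               quality_read(paste0(r$id, "|short"), r$sequence, r$quals)))
    write_fastq(bad, paste0(output_prefix, ".bad.fastq"), offset)
    if (params$collapse)
      write_names(split_groups$kept, paste0(output_prefix, ".names"))
    write.table(report, paste0(output_prefix, ".report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  structure(list(reads = report, summary = summary,
                 kept_groups = split_groups$kept,
                 discarded_groups = split_groups$discarded),
            class = "pbf_report")
}

#' @export
print.pbf_report <- function(x, ...) {
  s <- x$summary
  cat("<pbf_report>\n")
  cat("  input reads:      ", s$input, "\n", sep = "")
  cat("  short (truncated):", format(s$short, width = nchar(s$input) + 1),
      "\n", sep = "")
  cat("  kept:             ", format(s$kept, width = nchar(s$input) + 1),
      "\n", sep = "")
  cat("  discarded:        ", format(s$discarded, width = nchar(s$input) + 1),
      "\n", sep = "")
  p <- s$params
  cat("  alpha=", p$alpha, " uncert=", p$uncert,
      if (!is.null(p$trunc_len)) paste0(" trunc_len=", p$trunc_len),
      if (p$collapse) " collapse" else " no-collapse",
      if (p$use_poisson_approx) " poisson-approx", "\n", sep = "")
  invisible(x)
}

#' @export
summary.pbf_report <- function(object, ...) {
  df <- object$reads
  out <- c(object$summary[c("input", "short", "kept", "discarded")],
           list(mean_lambda = mean(df$lambda, na.rm = TRUE),
                mean_jxi = mean(df$jxi, na.rm = TRUE),
                n_groups = length(object$kept_groups) +
                  length(object$discarded_groups)))
  class(out) <- "summary.pbf_report"
  out
}

#' @export
print.summary.pbf_report <- function(x, ...) {
  cat("reads: ", x$input, " in, ", x$kept, " kept, ", x$discarded,
      " discarded (", x$short, " too short)\n", sep = "")
  cat("groups:", x$n_groups, "\n")
  cat(sprintf("mean expected errors (lambda): %.4f; mean predicted max (j_xi): %.4f\n",
              x$mean_lambda, x$mean_jxi))
  invisible(x)
}
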