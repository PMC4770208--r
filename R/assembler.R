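#' Global alignment with free terminal gaps
#'
#' Needleman-Wunsch dynamic programming in overlap (semi-global) mode:
#' terminal gaps cost nothing, so the non-overlapping tails of a mate pair
#' are not penalised.  Interior gaps carry a linear cost.  Traceback is
#' deterministic (ties prefer diagonal, then a gap in the second sequence,
#' then a gap in the first).
#'
#' @param seq1,seq2 Non-empty base strings.
#' @param match Score for identical bases (default +1).
#' @param mismatch Score for conflicting bases (default -1).
#' @param gap Score per interior gap position (default -2).
#' @return An object of class `alignment`: `aligned1` and `aligned2`
#'   (equal-length gapped strings) and `score` (terminal gaps excluded).
#' @examples
#' global_align("ACGTACGT", "GTACGTTT")
#' @export
global_align <- function(seq1, seq2, match = 1, mismatch = -1, gap = -2) {
  seq1 <- toupper(as.character(seq1))
  seq2 <- toupper(as.character(seq2))
  if (nchar(seq1) == 0L || nchar(seq2) == 0L)
    stop("sequences must be non-empty")
  res <- .nw_overlap(seq1, seq2, match, mismatch, gap)
  structure(res, class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment> score ", x$score, "\n  ", x$aligned1, "\n  ",
      x$aligned2, "\n", sep = "")
  invisible(x)
}

#' Assembly settings for paired-read merging
#'
#' @param match,mismatch,gap Alignment scores passed to [global_align()].
#' @param deltaq Quality-difference threshold for conflicting columns: when
#'   the two bases disagree, the base of the higher-quality read is taken
#'   only if its quality exceeds the other by more than `deltaq`; otherwise
#'   the consensus base is `N`.  Default 6 (the conventional merge
#'   setting).
#' @return A list of class `assembly_params`.
#' @export
assembly_params <- function(match = 1, mismatch = -1, gap = -2, deltaq = 6) {
  stopifnot(deltaq >= 0)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 deltaq = deltaq),
            class = "assembly_params")
}

#' Merge a mate pair into a contig
#'
#' Reverse-complements the reverse-strand mate, aligns it against the
#' forward read with [global_align()], and builds the consensus
#' column by column:
#' \itemize{
#'   \item one read gapped (including the single-coverage terminal tails):
#'     the other read's base and quality are kept;
#'   \item bases agree: that base, with the larger of the two qualities;
#'   \item bases conflict: the base of the higher-quality read when the
#'     quality difference exceeds `deltaq`, otherwise `N`.
#' }
#' In every emitted column the consensus quality is the column maximum of
#' the member qualities.
#'
#' @param fwd Forward [quality_read()].
#' @param rev Reverse-strand mate as read from file (reverse-complemented
#'   internally).
#' @param params An [assembly_params()] object.
#' @return An object of class `contig`: `read` (the consensus
#'   `quality_read`) and `n_mismatches` (count of conflicting columns).
#' @export
make_contig <- function(fwd, rev, params = assembly_params()) {
  stopifnot(inherits(fwd, "quality_read"), inherits(rev, "quality_read"))
  if (nchar(fwd$sequence) == 0L || nchar(rev$sequence) == 0L)
    stop("reads must be non-empty")
  rc <- reverse_complement(rev)
  aln <- global_align(fwd$sequence, rc$sequence,
                      params$match, params$mismatch, params$gap)
  a1 <- strsplit(aln$aligned1, "", fixed = TRUE)[[1]]
  a2 <- strsplit(aln$aligned2, "", fixed = TRUE)[[1]]
  L <- length(a1)
  cons <- character(L)
  cq <- integer(L)
  i1 <- 0L
  i2 <- 0L
  n_mm <- 0L
  for (k in seq_len(L)) {
    b1 <- a1[k]; b2 <- a2[k]
    g1 <- b1 == "-"; g2 <- b2 == "-"
    stopifnot(!(g1 && g2))  # cannot occur: an all-gap column scores worse
    if (g1) {
      i2 <- i2 + 1L
      cons[k] <- b2; cq[k] <- rc$quals[i2]
    } else if (g2) {
      i1 <- i1 + 1L
      cons[k] <- b1; cq[k] <- fwd$quals[i1]
    } else {
      i1 <- i1 + 1L; i2 <- i2 + 1L
      q1 <- fwd$quals[i1]; q2 <- rc$quals[i2]
      qmax <- max(q1, q2)
      if (b1 == b2) {
        cons[k] <- b1
      } else {
        n_mm <- n_mm + 1L
        cons[k] <- if (abs(q1 - q2) > params$deltaq) {
          if (q1 >= q2) b1 else b2
        } else "N"
      }
      cq[k] <- qmax
    }
  }
  read <- quality_read(fwd$id, paste(cons, collapse = ""), cq)
  structure(list(read = read, n_mismatches = n_mm), class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat("<contig> ", x$read$id, " (", nchar(x$read$sequence), " nt, ",
      x$n_mismatches, " mismatching columns)\n", sep = "")
  invisible(x)
}
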