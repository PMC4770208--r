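#' Construct a quality read
#'
#' The unit of work for the filter: a sequence over `{A,C,G,T,N}` together
#' with one integer Phred score per base.
#'
#' @param id Character label.
#' @param sequence Base string; lowercase is accepted and uppercased
#'   (soft-masking carries no meaning for the error model).
#' @param quals Integer vector of Phred scores, one per base, each in
#'   `[0, 93]` (the printable FASTQ range).
#' @return An object of class `quality_read` with fields `id`, `sequence`
#'   and `quals`.
#' @examples
#' quality_read("r1", "ACGT", c(30, 30, 40, 40))
#' @export
quality_read <- function(id, sequence, quals) {
  stopifnot(is.character(id), length(id) == 1L)
  sequence <- toupper(as.character(sequence))
  quals <- as.integer(quals)
  if (nchar(sequence) != length(quals))
    stop("read '", id, "': sequence length (", nchar(sequence),
         ") differs from number of quality scores (", length(quals), ")")
  if (grepl("[^ACGTN]", sequence))
    stop("read '", id, "': sequence contains characters outside {A,C,G,T,N}")
  if (length(quals) && (anyNA(quals) || any(quals < 0L) || any(quals > 93L)))
    stop("read '", id, "': Phred scores must be integers in [0, 93]")
  structure(list(id = id, sequence = sequence, quals = quals),
            class = "quality_read")
}

#' @export
print.quality_read <- function(x, ...) {
  cat("<quality_read> ", x$id, " (", nchar(x$sequence), " nt)\n", sep = "")
  show <- function(s) if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat("  seq:  ", show(x$sequence), "\n", sep = "")
  cat("  qual: ", show(paste(x$quals, collapse = " ")), "\n", sep = "")
  invisible(x)
}

#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records and decodes quality characters as
#' `code - offset`.  The parser is strict: a record whose quality string
#' does not match its sequence length, or a missing `@` header, is an error
#' naming the record index, and a decoded score outside `[0, 93]` suggests
#' the other quality-score offset.
#'
#' @param path FASTQ file (plain or gzipped).
#' @param offset Quality encoding offset, 33 (Sanger/modern Illumina,
#'   default) or 64 (legacy Illumina).
#' @return List of [quality_read()] objects in file order.
#' @seealso [write_fastq()]
#' @export
read_fastq <- function(path, offset = 33) {
  stopifnot(file.exists(path), offset %in% c(33, 64))
  lines <- readLines(path)
  if (length(lines) == 0L) return(list())
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4")
  n <- length(lines) %/% 4L
  out <- vector("list", n)
  for (k in seq_len(n)) {
    hdr <- lines[4L * k - 3L]
    seq <- lines[4L * k - 2L]
    qstr <- lines[4L * k]
    if (!startsWith(hdr, "@"))
      stop("record ", k, ": header does not start with '@'")
    if (nchar(seq) != nchar(qstr))
      stop("record ", k, ": sequence and quality strings differ in length")
    q <- utf8ToInt(qstr) - offset
    if (length(q) && (min(q) < 0L || max(q) > 93L))
      stop("record ", k, ": decoded Phred score outside [0, 93]; ",
           "is the quality offset ", offset, " correct? (try ",
           if (offset == 33) 64 else 33, ")")
    id <- sub("\\s.*$", "", substring(hdr, 2L))
    out[[k]] <- quality_read(id, seq, q)
  }
  out
}

#' Write reads to FASTQ
#'
#' Emits 4-line records with no line wrapping.  Reading the file back with
#' [read_fastq()] at the same offset reproduces the input exactly.
#'
#' @param reads List of [quality_read()] objects.
#' @param path Output file.
#' @param offset Quality encoding offset (33 or 64).
#' @export
write_fastq <- function(reads, path, offset = 33) {
  stopifnot(offset %in% c(33, 64))
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    if (length(r$quals) && max(r$quals) + offset > 126L)
      stop("read '", r$id, "': quality ", max(r$quals),
           " not printable at offset ", offset)
    qstr <- if (length(r$quals)) intToUtf8(r$quals + offset) else ""
    writeLines(c(paste0("@", r$id), r$sequence, "+", qstr), con)
  }
  invisible(NULL)
}

#' Read paired FASTA and quality files
#'
#' The 454-era convention: a FASTA file plus a `.qual` companion holding
#' whitespace-separated integer Phred scores under identical headers, in
#' identical order.
#'
#' @param fasta_path FASTA file.
#' @param qual_path Companion quality file.
#' @return List of [quality_read()] objects.
#' @export
read_fasta_qual <- function(fasta_path, qual_path) {
  stopifnot(file.exists(fasta_path), file.exists(qual_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  quals <- .read_qual_records(qual_path)
  if (length(seqs) != length(quals$id))
    stop("record count mismatch: ", length(seqs), " FASTA records vs ",
         length(quals$id), " quality records")
  ids <- sub("\\s.*$", "", names(seqs))
  if (length(ids)) {
    diverge <- which(ids != quals$id)
    if (length(diverge))
      stop("id mismatch at record ", diverge[1], ": FASTA '", ids[diverge[1]],
           "' vs qual '", quals$id[diverge[1]], "'")
  }
  lapply(seq_along(seqs), function(k)
    quality_read(ids[k], as.character(seqs[[k]]), quals$scores[[k]]))
}

# parse a .qual file into parallel id / integer-vector lists
.read_qual_records <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(lines) && length(hdr) == 0L)
    stop("no '>' headers found in quality file ", path)
  ids <- sub("\\s.*$", "", substring(lines[hdr], 2L))
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  scores <- lapply(seq_along(hdr), function(k) {
    if (starts[k] > ends[k]) return(integer(0))
    body <- paste(lines[starts[k]:ends[k]], collapse = " ")
    as.integer(strsplit(trimws(body), "\\s+")[[1]])
  })
  list(id = ids, scores = scores)
}

#' Write a dereplication names file
#'
#' Two-column text in the mothur names-file dialect: the representative id,
#' a tab, then the comma-separated ids of all group members with the
#' representative first.  Downstream mothur-style pipelines consume this
#' together with the representative sequences.
#'
#' @param groups List of collapsed groups as returned by [collapse_reads()].
#' @param path Output file.
#' @export
write_names <- function(groups, path) {
  all_members <- unlist(lapply(groups, `[[`, "members"), use.names = FALSE)
  dup <- anyDuplicated(all_members)
  if (dup)
    stop("duplicate member id across groups: '", all_members[dup], "'")
  lines <- vapply(groups, function(g) {
    members <- c(g$representative, setdiff(g$members, g$representative))
    paste0(g$representative, "\t", paste(members, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(NULL)
}

#' Reverse complement of a read
#'
#' Watson-Crick complement of the sequence, reversed, with the quality
#' vector reversed alongside; `N` maps to `N`.  Applying it twice is the
#' identity.
#'
#' @param read A [quality_read()].
#' @return A `quality_read` on the opposite strand.
#' @export
reverse_complement <- function(read) {
  stopifnot(inherits(read, "quality_read"))
  comp <- chartr("ACGTN", "TGCAN", read$sequence)
  revseq <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  quality_read(read$id, revseq, rev(read$quals))
}
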