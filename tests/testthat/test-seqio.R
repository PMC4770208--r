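test_that("FASTQ quality decoding honours the chosen offset", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "AC", "+", "II"), fq)
  reads <- read_fastq(fq, offset = 33)
  expect_equal(reads[[1]]$quals, c(40L, 40L))
  expect_equal(reads[[1]]$sequence, "AC")

  # same bytes at offset 64 decode 31 points lower
  reads64 <- read_fastq(fq, offset = 64)
  expect_equal(reads64[[1]]$quals, c(9L, 9L))
})

test_that("malformed FASTQ records are rejected with the record index", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), fq)
  expect_error(read_fastq(fq), "record 1.*differ in length")

  writeLines(c("@r1", "AC", "+", "II", "r2", "AC", "+", "II"), fq)
  expect_error(read_fastq(fq), "record 2.*'@'")

  # legacy Phred+64 bytes read at offset 33 give scores > 93 is impossible,
  # but offset-64 reading of Sanger bytes goes negative and names the fix
  writeLines(c("@r1", "AC", "+", "!!"), fq)
  expect_error(read_fastq(fq, offset = 64), "record 1.*offset")
})

test_that("empty FASTQ yields an empty read list", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  file.create(fq)
  expect_identical(read_fastq(fq), list())
})

test_that("FASTQ round trip is the identity on id, sequence and quals", {
  set.seed(11)
  reads <- lapply(seq_len(100), function(k)
    random_read(sprintf("rt%03d", k), sample(20:80, 1), qmin = 0, qmax = 93))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back, reads)

  # and an empty stream writes an empty file
  write_fastq(list(), fq)
  expect_identical(readLines(fq), character(0))
})

test_that("FASTA plus qual files pair records by id and order", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  qu <- withr::local_tempfile(fileext = ".qual")
  writeLines(c(">r1", "ACG", ">r2", "TTAA"), fa)
  writeLines(c(">r1", "30 30 30", ">r2", "12 13 14 15"), qu)
  reads <- read_fasta_qual(fa, qu)
  expect_equal(reads[[1]], quality_read("r1", "ACG", c(30, 30, 30)))
  expect_equal(reads[[2]], quality_read("r2", "TTAA", 12:15))

  writeLines(c(">r1", "30 30", ">r2", "12 13 14 15"), qu)
  expect_error(read_fasta_qual(fa, qu), "r1")

  writeLines(c(">r2", "12 13 14 15", ">r1", "30 30 30"), qu)
  expect_error(read_fasta_qual(fa, qu), "id mismatch at record 1")

  writeLines(c(">r1", "30 30 30"), qu)
  expect_error(read_fasta_qual(fa, qu), "count mismatch")
})

test_that("names file follows the mothur dialect and conserves members", {
  g1 <- structure(list(sequence = "AA", members = c("r1", "r7"),
                       representative = "r1", rep_jxi = 0.1),
                  class = "collapsed_group")
  g2 <- structure(list(sequence = "CC", members = "r2",
                       representative = "r2", rep_jxi = 0.5),
                  class = "collapsed_group")
  path <- withr::local_tempfile(fileext = ".names")
  write_names(list(g1, g2), path)
  lines <- readLines(path)
  expect_equal(lines, c("r1\tr1,r7", "r2\tr2"))
  members <- unlist(strsplit(sub("^[^\t]+\t", "", lines), ","))
  expect_equal(length(members), 3L)  # conservation

  g_dup <- structure(list(sequence = "GG", members = "r7",
                          representative = "r7", rep_jxi = 0),
                     class = "collapsed_group")
  expect_error(write_names(list(g1, g_dup), path), "duplicate member id.*r7")
})

test_that("reverse_complement is a quality-preserving involution", {
  r <- quality_read("p", "ACGT", c(10, 20, 30, 40))
  rc <- reverse_complement(r)
  expect_equal(rc$sequence, "ACGT")           # palindrome
  expect_equal(rc$quals, c(40, 30, 20, 10))   # qualities reversed

  r2 <- quality_read("n", "AAN", c(1, 2, 3))
  expect_equal(reverse_complement(r2)$sequence, "NTT")
  expect_equal(reverse_complement(r2)$quals, c(3, 2, 1))

  set.seed(5)
  for (k in 1:20) {
    x <- random_read(paste0("inv", k), sample(1:50, 1))
    expect_equal(reverse_complement(reverse_complement(x)), x)
  }

  expect_error(quality_read("bad", "ACRT", c(1, 2, 3, 4)), "outside")
})

test_that("quality_read enforces its invariants", {
  expect_error(quality_read("x", "ACGT", c(1, 2, 3)), "differs")
  expect_error(quality_read("x", "AC", c(1, 94)), "\\[0, 93\\]")
  expect_error(quality_read("x", "AC", c(-1, 4)), "\\[0, 93\\]")
  # lowercase input is uppercased
  expect_equal(quality_read("x", "acgt", 1:4)$sequence, "ACGT")
})
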