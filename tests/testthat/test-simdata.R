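test_that("simulation is reproducible from its seed and leaves the RNG alone", {
  tpl <- random_templates(3, 80, seed = 1)
  a <- simulate_reads(tpl, 20, qprofile_decay(30, 10), seed = 99)
  b <- simulate_reads(tpl, 20, qprofile_decay(30, 10), seed = 99)
  expect_equal(a, b)
  c <- simulate_reads(tpl, 20, qprofile_decay(30, 10), seed = 100)
  expect_false(identical(a, c))

  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(simulate_reads(tpl, 5, qprofile_constant(30), seed = 7))
  expect_equal(runif(3), before)  # caller's RNG stream undisturbed
})

test_that("recorded errors are real substitutions against the template", {
  tpl <- random_templates(2, 100, seed = 3)
  sims <- simulate_reads(tpl, 50, qprofile_decay(25, 5), seed = 4)
  for (s in sims) {
    expect_equal(s$true_errors, length(s$error_positions))
    tpl_chars <- strsplit(tpl[[s$template_id]], "")[[1]]
    read_chars <- strsplit(s$read$sequence, "")[[1]]
    # the recorded positions are exactly where read and template disagree
    expect_equal(which(read_chars != tpl_chars), s$error_positions)
  }
})

test_that("a zero-quality profile corrupts every base", {
  tpl <- random_templates(1, 40, seed = 5)
  sims <- simulate_reads(tpl, 10, qprofile_constant(0), seed = 6)
  for (s in sims) expect_equal(s$true_errors, 40L)
})

test_that("mean true errors converges to the mean expected errors lambda", {
  tpl <- random_templates(1, 250, seed = 7)
  sims <- simulate_reads(tpl, 10000, qprofile_constant(40), seed = 8)
  true_mean <- mean(vapply(sims, `[[`, integer(1), "true_errors"))
  lambda <- 250 * 1e-4  # 0.025 expected errors per read at Q40
  se <- sqrt(lambda / 10000)
  expect_lt(abs(true_mean - lambda), 3 * se)
})

test_that("true errors rarely exceed the integer-rounded predicted maximum", {
  # the quantile construction guarantees P(true > ceiling(j_xi)) <= alpha:
  # the cumulative at the stopping point j_max >= ceiling(j_xi) reaches xi
  tpl <- random_templates(2, 250, seed = 17)
  n <- 20000
  sims <- c(simulate_reads(tpl, n / 2, qprofile_constant(38), seed = 11),
            simulate_reads(tpl, n / 2, qprofile_decay(38, 15), seed = 12))
  exceed <- vapply(sims, function(s) {
    jxi <- predicted_max_errors(phred_to_prob(s$read$quals), 0.995)
    s$true_errors > ceiling(jxi)
  }, logical(1))
  alpha <- 0.005
  bound <- alpha + 3 * sqrt(alpha * (1 - alpha) / n)
  expect_lte(mean(exceed), bound)
})

test_that("pair simulation respects its geometry and plants verifiable errors", {
  tpl <- random_templates(1, 200, seed = 20)[[1]]
  expect_error(simulate_pair(tpl, read_len = 150, overlap = 40,
                             profile = qprofile_constant(30)), "too short")
  expect_error(simulate_pair(tpl, read_len = 50, overlap = 60,
                             profile = qprofile_constant(30)))

  pr <- simulate_pair(tpl, read_len = 120, overlap = 60,
                      profile = qprofile_constant(93), seed = 21)
  expect_equal(nchar(pr$fwd$sequence), 120L)
  expect_equal(nchar(pr$rev$sequence), 120L)
  expect_equal(nchar(pr$span), 180L)
  # the reverse mate really is the opposite strand of the template window
  expect_equal(reverse_complement(pr$rev)$sequence, substr(tpl, 61, 180))
})

test_that("planted overlap conflicts resolve by quality difference", {
  tpl <- random_templates(1, 150, seed = 30)[[1]]
  pr <- simulate_pair(tpl, read_len = 100, overlap = 50,
                      profile = qprofile_constant(93), seed = 31)
  # plant a conflict at forward position 80 (inside the overlap 51..100)
  chars <- strsplit(pr$fwd$sequence, "")[[1]]
  chars[80] <- setdiff(c("A", "C", "G", "T"), chars[80])[1]

  # quality gap above deltaq: the untouched (higher-quality) mate wins
  lowq <- pr$fwd$quals; lowq[80] <- 10L
  fwd_low <- quality_read(pr$fwd$id, paste(chars, collapse = ""), lowq)
  ct <- make_contig(fwd_low, pr$rev, assembly_params(deltaq = 6))
  expect_equal(ct$read$sequence, pr$span)
  expect_equal(ct$n_mismatches, 1L)

  # quality gap within deltaq: ambiguity is recorded as N
  nearq <- pr$fwd$quals; nearq[80] <- 90L
  fwd_near <- quality_read(pr$fwd$id, paste(chars, collapse = ""), nearq)
  ct2 <- make_contig(fwd_near, pr$rev, assembly_params(deltaq = 6))
  expect_equal(substr(ct2$read$sequence, 80, 80), "N")
  expect_equal(ct2$n_mismatches, 1L)
})
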