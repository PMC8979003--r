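test_that("degenerate scanning applies IUPAC base sets position-wise", {
  hits <- scan_iupac("WTAGWWHWWHD", "ATAGTTATTAT")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 0L)
  expect_equal(hits$mismatches, 0L)

  expect_equal(nrow(scan_iupac("WTAGWWHWWHD", "GTAGTTATTAT")), 0L)  # G not in W
  expect_equal(nrow(scan_iupac("NNNN", "ACGTACGTAC")), 7L)          # 10-4+1
  expect_error(scan_iupac("WXAG", "ACGT"), "IUPAC")
})

test_that("both printed promoter literals carry a window matching the order-level consensus", {
  pre <- motif_presets()
  expect_gt(nrow(scan_iupac(pre$hypocreales, pre$promoter_11mer$symbols)), 0L)
  expect_gt(nrow(scan_iupac(pre$hypocreales, pre$promoter_12mer$symbols)), 0L)
})

test_that("mismatch tolerance is monotone and hits match the brute-force oracle", {
  set.seed(21)
  for (i in 1:5) {
    region <- random_dna(500, at = 0.72)
    prev <- NULL
    for (m in 0:2) {
      got <- scan_iupac("WTAGWWHWWHD", region, max_mismatch = m)$position
      expect_equal(got, oracle_iupac_positions("WTAGWWHWWHD", region, m))
      if (!is.null(prev)) expect_true(all(prev %in% got))
      prev <- got
    }
  }
})

test_that("minus-strand hits mirror those of the reverse-complemented region", {
  set.seed(22)
  region <- random_dna(300, at = 0.7)
  h_fwd <- scan_iupac("TAAATT", region, strands = "both")
  h_rc <- scan_iupac("TAAATT", revcomp(region), strands = "both")
  n <- nchar(region); L <- 6L
  mirrored <- sort((n - h_rc$position - L))
  expect_equal(sort(h_fwd$position), mirrored)
})

test_that("PWM probabilities follow the pseudocount formula", {
  p0 <- build_pwm(c("AA", "AA"), pseudocount = 0)
  expect_equal(unname(p0$probs[1, ]), c(1, 0, 0, 0))
  p1 <- build_pwm(c("A", "C"), pseudocount = 1)
  expect_equal(unname(p1$probs[1, ]), c(2, 2, 1, 1) / 6)
  expect_error(build_pwm(c("AA", "A")), "ragged")
  expect_error(build_pwm(character(0)), "at least 2")
  expect_error(build_pwm(c("AN", "AC")), "unambiguous")
})

test_that("PWM scanning scores log2 odds against the attainable maximum", {
  pwm <- build_pwm(c("ACGT", "ACGT"), pseudocount = 0.25)
  self <- scan_pwm(pwm, "ACGT", threshold_frac = 1)
  expect_equal(nrow(self), 1L)
  expect_equal(self$position, 0L)

  # zero-information motif: every window scores 0 and passes threshold 1
  flat <- build_pwm(c("AC", "CA", "GT", "TG"), pseudocount = 0)
  flat$probs[] <- 0.25
  every <- scan_pwm(flat, "ACGTACGT", threshold_frac = 1)
  expect_equal(nrow(every), 7L)
  expect_true(all(every$score == 0))

  expect_error(scan_pwm(pwm, "ACGT", threshold_frac = 0), "threshold")
  expect_error(scan_pwm(pwm, "ACGT", threshold_frac = 1.5), "threshold")
})

test_that("PWM hits equal brute-force per-window rescoring", {
  set.seed(23)
  inst <- c("ATAGTTATTAT", "TTAGAATATTA", "ATAGATATAAT", "TTAGTTCTTAT",
            "ATAGAACAATT", "ATAGTTATAAT")
  pwm <- build_pwm(inst)
  for (i in 1:4) {
    region <- random_dna(1500, at = 0.72)
    for (frac in c(0.6, 0.8)) {
      got <- scan_pwm(pwm, region, threshold_frac = frac)$position
      expect_equal(got, oracle_pwm_positions(pwm$probs, pwm$background,
                                             region, frac))
    }
  }
})

test_that("consensus building follows the majority / coverage rule table", {
  expect_equal(build_consensus(c("ATAT", "ATAT"))$symbols, "ATAT")
  expect_equal(build_consensus(c("ATAT", "TTAT"), t_major = 0.75,
                               t_cover = 0)$symbols, "WTAT")
  # A, C and T present at one position -> H
  expect_equal(build_consensus(c("A", "C", "T", "A"), t_major = 0.8,
                               t_cover = 0)$symbols, "H")
  expect_error(build_consensus(c("A", "C"), t_major = 0.4), "t_major")
  expect_error(build_consensus(c("A", "C"), t_cover = 0.9), "t_cover")
})

test_that("a zero-coverage consensus matches every instance it was built from", {
  # guaranteed when no minority base is dropped by a majority call, i.e.
  # t_major = 1: every observed base is then covered by the emitted code
  set.seed(24)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    inst <- vapply(seq_len(n), function(j) random_dna(12, at = 0.7), "")
    cons <- build_consensus(inst, t_major = 1, t_cover = 0)
    for (s in inst) {
      expect_equal(nrow(scan_iupac(cons, s)), 1L)
    }
  }
})

test_that("six planted promoter instances rebuild their planting consensus", {
  sim <- simulate_genome(seed = 12, promoter_source = "pwm-sample")
  inst <- sim$truth$promoters$instance
  pwm <- build_pwm(inst)
  argmax <- paste(colnames(pwm$probs)[apply(pwm$probs, 1, which.max)],
                  collapse = "")
  # every argmax base is drawn from the degenerate planting consensus
  expect_equal(nrow(scan_iupac("WTAGWWHWWHD", argmax)), 1L)
})

test_that("motifs and PWMs serialize to JSON and MEME-style text", {
  pwm <- build_pwm(c("ACGT", "ACGA"))
  j <- withr::local_tempfile(fileext = ".json")
  m <- withr::local_tempfile(fileext = ".txt")
  write_motif_json(pwm, j)
  expect_equal(jsonlite::read_json(j)$type, "pwm")
  write_pwm_meme(pwm, m)
  expect_true(any(grepl("letter-probability", readLines(m))))
  write_motif_json(motif_presets()$terminator, j)
  expect_equal(jsonlite::read_json(j)$symbols, "TAAATT")
})
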