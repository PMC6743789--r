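test_that("build_pwm converts counts to smoothed probabilities", {
  pwm <- build_pwm(rbind(c(10, 0, 0, 0)), pseudocount = 0)
  expect_equal(unname(pwm$prob[1, ]), c(1, 0, 0, 0))
  pwm2 <- build_pwm(rbind(c(1, 1, 1, 1)), pseudocount = 0)
  expect_equal(unname(pwm2$prob[1, ]), rep(0.25, 4))
  pwm3 <- build_pwm(rbind(c(3, 1, 0, 0)), pseudocount = 0.25)
  expect_equal(unname(pwm3$prob[1, ]), c(0.65, 0.25, 0.05, 0.05))
  expect_equal(rowSums(pwm3$prob), 1)
  expect_error(build_pwm(rbind(c(0, 0, 0, 0)), pseudocount = 0), "all-zero")
  expect_error(build_pwm(rbind(c(-1, 1, 1, 1))), "counts")
})

test_that("PWM count matrices round-trip through the text format", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#motifA", "3 1 0 0", "0 0 4 0",
               "#motifB", "1 1 1 1"), f)
  pwms <- read_pwms(f, pseudocount = 0.25)
  expect_equal(names(pwms), c("motifA", "motifB"))
  expect_equal(unname(pwms$motifA$prob[1, ]), c(0.65, 0.25, 0.05, 0.05))
  expect_equal(nrow(pwms$motifB$prob), 1)
})

test_that("consensus scanning finds the planted site with full score", {
  pwm <- consensus_pwm("TGACGT", weight = 1e9, pseudocount = 0)
  seq <- paste0("AAAAA", "TGACGT", "AAAAA")
  hits <- scan_sequence(pwm, seq, threshold_fraction = 1)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 5L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score_fraction, 1)

  # reverse complement of the consensus: one reverse-strand hit at the
  # mirrored offset
  rc <- paste0("AAAAA", "ACGTCA", "AAAAA")
  hits_rc <- scan_sequence(pwm, rc, threshold_fraction = 1)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$offset, 5L)
})

test_that("scanning respects N masking, short input and degenerate PWMs", {
  pwm <- consensus_pwm("TGACGT", weight = 1e9, pseudocount = 0)
  expect_equal(nrow(scan_sequence(pwm, "TGANGT", threshold_fraction = 0.5)),
               0)
  expect_equal(nrow(scan_sequence(pwm, "TGA")), 0)
  # uniform PWM against uniform background: max score 0, no hits
  uni <- build_pwm(matrix(1, 4, 4), pseudocount = 0)
  expect_equal(nrow(scan_sequence(uni, "ACGTACGTACGT", 0.5)), 0)
})

test_that("a sequence and its reverse complement give mirror-image hits", {
  set.seed(31)
  pwm <- consensus_pwm("TGACGTCA", weight = 10)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  seq <- paste0(substr(seq, 1, 100), "TGACGTCA", substr(seq, 109, 300))
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  h1 <- scan_sequence(pwm, seq, 0.8)
  h2 <- scan_sequence(pwm, rc, 0.8)
  expect_equal(nrow(h1), nrow(h2))
  w <- nrow(pwm$prob)
  mirrored <- sort(nchar(seq) - w - h2$offset)
  expect_equal(sort(h1$offset), mirrored)
  expect_equal(sort(h1$score), sort(h2$score))
})

test_that("consensus score equals the maximal attainable score exactly", {
  pwm <- consensus_pwm("TTGACA", weight = 7, pseudocount = 0.25)
  hits <- scan_sequence(pwm, "TTGACA", threshold_fraction = 0,
                        both_strands = FALSE)
  max_score <- sum(apply(log2(pwm$prob / 0.25), 1, max))
  expect_equal(hits$score, max_score)
  expect_equal(hits$score_fraction, 1)
})

test_that("motif enrichment matches Fisher enumeration on fixed tables", {
  pwm <- consensus_pwm("TGACGTCA", weight = 1e9, pseudocount = 0)
  with_hit <- paste0("AAAAAAAA", "TGACGTCA", "AAAAAAAA")
  without <- paste0(strrep("AC", 12))
  mk <- function(nhit, ntot, prefix) {
    s <- c(rep(with_hit, nhit), rep(without, ntot - nhit))
    stats::setNames(s, paste0(prefix, seq_len(ntot)))
  }
  # extreme 10/10 vs 0/10 table: two-sided enumeration gives 2 / C(20,10)
  res <- motif_enrichment(pwm, mk(10, 10, "f"), mk(0, 10, "b"), 0.9)
  expect_equal(res$fg_hits, 10L)
  expect_equal(res$bg_hits, 0L)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_true(is.finite(res$odds_ratio) && res$odds_ratio > 1)

  # equal hit rates: no enrichment
  res2 <- motif_enrichment(pwm, mk(3, 10, "f"), mk(3, 10, "b"), 0.9)
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p, 1)

  # enumeration oracle across assorted margins <= 30
  for (tab in list(c(5, 3, 2, 8), c(1, 9, 7, 3), c(6, 6, 6, 6),
                   c(0, 10, 10, 0), c(12, 3, 4, 11))) {
    res3 <- motif_enrichment(pwm, mk(tab[1], tab[1] + tab[2], "f"),
                             mk(tab[3], tab[3] + tab[4], "b"), 0.9)
    expect_equal(res3$p, oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
  expect_error(motif_enrichment(pwm, character(0), mk(1, 2, "b")),
               "non-empty")
})
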