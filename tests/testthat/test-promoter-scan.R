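# PWM scoring, minSUM calibration, scanning, and enrichment.

test_that("uniform PWM scores zero everywhere; N contributes zero", {
  uni <- new_pwm(matrix(0.25, 4, 6), id = "UNI", pseudocount = 0)
  expect_equal(score_site(uni, random_seq(20), 5), 0)
  sharp <- new_pwm(matrix(c(40, 1, 1, 1), 4, 5), id = "SHARP")
  allN <- paste(rep("N", 10), collapse = "")
  expect_equal(score_site(sharp, allN, 2), 0)
  expect_error(score_site(sharp, "ACGT", 1), "out of bounds")
})

test_that("score_site matches the per-position oracle on random pairs", {
  set.seed(21)
  for (i in 1:100) {
    L <- sample(4:12, 1)
    pwm <- random_pwm(L)
    seq <- random_seq(60)
    pos <- sample(60 - L + 1, 1)
    strand <- sample(c("+", "-"), 1)
    expect_equal(score_site(pwm, seq, pos, strand),
                 oracle_score(pwm, seq, pos, strand), tolerance = 1e-9)
  }
})

test_that("calibrate_threshold matches exhaustive enumeration (L <= 6)", {
  set.seed(33)
  for (i in 1:20) {
    pwm <- random_pwm(sample(4:6, 1))
    got <- calibrate_threshold(pwm)
    orc <- oracle_calibrate(pwm)
    expect_equal(as.numeric(got), orc$cutoff, tolerance = 1e-9)
    expect_equal(attr(got, "fn") + attr(got, "fp"), orc$objective,
                 tolerance = 1e-9)
  }
})

test_that("near-deterministic PWMs calibrate to low total error", {
  set.seed(5)
  cons <- sample(1:4, 6, replace = TRUE)
  mat <- matrix(0.01, 4, 6)
  mat[cbind(cons, 1:6)] <- 0.97
  pwm <- new_pwm(sweep(mat, 2, colSums(mat), "/"), id = "DET",
                 pseudocount = 0.01)
  got <- calibrate_threshold(pwm)
  expect_lt(attr(got, "fn") + attr(got, "fp"), 0.05)
})

test_that("uniform PWM calibrates to its single achievable score", {
  uni <- new_pwm(matrix(0.25, 4, 5), id = "UNI", pseudocount = 0)
  got <- calibrate_threshold(uni)
  expect_equal(as.numeric(got), 0)             # the maximal (only) score
  expect_equal(attr(got, "fn") + attr(got, "fp"), 1)
})

test_that("DP score distributions sum to one under both models", {
  set.seed(8)
  for (L in c(5, 9, 14)) {   # L = 14 exercises the coarse-grid branch
    pwm <- random_pwm(L)
    d <- attr(calibrate_threshold(pwm), "distribution")
    expect_equal(sum(d$p_motif), 1, tolerance = 1e-9)
    expect_equal(sum(d$p_background), 1, tolerance = 1e-9)
  }
})

planted_promoters <- function(pwm, n, plant, seed) {
  set.seed(seed)
  cons <- consensus_of(pwm)
  L <- nchar(cons)
  seqs <- vapply(seq_len(n), function(i) {
    s <- random_seq(1101)
    if (plant(i)) {
      at <- sample(1101 - L + 1, 1)
      substr(s, at, at + L - 1) <- cons
    }
    s
  }, character(1))
  names(seqs) <- sprintf("Y%04d", seq_len(n))
  promoter_set(seqs)
}

sharp_test_pwm <- function(seed = 9, L = 12) {
  set.seed(seed)
  cons <- sample(1:4, L, replace = TRUE)
  mat <- matrix(0.01 / 3, 4, L)
  mat[cbind(cons, seq_len(L))] <- 0.99
  new_pwm(mat, id = "PL", tf = "PLANTED", pseudocount = 0.01)
}

test_that("scan_set detects an embedded consensus at the right offset", {
  pwm <- sharp_test_pwm()
  lib <- calibrate_library(pwm_library(list(pwm)))
  cons <- consensus_of(pwm)
  set.seed(10)
  s <- random_seq(1101)
  substr(s, 501, 512) <- cons   # 1-based position 501 -> offset -500
  prom <- promoter_set(c(gene1 = s))
  hits <- scan_set(lib, prom)
  expect_true(any(hits$gene == "gene1" & hits$offset == -500 &
                    hits$strand == "+"))
})

test_that("all-N promoters produce no hits for a positive threshold", {
  pwm <- sharp_test_pwm()
  lib <- calibrate_library(pwm_library(list(pwm)))
  expect_gt(lib[[1]]$threshold, 0)
  prom <- promoter_set(c(g = paste(rep("N", 1101), collapse = "")))
  expect_equal(nrow(scan_set(lib, prom)), 0L)
})

test_that("reverse-complementing promoters swaps strands, keeps counts", {
  pwm <- sharp_test_pwm(seed = 14)
  lib <- calibrate_library(pwm_library(list(pwm)))
  prom <- planted_promoters(pwm, 20, function(i) i <= 15, seed = 15)
  rc <- vapply(unclass(prom), function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1))
  prom_rc <- promoter_set(rc)
  h1 <- scan_set(lib, prom)
  h2 <- scan_set(lib, prom_rc)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sum(h1$strand == "+"), sum(h2$strand == "-"))
  expect_equal(sort(h1$score), sort(h2$score))
})

test_that("scan_set equals the per-position oracle on a small fixture", {
  set.seed(18)
  pwms <- list(random_pwm(5), sharp_test_pwm(seed = 19, L = 6))
  pwms[[1]]$id <- "RA"; pwms[[2]]$id <- "RB"
  lib <- calibrate_library(pwm_library(pwms))
  prom <- promoter_set(stats::setNames(
    vapply(1:4, function(i) random_seq(80), character(1)),
    paste0("g", 1:4)))
  hits <- scan_set(lib, prom)
  for (pw in lib) {
    L <- ncol(pw$mat)
    for (g in names(prom)) {
      for (pos in seq_len(nchar(prom[[g]]) - L + 1)) {
        for (st in c("+", "-")) {
          sc <- oracle_score(pw, unclass(prom)[[g]], pos, st)
          off <- pos - 1 + attr(prom, "window_end") - nchar(prom[[g]]) + 1
          found <- any(hits$matrix_id == pw$id & hits$gene == g &
                         hits$strand == st & hits$offset == off)
          expect_equal(found, sc >= pw$threshold)
          if (found) {
            expect_equal(
              hits$score[hits$matrix_id == pw$id & hits$gene == g &
                           hits$strand == st & hits$offset == off],
              sc, tolerance = 1e-9)
          }
        }
      }
    }
  }
})

test_that("tf_candidates finds a planted motif and respects degenerates", {
  pwm <- sharp_test_pwm(seed = 25)
  decoy <- sharp_test_pwm(seed = 26)
  decoy$id <- "DC"; decoy$tf <- "DECOY"
  lib <- calibrate_library(pwm_library(list(pwm, decoy)))
  yes <- planted_promoters(pwm, 100, function(i) i <= 80, seed = 27)
  no <- planted_promoters(pwm, 100, function(i) i <= 5, seed = 28)
  no <- promoter_set(stats::setNames(unclass(no), sub("Y", "N", names(no))))
  res <- tf_candidates(yes, no, lib)
  expect_true("PLANTED" %in% res$candidates)
  # the planted matrix dominates any chance fluctuation of the decoy
  expect_lt(res$records$p[res$records$matrix_id == "PL"],
            1e-6 * min(res$records$p[res$records$matrix_id == "DC"], 1))
  # the same sequences on both sides -> equal densities, nothing enriched
  twin <- promoter_set(stats::setNames(unclass(yes),
                                       sub("Y", "T", names(yes))))
  res2 <- tf_candidates(yes, twin, lib)
  expect_length(res2$candidates, 0)
})

test_that("tf_candidates handles zero-hit matrices and small yes sets", {
  uni <- new_pwm(matrix(0.25, 4, 8), id = "U", tf = "UTF", pseudocount = 0)
  uni$threshold <- 1   # unattainable: every score is 0
  lib <- structure(list(U = uni), class = "kr_pwm_library")
  set.seed(31)
  yes <- promoter_set(c(a = random_seq(500), b = random_seq(500),
                        c = random_seq(500)))
  no <- promoter_set(c(x = random_seq(500), y = random_seq(500)))
  res <- tf_candidates(yes, no, lib)
  expect_equal(res$records$p, 1)
  expect_length(res$candidates, 0)
  expect_warning(tf_candidates(yes[1], no, lib), "low-power")
  expect_error(tf_candidates(yes, yes, lib), "disjoint")
})
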