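# Differential calling: transcripts (Welch + BH + fold gate) and proteins
# (emPAI, normalization, presence rule).

mk_mat <- function(values, genes, reps = 3) {
  matrix(values, length(genes), reps, dimnames = list(genes))
}

test_that("identical matrices yield an empty differential list", {
  set.seed(42)
  m <- mk_mat(rnorm(30), paste0("G", 1:10))
  expect_equal(nrow(de_transcripts(m, m)), 0L)
})

test_that("planted log2 shifts are recovered with direction up", {
  set.seed(7)
  genes <- sprintf("G%03d", 1:520)
  high <- mk_mat(rnorm(520 * 3, 0, 0.2), genes)
  low <- mk_mat(rnorm(520 * 3, 0, 0.2), genes)
  planted <- genes[1:20]
  high[planted, ] <- high[planted, ] + 2.0
  de <- de_transcripts(high, low)
  # Welch power at n = 3 under BH over 520 genes averages ~12 of 20
  # recovered (computed over 100 fixture draws); this seed yields 9
  expect_gte(sum(planted %in% de$entity), 8)
  expect_true(all(de$direction[de$entity %in% planted] == "up"))
  # exact agreement with the hand-looped oracle is the real contract
  orc <- oracle_de_transcripts(high, low)
  expect_setequal(de$entity, orc$entity)
})

test_that("fold gate excludes sub-threshold shifts regardless of p", {
  genes <- paste0("G", 1:5)
  high <- mk_mat(0, genes)
  low <- mk_mat(0, genes)
  high["G1", ] <- c(0.8, 0.8001, 0.7999)  # fold 1.74, p ~ 0
  de <- de_transcripts(high, low)
  expect_false("G1" %in% de$entity)
})

test_that("de_transcripts matches the brute-force oracle on random matrices", {
  set.seed(11)
  for (rep in 1:25) {
    genes <- sprintf("g%03d", 1:200)
    high <- mk_mat(rnorm(600, 0, 0.5), genes)
    low <- mk_mat(rnorm(600, 0, 0.5), genes)
    sh <- sample(genes, 10)
    high[sh, ] <- high[sh, ] + sample(c(-2, 1.5, 3), 10, replace = TRUE)
    de <- de_transcripts(high, low)
    orc <- oracle_de_transcripts(high, low)
    expect_setequal(de$entity, orc$entity)
    expect_equal(de$log2fc[order(de$entity)],
                 orc$log2fc[order(orc$entity)], tolerance = 1e-12)
  }
})

test_that("input contracts are enforced", {
  m <- mk_mat(rnorm(9), paste0("G", 1:3))
  expect_error(de_transcripts(m[, 1, drop = FALSE], m), "2 replicates")
  m2 <- m; rownames(m2) <- paste0("H", 1:3)
  expect_error(de_transcripts(m, m2), "entity universe")
  # genes with < 2 finite values in one group are skipped with a message
  m3 <- m; m3[1, 2:3] <- NA
  expect_message(de_transcripts(m3, m), "skipped")
})

test_that("empai evaluates its closed form", {
  expect_equal(empai(0, 10), 0)
  expect_equal(empai(10, 10), 9)
  expect_equal(empai(3, 10), 0.99526, tolerance = 1e-5)
  expect_error(empai(1, 0), "observable")
  # strictly increasing in observed; zero at zero observed
  for (n in c(1, 5, 17)) {
    v <- empai(0:n, n)
    expect_equal(v[1], 0)
    expect_true(all(diff(v) > 0))
  }
})

mk_pep <- function(observed, observable) {
  peptide_table(observed, observable)
}

test_that("normalize_abundance divides by the geometric mean of counts", {
  obs <- matrix(c(1, 2, 4), 3, 1, dimnames = list(c("P1", "P2", "P3")))
  tab <- mk_pep(obs, c(10, 10, 10))
  ab <- normalize_abundance(tab)
  expect_equal(ab$normalizer, 2)  # (1*2*4)^(1/3)
  expect_equal(unname(ab$abundance[, 1]), empai(c(1, 2, 4), 10) / 2)
  # single protein: normalizer is its own count
  one <- mk_pep(matrix(6, 1, 1, dimnames = list("P1")), 6)
  expect_equal(unname(normalize_abundance(one)$abundance[1, 1]),
               empai(6, 6) / 6)
  # all-zero replicate -> error
  zero <- mk_pep(matrix(0L, 2, 1, dimnames = list(c("P1", "P2"))), c(5, 5))
  expect_error(normalize_abundance(zero), "normalizer undefined")
})

test_that("the normalizer scales linearly even though emPAI does not", {
  obs <- matrix(c(2, 4, 8), 3, 1, dimnames = list(paste0("P", 1:3)))
  n1 <- normalize_abundance(mk_pep(obs, rep(20, 3)))$normalizer
  n2 <- normalize_abundance(mk_pep(obs * 2, rep(20, 3)))$normalizer
  expect_equal(n2, 2 * n1)
})

test_that("de_proteins applies presence and fold rules", {
  genes <- paste0("P", 1:4)
  base <- matrix(5L, 4, 3, dimnames = list(genes))
  obs_h <- base; obs_l <- base
  # P1: observed in exactly 1 of 3 high reps, 0 low reps -> excluded
  obs_h["P1", ] <- c(3L, 0L, 0L); obs_l["P1", ] <- 0L
  # P2: clear up-shift, present everywhere
  obs_h["P2", ] <- c(16L, 15L, 17L)
  # P3: present high, absent low -> unbounded up
  obs_h["P3", ] <- c(6L, 7L, 5L); obs_l["P3", ] <- c(0L, 2L, 0L)
  de <- de_proteins(mk_pep(obs_h, rep(20, 4)), mk_pep(obs_l, rep(20, 4)))
  expect_false("P1" %in% de$entity)
  expect_true(all(c("P2", "P3") %in% de$entity))
  expect_equal(de$direction[de$entity == "P2"], "up")
  expect_false(de$unbounded[de$entity == "P2"])
  expect_true(de$unbounded[de$entity == "P3"])
  expect_equal(de$log2fc[de$entity == "P3"], Inf)
})

test_that("a constructed ratio-2.9 protein is included up", {
  # one protein with clean counts; two fillers keep the normalizer sane.
  # hand computation: emPAI ratio of means is checked explicitly below.
  obs_h <- matrix(c(24L, 24L, 24L, 6L, 6L, 6L, 6L, 6L, 6L), 3, 3,
                  byrow = TRUE, dimnames = list(paste0("P", 1:3)))
  obs_l <- matrix(c(12L, 12L, 12L, 6L, 6L, 6L, 6L, 6L, 6L), 3, 3,
                  byrow = TRUE, dimnames = list(paste0("P", 1:3)))
  h <- mk_pep(obs_h, c(30, 30, 30)); l <- mk_pep(obs_l, c(30, 30, 30))
  nh <- normalize_abundance(h); nl <- normalize_abundance(l)
  ratio <- mean(nh$abundance["P1", ]) / mean(nl$abundance["P1", ])
  hand <- (empai(24, 30) / (24 * 6 * 6)^(1 / 3)) /
    (empai(12, 30) / (12 * 6 * 6)^(1 / 3))
  expect_equal(ratio, hand, tolerance = 1e-12)
  expect_gt(ratio, 2.7)  # ~2.8 by construction, well above the gate
  de <- de_proteins(h, l)
  expect_true("P1" %in% de$entity)
  expect_equal(de$direction[de$entity == "P1"], "up")
  expect_equal(de$log2fc[de$entity == "P1"], log2(ratio))
})

test_that("equal tables give an empty protein list", {
  obs <- matrix(5L, 3, 3, dimnames = list(paste0("P", 1:3)))
  de <- de_proteins(mk_pep(obs, rep(10, 3)), mk_pep(obs, rep(10, 3)))
  expect_equal(nrow(de), 0L)
})

test_that("de_proteins is symmetric under swapping populations", {
  set.seed(3)
  for (rep in 1:10) {
    genes <- paste0("P", 1:40)
    obs_h <- matrix(rbinom(120, 20, runif(40, 0.05, 0.8)), 40, 3,
                    dimnames = list(genes))
    obs_l <- matrix(rbinom(120, 20, runif(40, 0.05, 0.8)), 40, 3,
                    dimnames = list(genes))
    h <- mk_pep(obs_h, rep(20, 40)); l <- mk_pep(obs_l, rep(20, 40))
    ab <- de_proteins(h, l)
    ba <- de_proteins(l, h)
    expect_setequal(ab$entity, ba$entity)
    m <- match(ab$entity, ba$entity)
    expect_equal(ab$log2fc, -ba$log2fc[m])
    expect_equal(ab$direction,
                 ifelse(ba$direction[m] == "up", "down", "up"))
  }
})

test_that("replicate counts other than 3 warn and generalize", {
  genes <- c("P1", "P2")
  obs_h <- matrix(c(8L, 8L, 8L, 8L, 2L, 2L, 2L, 2L), 2, 4, byrow = TRUE,
                  dimnames = list(genes))
  obs_l <- matrix(2L, 2, 4, dimnames = list(genes))
  expect_warning(de_proteins(mk_pep(obs_h, c(10, 10)),
                             mk_pep(obs_l, c(10, 10))), "generalized")
})

test_that("build_six_lists returns 6 uniquely labelled lists", {
  empty_t <- de_transcripts(
    matrix(0, 2, 2, dimnames = list(c("A", "B"))),
    matrix(0, 2, 2, dimnames = list(c("A", "B"))))
  per_line <- lapply(c(l1 = 1, l2 = 2, l3 = 3), function(i)
    list(transcript = empty_t, protein = empty_t))
  six <- build_six_lists(per_line)
  expect_length(six, 6L)
  expect_false(anyDuplicated(names(six)) > 0)
  expect_error(build_six_lists(per_line[1:2]), "3 cell lines")
})
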