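# Independent Weir-Cockerham oracle: direct variance-components evaluation
# with the general r-population formulas, plain loops, no shared code with
# the package implementation.
wc_theta_oracle <- function(a1, a2, pop) {
  num <- den <- 0
  for (l in seq_len(nrow(a1))) {
    ok <- !is.na(a1[l, ]) & !is.na(a2[l, ])
    g1 <- a1[l, ok]; g2 <- a2[l, ok]; pp <- pop[ok]
    pops <- unique(pop)
    n_i <- sapply(pops, function(p) sum(pp == p))
    if (any(n_i < 2)) next
    r <- length(pops)
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in 0:2) {
      p_i <- sapply(pops, function(p) {
        sum(c(g1[pp == p], g2[pp == p]) == al) / (2 * sum(pp == p))
      })
      h_i <- sapply(pops, function(p) {
        mean(((g1 == al) + (g2 == al))[pp == p] == 1)
      })
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

test_that("theta matches a brute-force variance-components oracle exactly", {
  # 2 populations, 2 loci, 4 individuals each, multi-allelic with hets
  a1 <- matrix(c(0L, 0L, 1L, 1L, 1L, 2L, 1L, 2L,
                 1L, 0L, 1L, 1L, 2L, 2L, 1L, 1L), 2, 8, byrow = TRUE)
  a2 <- matrix(c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 2L,
                 1L, 1L, 1L, 0L, 2L, 1L, 2L, 2L), 2, 8, byrow = TRUE)
  pop <- rep(c("X", "Y"), each = 4)
  man <- manifest_for(sprintf("S%03d", 1:8), pop)
  g <- geno_from(a1, a2)
  est <- pairwise_fst(g, man, "X", "Y")
  expect_equal(est$theta, wc_theta_oracle(a1, a2, pop), tolerance = 1e-12)
  # audit components reproduce the ratio of sums
  expect_equal(est$theta,
               sum(est$components$a) /
                 sum(est$components$a + est$components$b + est$components$c),
               tolerance = 1e-15)
})

test_that("theta is ~0 for identical populations and exactly 1 for fixed difference", {
  set.seed(11)
  a1 <- matrix(sample(0:1, 200 * 40, TRUE), 200, 40)
  a2 <- matrix(sample(0:1, 200 * 40, TRUE), 200, 40)
  man <- manifest_for(sprintf("S%03d", 1:40), rep(c("X", "Y"), each = 20))
  g <- geno_from(a1, a2)
  expect_lt(abs(pairwise_fst(g, man, "X", "Y")$theta), 0.02)

  a1f <- matrix(rep(c(0L, 1L), each = 10), 50, 20, byrow = TRUE)
  gf <- geno_from(a1f, a1f)
  manf <- manifest_for(sprintf("S%03d", 1:20), rep(c("X", "Y"), each = 10))
  expect_identical(pairwise_fst(gf, manf, "X", "Y")$theta, 1)
})

test_that("theta is symmetric in its arguments and errors on degenerate input", {
  set.seed(5)
  a1 <- matrix(sample(0:2, 50 * 20, TRUE), 50, 20)
  a2 <- matrix(sample(0:2, 50 * 20, TRUE), 50, 20)
  man <- manifest_for(sprintf("S%03d", 1:20), rep(c("X", "Y"), each = 10))
  g <- geno_from(a1, a2)
  expect_identical(pairwise_fst(g, man, "X", "Y")$theta,
                   pairwise_fst(g, man, "Y", "X")$theta)
  man1 <- man; man1$population[2:10] <- "Z"
  expect_error(pairwise_fst(g, man1, "X", "Y"), "at least 2")
  mono <- geno_from(matrix(1L, 10, 20), matrix(1L, 10, 20))
  expect_error(pairwise_fst(mono, man, "X", "Y"), "polymorphic")
})

test_that("label permutation of one panmictic population centres theta on 0", {
  set.seed(23)
  n <- 30; L <- 60
  p <- runif(L, 0.2, 0.8)
  a1 <- matrix(as.integer(runif(L * n) < p), L, n)
  a2 <- matrix(as.integer(runif(L * n) < p), L, n)
  g <- geno_from(a1, a2)
  thetas <- vapply(1:200, function(i) {
    lab <- sample(rep(c("X", "Y"), each = n / 2))
    man <- manifest_for(g$samples, lab)
    pairwise_fst(g, man, "X", "Y")$theta
  }, numeric(1))
  expect_lt(abs(mean(thetas)), 0.01)
})

test_that("all-pairs F_ST gives a symmetric zero-diagonal matrix", {
  sim <- simulate_cnv_study(sim_config(n_loci = 80, seed = 3))
  g <- code_biallelic(sim$states)
  fm <- fst_all_pairs(g, sim$manifest)
  expect_identical(fm$matrix, t(fm$matrix))
  expect_true(all(diag(fm$matrix) == 0))
  expect_true(all(fm$matrix <= 1 & fm$matrix >= -0.1))
  expect_identical(nrow(fm$pairs), 3L)
})

test_that("ancestry-informativeness binning follows the delta/rare rule", {
  freqs <- tibble::tibble(
    cnvr_id = c("R1", "R2", "R3", "R4"),
    f_og  = c(0.50, 0.30, 0.40, 0.02),
    f_ind = c(0.48, 0.00, 0.38, 0.01),
    f_afr_Y = c(0.05, 0.00, 0.42, 0.01)
  )
  out <- classify_aic(freqs)
  expect_identical(out$class, c("indian_close", "unique", "unassigned",
                                "unassigned"))
  expect_equal(out$d_ind, abs(freqs$f_og - freqs$f_ind))
  # mirrored frequencies preserve distance-based classes
  mirrored <- dplyr::mutate(freqs[c(1, 3), ],
                            f_og = 1 - f_og, f_ind = 1 - f_ind,
                            f_afr_Y = 1 - f_afr_Y)
  expect_identical(classify_aic(mirrored)$class, out$class[c(1, 3)])
  # African side classified symmetrically
  afr <- tibble::tibble(f_og = 0.5, f_ind = 0.05, f_afr_Y = 0.52)
  expect_identical(classify_aic(afr)$class, "african_close")
  expect_error(classify_aic(tibble::tibble(f_og = 1.2, f_ind = 0,
                                           f_afr_Y = 0)), "0, 1")
})

test_that("African ancestor frequencies aggregate by mean or max", {
  freqs <- tibble::tibble(f_og = 0.5, f_ind = 0.0,
                          f_afr_YRI = 0.2, f_afr_LWK = 0.6)
  expect_equal(classify_aic(freqs)$f_afr, 0.4)
  expect_equal(classify_aic(freqs, afr_summary = "max")$f_afr, 0.6)
})

test_that("ancestry frequency table uses class-matched matrices and drops gain_loss", {
  man <- dplyr::bind_rows(
    manifest_for(c("O1", "O2", "O3", "O4"), "OG", "admixed"),
    manifest_for(c("I1", "I2"), "LP4", "ancestral_indian"),
    manifest_for(c("Y1", "Y2"), "YRI", "ancestral_african")
  )
  segs <- dplyr::bind_rows(
    # R1: deletion carried by 2/4 OG, 1/2 LP4
    purrr::map_dfr(c("O1", "O2", "I1"),
                   ~seg_row(sample_id = .x, start = 1000L, end = 5000L)),
    # R2: duplication in OG only
    seg_row(sample_id = "O1", start = 50000L, end = 60000L, cn_state = 3L),
    # R3: gain-loss (mixed states) must be excluded
    seg_row(sample_id = "O1", start = 200000L, end = 210000L, cn_state = 1L),
    seg_row(sample_id = "Y1", start = 205000L, end = 215000L, cn_state = 3L)
  )
  cn <- build_cnvrs(segs, man, min_freq = 0)
  ft <- cnvr_ancestry_freqs(cn, man)
  expect_identical(nrow(ft), 2L)
  r1 <- ft[ft$class == "del", ]
  expect_equal(r1$f_og, 0.5)
  expect_equal(r1$f_ind, 0.5)
  r2 <- ft[ft$class == "dup", ]
  expect_equal(r2$f_og, 0.25)
  expect_equal(r2$f_afr_YRI, 0)
})

test_that("population-specific CNVR detection splits specific from private", {
  man <- dplyr::bind_rows(
    manifest_for(c("O1", "O2", "O3"), "OG", "admixed"),
    manifest_for(c("I1", "I2"), "LP4", "ancestral_indian"),
    manifest_for(c("Y1", "Y2"), "YRI", "ancestral_african"),
    manifest_for(c("C1", "C2"), "CEU", "other")
  )
  segs <- dplyr::bind_rows(
    # R1: OG only -> specific and strictly private
    purrr::map_dfr(c("O1", "O2", "O3"),
                   ~seg_row(sample_id = .x, start = 1000L, end = 5000L)),
    # R2: OG + CEU -> specific (ancestors clean) but not private
    seg_row(sample_id = "O1", start = 50000L, end = 55000L),
    seg_row(sample_id = "C1", start = 52000L, end = 56000L),
    # R3: YRI only -> neither
    seg_row(sample_id = "Y1", start = 100000L, end = 105000L)
  )
  cn <- build_cnvrs(segs, man, min_freq = 0)
  res <- og_specific_cnvrs(cn, man)
  ids <- cn$regions$cnvr_id[order(cn$regions$start)]
  expect_setequal(res$specific_ids, ids[1:2])
  expect_identical(res$strictly_private_ids, ids[1])
  expect_true(all(res$strictly_private_ids %in% res$specific_ids))
  expect_error(og_specific_cnvrs(cn, man, "nope"), "population")
})
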