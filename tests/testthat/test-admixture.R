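# Simulated genotypes where component 1 is fixed for haploid allele 1 and
# component 2 for allele 0 at every locus; admixed copies pick a component
# by coin flip with the given weight.
opposite_fixed_geno <- function(n_anc = 10, n_adm = 30, n_loci = 500,
                                w = 0.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_anc + n_adm
  draw_copy <- function() {
    cbind(matrix(1L, n_loci, n_anc), matrix(0L, n_loci, n_anc),
          matrix(as.integer(runif(n_loci * n_adm) < w), n_loci, n_adm))
  }
  a1 <- draw_copy(); a2 <- draw_copy()
  samples <- c(sprintf("A%02d", 1:n_anc), sprintf("B%02d", 1:n_anc),
               sprintf("M%02d", 1:n_adm))
  list(geno = geno_from(a1, a2, samples = samples),
       manifest = tibble::tibble(
         sample_id = samples,
         population = rep(c("PA", "PB", "PM"), c(n_anc, n_anc, n_adm)),
         role = rep(c("ancestral_indian", "ancestral_african", "admixed"),
                    c(n_anc, n_anc, n_adm))
       ))
}

test_that("K = 1 reduces to observed allele frequencies in one iteration", {
  set.seed(3)
  a1 <- matrix(sample(0:2, 60, TRUE), 20, 3)
  a2 <- matrix(sample(0:2, 60, TRUE), 20, 3)
  fit <- fit_admixture(geno_from(a1, a2), K = 1, n_restarts = 1)
  expect_true(all(fit$Q == 1))
  expect_identical(fit$n_iter, 1L)
  obs <- t(vapply(seq_len(20), function(l) {
    al <- c(a1[l, ], a2[l, ])
    tabulate(al + 1L, 3L) / length(al)
  }, numeric(3)))
  expect_equal(unname(fit$P[, 1, ]), obs, tolerance = 1e-12)
})

test_that("EM recovers 50/50 admixture between opposite-fixed components", {
  d <- opposite_fixed_geno(w = 0.5, seed = 5)
  fit <- fit_admixture(d$geno, K = 2, n_restarts = 2, max_iter = 200,
                       tol = 1e-4, seed = 2)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  fit <- align_components(fit, d$manifest, c("PA", "PB"))
  means <- mean_ancestry_by_population(fit, d$manifest)
  adm <- as.numeric(means[means$population == "PM", -1])
  expect_lt(max(abs(adm - 0.5)), 0.05)
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-8))
  expect_true(all(abs(apply(fit$P, c(1, 2), sum) - 1) < 1e-8))
})

test_that("ancestry recovery on Balding-Nichols admixture has low error", {
  cfg <- sim_config(n_loci = 600, theta = 0.2, seed = 19,
                    populations = tibble::tibble(
                      label = c("IND", "AFR", "ADM"),
                      role = c("ancestral_indian", "ancestral_african", "admixed"),
                      n_samples = c(30L, 30L, 40L),
                      component = c(1L, 2L, NA)))
  sim <- simulate_cnv_study(cfg)
  fit <- fit_admixture(code_biallelic(sim$states), K = 2, n_restarts = 2,
                       max_iter = 250, tol = 1e-4, seed = 4)
  fit <- align_components(fit, sim$manifest, c("IND", "AFR"))
  adm <- sim$manifest$role == "admixed"
  rmse <- sqrt(mean((fit$Q[adm, ] - sim$truth$true_Q[adm, ])^2))
  expect_lt(rmse, 0.08)
})

test_that("restarts agree on the attained likelihood for well-separated data", {
  d <- opposite_fixed_geno(n_anc = 8, n_adm = 15, n_loci = 200, seed = 9)
  f1 <- fit_admixture(d$geno, K = 2, n_restarts = 2, max_iter = 300,
                      tol = 1e-6, seed = 100)
  f2 <- fit_admixture(d$geno, K = 2, n_restarts = 2, max_iter = 300,
                      tol = 1e-6, seed = 200)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-3)
})

test_that("missing copies are ignored and all-missing loci dropped", {
  a1 <- matrix(c(0L, NA, 1L, NA), 2, 2) # second locus missing everywhere
  a2 <- matrix(c(0L, NA, 1L, NA), 2, 2)
  expect_warning(fit <- fit_admixture(geno_from(a1, a2), K = 1, n_restarts = 1),
                 "dropping")
  expect_length(fit$loci, 1L)
  expect_error(fit_admixture(geno_from(a1, a2), K = 5), "exceed")
})

test_that("supervised fit pins flagged ancestral rows to unit vectors", {
  d <- opposite_fixed_geno(n_anc = 6, n_adm = 10, n_loci = 100, seed = 3)
  n <- length(d$geno$samples)
  fx <- matrix(NA_real_, n, 2)
  anc1 <- d$manifest$role == "ancestral_indian"
  anc2 <- d$manifest$role == "ancestral_african"
  fx[anc1, ] <- rep(c(1, 0), each = sum(anc1))
  fx[anc2, ] <- rep(c(0, 1), each = sum(anc2))
  fit <- fit_admixture(d$geno, K = 2, n_restarts = 1, max_iter = 100,
                       fixed_Q = fx, seed = 1)
  expect_identical(unname(fit$Q[anc1, 1]), rep(1, sum(anc1)))
  expect_identical(unname(fit$Q[anc2, 2]), rep(1, sum(anc2)))
})

test_that("population means are exact for constant Q and permutation-equivariant", {
  Q <- rbind(matrix(c(0.7, 0.3), 4, 2, byrow = TRUE),
             matrix(c(0.2, 0.8), 2, 2, byrow = TRUE))
  samples <- sprintf("S%d", 1:6)
  fit <- structure(list(
    Q = `dimnames<-`(Q, list(samples, c("K1", "K2"))),
    P = array(0.5, c(1, 2, 3)), K = 2L, samples = samples,
    loci = "L1", component_labels = c("K1", "K2")
  ), class = "admixture_fit")
  man <- manifest_for(samples, rep(c("PX", "PY"), c(4, 2)))
  means <- mean_ancestry_by_population(fit, man)
  expect_equal(as.numeric(means[means$population == "PX", -1]), c(0.7, 0.3))
  expect_equal(unname(rowSums(as.matrix(means[, -1]))), c(1, 1))
  # permuting components permutes the table columns identically
  fit2 <- fit
  fit2$Q <- fit$Q[, 2:1]
  means2 <- mean_ancestry_by_population(fit2, man)
  expect_equal(means2$K2, means$K2)
  expect_error(mean_ancestry_by_population(fit, man[-1, ]), "absent")
})

test_that("component alignment is optimal, idempotent, and bounded by K", {
  d <- opposite_fixed_geno(n_anc = 6, n_adm = 8, n_loci = 150, seed = 7)
  fit <- fit_admixture(d$geno, K = 2, n_restarts = 2, max_iter = 200, seed = 5)
  al1 <- align_components(fit, d$manifest, c("PA", "PB"))
  means <- mean_ancestry_by_population(al1, d$manifest)
  expect_gt(means$PA[means$population == "PA"], 0.9)
  expect_gt(means$PB[means$population == "PB"], 0.9)
  al2 <- align_components(al1, d$manifest, c("PA", "PB"))
  expect_identical(al1$Q, al2$Q)

  # the chosen assignment attains the exhaustive-search maximum
  M <- as.matrix(mean_ancestry_by_population(fit, d$manifest)[, -1])
  rownames(M) <- mean_ancestry_by_population(fit, d$manifest)$population
  best <- max(M["PA", 1] + M["PB", 2], M["PA", 2] + M["PB", 1])
  Ma <- as.matrix(means[, -1])
  rownames(Ma) <- means$population
  expect_equal(Ma["PA", 1] + Ma["PB", 2], best)

  expect_error(align_components(fit, d$manifest, c("PA", "PB", "PM")), "more reference")
})

test_that("tidy and glance expose the fit in broom style", {
  d <- opposite_fixed_geno(n_anc = 4, n_adm = 4, n_loci = 50, seed = 2)
  fit <- fit_admixture(d$geno, K = 2, n_restarts = 1, max_iter = 50, seed = 1)
  td <- tidy(fit)
  expect_identical(nrow(td), 2L * length(d$geno$samples))
  expect_true(all(c("sample_id", "component", "proportion") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$K, 2L)
  expect_identical(gl$n_loci, 50L)
})
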