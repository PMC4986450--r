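# Maximum-likelihood admixture estimation by EM. Model: each of an
# individual's two allele copies at locus l is drawn from ancestral
# component k with probability q_ik, then takes allele a (a haploid copy
# count in {0,1,2}) with probability p_lka. EM alternates closed-form
# responsibilities for (copy -> component) with Q and P updates; the
# observed-data log-likelihood is non-decreasing every iteration. This is
# the point-estimation counterpart of Bayesian admixture clustering
# (STRUCTURE-style), on the same likelihood, without priors.

#' Fit an admixture model to biallelic CNV genotypes
#'
#' Estimates per-individual ancestry proportions Q (individuals x K) and
#' per-component allele frequencies P (loci x K x alleles) by
#' expectation--maximisation, with multiple seeded restarts; the restart
#' with the best log-likelihood is returned. Missing allele copies
#' contribute nothing to the likelihood; loci missing in every individual
#' are dropped with a warning.
#'
#' @param genotypes A `cnv_genotypes` object (alleles in \{0, 1, 2\}).
#' @param K Number of ancestral components (>= 1).
#' @param n_restarts Number of random restarts (default 10).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param fixed_Q Optional supervision: an individuals x K matrix whose
#'   non-`NA` rows (typically unit vectors for known ancestral samples)
#'   are held fixed through every update; rows of `NA` are estimated
#'   freely. Default `NULL` = fully unsupervised.
#' @return An `admixture_fit`: `Q`, `P`, `loglik`, `loglik_trace`
#'   (best restart), `K`, `seed`, `converged`, `n_iter`, `samples`,
#'   `loci`, `component_labels`.
#' @export
fit_admixture <- function(genotypes, K, n_restarts = 10L, max_iter = 500L,
                          tol = 1e-5, seed = 1L, fixed_Q = NULL) {
  stopifnot(inherits(genotypes, "cnv_genotypes"))
  assert_scalar_number(K, "K", 1)
  K <- as.integer(K)
  N <- length(genotypes$samples)
  if (K > N) abort("K cannot exceed the number of individuals.")
  G <- cbind(genotypes$a1, genotypes$a2) # loci x 2N; copy c of sample i in col i + (c-1)N
  keep <- rowSums(!is.na(G)) > 0L
  if (!all(keep)) {
    warn(sprintf("dropping %d locus/loci with no observed genotype.", sum(!keep)))
    G <- G[keep, , drop = FALSE]
  }
  loci <- genotypes$loci[keep]
  L <- nrow(G)
  if (L == 0L) abort("no locus with observed genotypes.")
  if (!all(G[!is.na(G)] %in% 0:2)) abort("alleles must be haploid copy counts in 0..2.")
  if (!is.null(fixed_Q)) {
    if (!is.matrix(fixed_Q) || nrow(fixed_Q) != N || ncol(fixed_Q) != K) {
      abort("`fixed_Q` must be an individuals x K matrix (NA rows are free).")
    }
  }

  idx <- rep(seq_len(N), 2L)          # column -> individual
  obs <- !is.na(G)
  copies_per_ind <- as.numeric(rowsum(colSums(obs), idx))
  # flat representation of observed copies: locus, individual, allele
  ridx <- row(G)[obs]                 # locus of each observed copy
  qidx <- idx[col(G)[obs]]            # individual of each observed copy
  gidx <- G[obs] + 1L                 # allele (1-based) of each observed copy
  rfac <- factor(ridx, levels = seq_len(L))
  qfac <- factor(qidx, levels = seq_len(N))
  allele_mask <- lapply(1:3, function(a) gidx == a)
  obs_per_locus <- as.vector(table(rfac))
  obs_freq <- vapply(1:3, function(a) {
    as.vector(rowsum(as.numeric(allele_mask[[a]]), rfac)) / pmax(obs_per_locus, 1L)
  }, numeric(L)) # L x 3 observed allele frequencies

  run_one <- function(restart_seed) {
    set.seed(restart_seed)
    if (K == 1L) {
      Q <- matrix(1, N, 1L)
      P <- array(obs_freq, dim = c(L, 1L, 3L))
      ll <- sum(log(pmax(obs_freq[cbind(ridx, gidx)], .Machine$double.xmin)))
      return(list(Q = Q, P = P, trace = ll, converged = TRUE, n_iter = 1L))
    }
    Q <- t(vapply(seq_len(N), function(i) rdirichlet1(rep(1, K)), numeric(K)))
    P <- array(0, dim = c(L, K, 3L))
    for (k in seq_len(K)) {
      pk <- obs_freq * exp(matrix(rnorm(L * 3L, 0, 0.35), L, 3L))
      pk <- pk + 1e-4
      P[, k, ] <- pk / rowSums(pk)
    }
    if (!is.null(fixed_Q)) {
      fx <- !is.na(fixed_Q[, 1L])
      Q[fx, ] <- fixed_Q[fx, , drop = FALSE]
    }
    trace <- numeric(0)
    converged <- FALSE
    it <- 0L
    pidx <- cbind(ridx, gidx)
    repeat {
      it <- it + 1L
      # E-step over the flat vector of observed copies
      num <- matrix(0, length(ridx), K)
      for (k in seq_len(K)) {
        num[, k] <- P[, k, ][pidx] * Q[qidx, k]
      }
      den <- rowSums(num)
      ll <- sum(log(pmax(den, .Machine$double.xmin)))
      trace <- c(trace, ll)
      if (it > 1L && ll - trace[it - 1L] < tol) {
        converged <- TRUE
        break
      }
      if (it >= max_iter) break
      # M-step: closed-form updates from responsibilities
      resp <- num / den
      Qnew <- rowsum(resp, qfac) / copies_per_ind
      for (k in seq_len(K)) {
        for (a in 1:3) {
          P[, k, a] <- rowsum(resp[, k] * allele_mask[[a]], rfac)
        }
        psum <- rowSums(P[, k, , drop = TRUE])
        P[, k, ] <- (P[, k, , drop = TRUE] + 1e-12) / (psum + 3e-12)
      }
      Q <- pmax(Qnew, 1e-12)
      Q <- Q / rowSums(Q)
      if (!is.null(fixed_Q)) {
        fx <- !is.na(fixed_Q[, 1L])
        Q[fx, ] <- fixed_Q[fx, , drop = FALSE]
      }
    }
    list(Q = Q, P = P, trace = trace, converged = converged, n_iter = it)
  }

  fits <- lapply(seq_len(max(1L, n_restarts)), function(r) run_one(as.integer(seed) + r - 1L))
  best <- fits[[which.max(vapply(fits, function(f) max(f$trace), 0))]]
  dimnames(best$Q) <- list(genotypes$samples, paste0("K", seq_len(K)))
  dimnames(best$P) <- list(loci, paste0("K", seq_len(K)), paste0("allele", 0:2))
  structure(list(
    Q = best$Q, P = best$P, loglik = max(best$trace),
    loglik_trace = best$trace, K = K, seed = as.integer(seed),
    converged = best$converged, n_iter = best$n_iter,
    samples = genotypes$samples, loci = loci,
    component_labels = paste0("K", seq_len(K))
  ), class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K = %d, %d individuals, %d loci, loglik %.2f (%s after %d iterations)\n",
              x$K, nrow(x$Q), length(x$loci), x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Long tidy view of estimated ancestry proportions
#'
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (sample, component): `sample_id`,
#'   `component`, `proportion`.
#' @export
tidy.admixture_fit <- function(x, ...) {
  as_tibble(x$Q, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "component",
                        values_to = "proportion")
}

#' One-row model summary of an admixture fit
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return A tibble: `K`, `n_individuals`, `n_loci`, `loglik`, `n_iter`,
#'   `converged`.
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(K = x$K, n_individuals = nrow(x$Q), n_loci = length(x$loci),
         loglik = x$loglik, n_iter = x$n_iter, converged = x$converged)
}

#' Mean ancestry proportions per population
#'
#' @param fit An `admixture_fit`.
#' @param manifest Sample manifest covering every fitted individual.
#' @return A tibble with one row per population and one column per
#'   component; component columns sum to 1 by row.
#' @export
mean_ancestry_by_population <- function(fit, manifest) {
  stopifnot(inherits(fit, "admixture_fit"))
  unknown <- setdiff(fit$samples, manifest$sample_id)
  if (length(unknown) > 0L) {
    abort(sprintf("fitted sample(s) absent from manifest: %s.",
                  paste(unknown, collapse = ", ")))
  }
  pop <- manifest$population[match(fit$samples, manifest$sample_id)]
  means <- rowsum(fit$Q, pop) / as.vector(table(pop)[sort(unique(pop))])
  means <- means[unique(pop), , drop = FALSE]
  dplyr::bind_cols(tibble(population = rownames(means)),
                   as_tibble(means))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Resolve label switching by aligning components to reference populations
#'
#' Components of an admixture fit are identifiable only up to permutation.
#' This permutes them so that reference population r's mean ancestry is
#' maximal on component r, choosing the injective assignment that
#' maximises the summed mean ancestry of each reference population on its
#' assigned component. Deterministic; applying it twice equals applying it
#' once.
#'
#' @param fit An `admixture_fit`.
#' @param manifest Sample manifest.
#' @param reference_pops Character vector (length <= K) of population
#'   labels, one per expected component, in the desired component order.
#'   Components beyond the references keep their relative order and stay
#'   unlabelled.
#' @return The fit with `Q` and `P` columns permuted and
#'   `component_labels` set to the reference populations (then `K<j>` for
#'   unassigned components).
#' @export
align_components <- function(fit, manifest, reference_pops) {
  stopifnot(inherits(fit, "admixture_fit"))
  R <- length(reference_pops)
  if (R > fit$K) abort("more reference populations than components.")
  means <- mean_ancestry_by_population(fit, manifest)
  M <- as.matrix(means[, -1L, drop = FALSE])
  rownames(M) <- means$population
  missing_pops <- setdiff(reference_pops, rownames(M))
  if (length(missing_pops) > 0L) {
    abort(sprintf("reference population(s) not in fit: %s.",
                  paste(missing_pops, collapse = ", ")))
  }
  # best injective assignment reference r -> component, by exhaustive search
  # over permutations (K is small)
  perms <- all_permutations(fit$K)
  ref_rows <- match(reference_pops, rownames(M))
  score <- vapply(perms, function(p) {
    sum(M[cbind(ref_rows, p[seq_len(R)])])
  }, numeric(1))
  best <- perms[[which.max(score)]]
  # components not assigned to a reference keep ascending original order
  rest <- setdiff(seq_len(fit$K), best[seq_len(R)])
  perm <- c(best[seq_len(R)], sort(rest))
  fit$Q <- fit$Q[, perm, drop = FALSE]
  fit$P <- fit$P[, perm, , drop = FALSE]
  fit$component_labels <- c(reference_pops,
                            paste0("K", sort(rest)))[seq_len(fit$K)]
  colnames(fit$Q) <- fit$component_labels
  dimnames(fit$P)[[2L]] <- fit$component_labels
  fit
}

#' Stacked-bar plot of individual ancestry proportions
#'
#' The conventional admixture bar plot: one bar per individual, stacked by
#' component, grouped by population.
#'
#' @param object An `admixture_fit`.
#' @param manifest Optional manifest for population facets.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.admixture_fit <- function(object, manifest = NULL, ...) {
  long <- tidy(object)
  if (!is.null(manifest)) {
    long <- dplyr::left_join(long, manifest[, c("sample_id", "population")],
                             by = "sample_id")
  } else {
    long$population <- "all"
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$proportion,
                                     fill = .data$component)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~population, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "Ancestry proportion", fill = "Component") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
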