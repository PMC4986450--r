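#' Simulation configuration for synthetic CNV study data
#'
#' Builds the configuration object consumed by [simulate_cnv_study()] and
#' its component steps. The defaults describe the study design the package
#' is organised around: two differentiated ancestral panels (an Indian-like
#' and an African-like component, Balding--Nichols `theta = 0.2`) and one
#' admixed population whose individual ancestry proportions are Dirichlet
#' with mean c(0.413, 0.587) -- i.e. a majority-African admixed group, as
#' estimated for the Siddi (OG) population that motivates this pipeline.
#'
#' @param n_loci Number of CNV loci to simulate.
#' @param populations Tibble with columns `label`, `role`, `n_samples` and
#'   `component` (the ancestral component index for ancestral-role
#'   populations; `NA` for admixed populations, whose ancestry is drawn per
#'   individual).
#' @param K Number of ancestral components.
#' @param theta Balding--Nichols differentiation parameter in (0, 1);
#'   approximately the F_ST between the ancestral components.
#' @param admix_alpha Dirichlet concentration vector (length `K`) for the
#'   per-individual ancestry of admixed samples. Default: `c(4.13, 5.87)`
#'   at `K = 2` (the study conditions above), flat `rep(1, K)` otherwise.
#' @param admix_Q Optional fixed ancestry proportions for admixed samples:
#'   a length-`K` vector (all admixed individuals identical) or a matrix
#'   with one row per admixed individual. Overrides `admix_alpha`.
#' @param frac_dup_loci Fraction of loci whose variant allele is a
#'   duplication; the remainder are deletions. The default reflects the
#'   strong excess of deletions over duplications typical of SNP-array CNV
#'   calls (roughly 7:1).
#' @param locus_size_range Range (bp) of simulated CNV locus sizes.
#' @param probe_spacing_bp Mean inter-probe distance on the simulated array.
#' @param lod_mean,lod_sd Parameters of the LOD-score emission for true
#'   segments (reflected at the LOD = 10 call floor).
#' @param noise_rates Named rates (relative to the number of true segments)
#'   of decoy segments, each violating exactly one quality filter:
#'   `low_probe`, `low_lod`, `oversized`, `gapped`, `non_autosomal`.
#' @param seed Integer seed; every draw in the generator descends from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 500,
                       populations = default_sim_populations(),
                       K = 2,
                       theta = 0.2,
                       admix_alpha = NULL,
                       admix_Q = NULL,
                       frac_dup_loci = 0.125,
                       locus_size_range = c(10e3, 100e3),
                       probe_spacing_bp = 2000,
                       lod_mean = 30, lod_sd = 8,
                       noise_rates = c(low_probe = 0, low_lod = 0,
                                       oversized = 0, gapped = 0,
                                       non_autosomal = 0),
                       seed = 1L) {
  assert_scalar_number(theta, "theta", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(frac_dup_loci, "frac_dup_loci", 0, 1)
  assert_scalar_number(n_loci, "n_loci", 1)
  # default emulates a majority-African admixed group at K = 2 (mean
  # ancestry 0.413/0.587); flat Dirichlet otherwise
  admix_alpha <- admix_alpha %||% (if (K == 2) c(4.13, 5.87) else rep(1, K))
  if (length(admix_alpha) != K || any(admix_alpha <= 0)) {
    abort("`admix_alpha` must be a strictly positive vector of length K.")
  }
  populations <- as_tibble(populations)
  assert_columns(populations, c("label", "role", "n_samples", "component"),
                 "populations table")
  if (sum(populations$n_samples) < 2L) abort("need at least 2 samples in total.")
  anc <- populations[populations$role != "admixed", ]
  if (any(is.na(anc$component)) || any(anc$component > K)) {
    abort("non-admixed populations need a `component` index in 1..K.")
  }
  rates <- c(low_probe = 0, low_lod = 0, oversized = 0, gapped = 0,
             non_autosomal = 0)
  rates[names(noise_rates)] <- noise_rates
  if (any(rates < 0)) abort("noise_rates must be non-negative.")
  structure(list(
    n_loci = as.integer(n_loci), populations = populations, K = as.integer(K),
    theta = theta, admix_alpha = admix_alpha, admix_Q = admix_Q,
    frac_dup_loci = frac_dup_loci, locus_size_range = locus_size_range,
    probe_spacing_bp = probe_spacing_bp, lod_mean = lod_mean, lod_sd = lod_sd,
    noise_rates = rates, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_sim_populations <- function() {
  tibble(
    label = c("IND", "AFR", "ADM"),
    role = c("ancestral_indian", "ancestral_african", "admixed"),
    n_samples = c(30L, 30L, 40L),
    component = c(1L, 2L, NA_integer_)
  )
}

#' Synthetic genome table for a simulation
#'
#' Four autosomes sized to hold the configured loci comfortably, plus one
#' non-autosomal chromosome (`chrX`) used only by non-autosomal decoys.
#'
#' @param config A [sim_config()].
#' @return A genome tibble (`chrom`, `length`, `is_autosome`).
#' @export
sim_genome <- function(config) {
  per_chrom <- ceiling(config$n_loci / 4)
  slot <- max(config$locus_size_range) + config$probe_spacing_bp + 60e3
  len <- max(60e6, per_chrom * slot + 2e6)
  tibble(
    chrom = c(paste0("chr", 1:4), "chrX"),
    length = c(rep(len, 4), 50e6),
    is_autosome = c(rep(TRUE, 4), FALSE)
  )
}

# Non-overlapping locus intervals, round-robin across autosomes, separated
# by at least one probe spacing so CNVR truth is unambiguous.
sim_loci <- function(config, genome) {
  set.seed(derive_seed(config$seed, "loci"))
  n <- config$n_loci
  autos <- genome$chrom[genome$is_autosome]
  chrom <- autos[((seq_len(n) - 1L) %% length(autos)) + 1L]
  sizes <- round(runif(n, config$locus_size_range[1], config$locus_size_range[2]))
  gaps <- round(config$probe_spacing_bp + runif(n, 5e3, 50e3))
  start <- integer(n)
  for (ch in autos) {
    idx <- which(chrom == ch)
    pos <- cumsum(gaps[idx] + sizes[idx]) - sizes[idx] + 1e4
    start[idx] <- as.integer(pos)
  }
  tibble(
    locus_id = sprintf("L%04d", seq_len(n)),
    chrom = chrom, start = start, end = as.integer(start + sizes)
  )
}

#' Simulate differentiated ancestral-component allele frequencies
#'
#' Balding--Nichols model: each locus draws an ancestral base frequency
#' p ~ Uniform(0.05, 0.95); each component k then draws its variant-allele
#' frequency from Beta(p(1-theta)/theta, (1-p)(1-theta)/theta), so the
#' expected differentiation among components is approximately `theta`.
#'
#' @param config A [sim_config()].
#' @return A `n_loci` x `K` matrix of variant-allele frequencies, with the
#'   base frequencies in attribute `base_freq`.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "frequencies"))
  theta <- config$theta
  p <- runif(config$n_loci, 0.05, 0.95)
  scale <- (1 - theta) / theta
  freqs <- vapply(seq_len(config$K), function(k) {
    rbeta(config$n_loci, p * scale, (1 - p) * scale)
  }, numeric(config$n_loci))
  freqs <- pmin(pmax(freqs, 1e-6), 1 - 1e-6)
  dimnames(freqs) <- list(sprintf("L%04d", seq_len(config$n_loci)),
                          paste0("K", seq_len(config$K)))
  attr(freqs, "base_freq") <- p
  freqs
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate diploid copy-number states for all individuals
#'
#' Each individual carries two haploid allele copies per locus. For an
#' ancestral-role individual both copies come from that population's
#' component; for an admixed individual each copy's component is drawn from
#' the individual's ancestry vector Q (Dirichlet unless fixed in the
#' config). A variant allele at a deletion locus contributes haploid copy 0
#' (vs reference 1), so the diploid state is 2 minus the variant-allele
#' count; at a duplication locus the variant allele contributes haploid
#' copy 2, so the state is 2 plus the variant-allele count.
#'
#' @param freqs Component frequency matrix from [simulate_frequencies()].
#' @param config The same [sim_config()].
#' @return A list: `states` (loci x samples integer matrix of diploid
#'   copy-number states 0--4), `manifest` (sample manifest tibble), and
#'   `truth` (a `sim_truth` list with `true_Q`, `true_freqs` per component,
#'   `pop_freqs` per population, `locus_class`, and `loci` intervals).
#' @export
simulate_individuals <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  if (ncol(freqs) != config$K) abort("K mismatch between freqs and config.")
  set.seed(derive_seed(config$seed, "individuals"))
  L <- nrow(freqs); K <- config$K
  pops <- config$populations
  n_total <- sum(pops$n_samples)

  manifest <- purrr::pmap_dfr(pops, function(label, role, n_samples, component) {
    tibble(sample_id = sprintf("%s_%03d", label, seq_len(n_samples)),
           population = label, role = role)
  })

  # per-individual ancestry
  Q <- matrix(0, n_total, K,
              dimnames = list(manifest$sample_id, colnames(freqs)))
  adm_seen <- 0L
  row0 <- 0L
  for (pi in seq_len(nrow(pops))) {
    n <- pops$n_samples[pi]
    rows <- row0 + seq_len(n)
    if (!is.na(pops$component[pi])) {
      Q[rows, pops$component[pi]] <- 1
    } else if (!is.null(config$admix_Q)) {
      fixed <- config$admix_Q
      if (is.matrix(fixed)) {
        Q[rows, ] <- fixed[adm_seen + seq_len(n), , drop = FALSE]
      } else {
        Q[rows, ] <- matrix(fixed, n, K, byrow = TRUE)
      }
      adm_seen <- adm_seen + n
    } else {
      Q[rows, ] <- t(vapply(seq_len(n), function(i) rdirichlet1(config$admix_alpha),
                            numeric(K)))
    }
    row0 <- row0 + n
  }
  Q <- Q / rowSums(Q)

  locus_class <- ifelse(runif(L) < config$frac_dup_loci, "dup", "del")

  # two allele copies per individual; each copy picks a component from Q_i
  n_var <- matrix(0L, L, n_total)
  for (i in seq_len(n_total)) {
    for (copy in 1:2) {
      z <- sample.int(K, L, replace = TRUE, prob = Q[i, ])
      v <- runif(L) < freqs[cbind(seq_len(L), z)]
      n_var[, i] <- n_var[, i] + as.integer(v)
    }
  }
  states <- matrix(2L, L, n_total,
                   dimnames = list(rownames(freqs), manifest$sample_id))
  del <- locus_class == "del"
  states[del, ] <- 2L - n_var[del, , drop = FALSE]
  states[!del, ] <- 2L + n_var[!del, , drop = FALSE]

  pop_of <- manifest$population
  pop_freqs <- vapply(unique(pop_of), function(p) {
    qbar <- colMeans(Q[pop_of == p, , drop = FALSE])
    as.numeric(freqs %*% qbar)
  }, numeric(L))
  rownames(pop_freqs) <- rownames(freqs)

  truth <- structure(list(
    true_Q = Q, true_freqs = freqs, pop_freqs = pop_freqs,
    locus_class = setNames(locus_class, rownames(freqs)),
    loci = sim_loci(config, sim_genome(config))
  ), class = "sim_truth")
  list(states = states, manifest = manifest, truth = truth)
}

#' Emit CNV segment calls (plus labelled decoys) from a state matrix
#'
#' Every non-normal cell of the state matrix becomes one segment spanning
#' its true locus interval, with probe count, maximum inter-probe gap, LOD
#' and confidence drawn so that every true segment passes the default
#' quality filters. Decoy segments -- each violating exactly one of the five
#' filter rules -- are appended at the configured `noise_rates`; their row
#' positions and classes are recorded in the returned truth, never in the
#' segment table itself.
#'
#' @param states,truth Output of [simulate_individuals()].
#' @param config The same [sim_config()].
#' @return A list: `segments` (segment tibble, true calls first, then
#'   decoys) and `truth` (input truth augmented with `decoys`, a tibble of
#'   decoy row indices and classes, and `n_true`).
#' @export
emit_segments <- function(states, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(derive_seed(config$seed, "segments"))
  loci <- truth$loci
  genome <- sim_genome(config)
  calls <- which(states != 2L, arr.ind = TRUE)
  n_true <- nrow(calls)
  mk_fields <- function(n, width) {
    n_probes <- pmax(5L, as.integer(round(width / config$probe_spacing_bp *
                                            runif(n, 0.8, 1.2))))
    max_gap <- as.integer(pmin(9999L, round(config$probe_spacing_bp *
                                              runif(n, 1.2, 3.5))))
    lod <- config$lod_mean + rnorm(n, 0, config$lod_sd)
    lod <- 10 + abs(lod - 10) # reflect at the call floor so LOD >= 10
    list(n_probes = n_probes, max_gap = max_gap, lod = round(lod, 2),
         confidence = round(runif(n, 0, 0.09), 4))
  }
  li <- calls[, "row"]
  width <- loci$end[li] - loci$start[li]
  f <- mk_fields(n_true, width)
  segs <- tibble(
    sample_id = colnames(states)[calls[, "col"]],
    chrom = loci$chrom[li],
    start = loci$start[li],
    end = loci$end[li],
    cn_state = as.integer(states[calls]),
    n_probes = f$n_probes, max_gap = f$max_gap, lod = f$lod,
    confidence = f$confidence
  )

  decoy_classes <- names(config$noise_rates)
  n_decoy <- as.integer(round(config$noise_rates * n_true))
  decoys <- purrr::map2_dfr(decoy_classes, n_decoy, function(cls, nd) {
    if (nd == 0L) return(tibble())
    tmpl_l <- sample.int(nrow(loci), nd, replace = TRUE)
    w <- loci$end[tmpl_l] - loci$start[tmpl_l]
    fd <- mk_fields(nd, w)
    d <- tibble(
      sample_id = sample(colnames(states), nd, replace = TRUE),
      chrom = loci$chrom[tmpl_l],
      start = loci$start[tmpl_l], end = loci$end[tmpl_l],
      cn_state = sample(c(0L, 1L, 3L, 4L), nd, replace = TRUE),
      n_probes = fd$n_probes, max_gap = fd$max_gap, lod = fd$lod,
      confidence = fd$confidence, decoy_class = cls
    )
    switch(cls,
      low_probe = { d$n_probes <- sample(1:4, nd, replace = TRUE); d },
      low_lod = { d$lod <- round(runif(nd, 0, 9.9), 2); d },
      oversized = {
        d$start <- 1e5 + as.integer(round(runif(nd, 0, 1e6)))
        d$end <- d$start + 1000000L + as.integer(round(runif(nd, 0, 5e5)))
        d
      },
      gapped = { d$max_gap <- as.integer(round(runif(nd, 10000, 30000))); d },
      non_autosomal = {
        d$chrom <- genome$chrom[!genome$is_autosome][1L]
        d
      }
    )
  })
  if (nrow(decoys) > 0L) {
    truth$decoys <- tibble(row = n_true + seq_len(nrow(decoys)),
                           class = decoys$decoy_class)
    decoys$decoy_class <- NULL
    segs <- dplyr::bind_rows(segs, decoys)
  } else {
    truth$decoys <- tibble(row = integer(), class = character())
  }
  truth$n_true <- n_true
  list(segments = segs, truth = truth)
}

#' Simulate a complete synthetic CNV study
#'
#' Runs the whole generator -- component frequencies, individuals, segment
#' emission -- and returns every artifact the downstream pipeline needs,
#' with ground truth for parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return A list: `segments`, `manifest`, `genome`, `states` (true loci x
#'   samples state matrix), `freqs` (component frequencies), `truth`.
#' @export
simulate_cnv_study <- function(config = sim_config()) {
  freqs <- simulate_frequencies(config)
  ind <- simulate_individuals(freqs, config)
  em <- emit_segments(ind$states, ind$truth, config)
  list(segments = em$segments, manifest = ind$manifest,
       genome = sim_genome(config), states = ind$states, freqs = freqs,
       truth = em$truth)
}

#' Write all artifacts of a simulated study to a directory
#'
#' Writes the segment TSV, manifest TSV, genome TSV and a JSON truth file
#' (ancestry matrix, per-population frequencies, locus classes, decoy
#' labels). Identical configurations produce byte-identical files.
#'
#' @param sim A [simulate_cnv_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_study <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_segments(sim$segments, file.path(dir, "segments.tsv"))
  write_manifest(sim$manifest, file.path(dir, "manifest.tsv"))
  write_genome(sim$genome, file.path(dir, "genome.tsv"))
  truth <- sim$truth
  jsonlite::write_json(list(
    true_Q = as.data.frame(truth$true_Q),
    pop_freqs = as.data.frame(truth$pop_freqs),
    locus_class = as.list(truth$locus_class),
    loci = truth$loci,
    decoys = truth$decoys,
    n_true = truth$n_true
  ), file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
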