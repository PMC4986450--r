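# Fixtures built in code; no data files.

tiny_genome <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr2", "chrX"),
    length = c(3e6, 3e6, 1e6),
    is_autosome = c(TRUE, TRUE, FALSE)
  )
}

# One valid segment row (internal coordinates), overridable field by field.
seg_row <- function(...) {
  base <- tibble::tibble(
    sample_id = "S1", chrom = "chr1", start = 1000L, end = 21000L,
    cn_state = 1L, n_probes = 10L, max_gap = 2000L, lod = 25, confidence = 0.01
  )
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

manifest_for <- function(sample_ids, population = "P1", role = "other") {
  tibble::tibble(sample_id = sample_ids,
                 population = rep_len(population, length(sample_ids)),
                 role = rep_len(role, length(sample_ids)))
}

# Genotypes object straight from allele matrices.
geno_from <- function(a1, a2, loci = NULL, samples = NULL) {
  loci <- loci %||% sprintf("L%03d", seq_len(nrow(a1)))
  samples <- samples %||% sprintf("S%03d", seq_len(ncol(a1)))
  cnvadmix:::new_cnv_genotypes(a1, a2, loci, samples)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Two clearly separated populations: n_fixed loci fixed for opposite
# copy-number states, the rest normal.
separable_states <- function(n_per_pop = 20, n_fixed = 50, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_pop
  states <- matrix(2L, n_fixed, n,
                   dimnames = list(sprintf("L%03d", seq_len(n_fixed)),
                                   sprintf("S%03d", seq_len(n))))
  states[, seq_len(n_per_pop)] <- 1L
  states[, n_per_pop + seq_len(n_per_pop)] <- 3L
  labels <- rep(c("P1", "P2"), each = n_per_pop)
  list(states = states, labels = labels,
       manifest = tibble::tibble(sample_id = colnames(states),
                                 population = labels, role = "other"))
}
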