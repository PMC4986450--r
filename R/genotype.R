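# Allelic recoding of diploid copy-number states. The haploid allele
# alphabet is copy counts {0, 1, 2}; the diploid state is the sum of the
# two allele copies, so the map is 0 -> 0/0, 1 -> 0/1, 2 -> 1/1,
# 3 -> 1/2, 4 -> 2/2 (total and invertible on {0..4}).

allele1_of_state <- c(`0` = 0L, `1` = 0L, `2` = 1L, `3` = 1L, `4` = 2L)
allele2_of_state <- c(`0` = 0L, `1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L)

new_cnv_genotypes <- function(a1, a2, loci, samples) {
  dimnames(a1) <- dimnames(a2) <- list(loci, samples)
  structure(list(a1 = a1, a2 = a2, loci = loci, samples = samples),
            class = "cnv_genotypes")
}

#' Recode diploid copy-number states as biallelic genotypes
#'
#' Converts integer copy-number states (0--4) to unordered pairs of haploid
#' copy-number alleles: 0 -> 0/0, 1 -> 0/1, 2 -> 1/1, 3 -> 1/2, 4 -> 2/2.
#' Missing states stay missing. The allele pair always sums back to the
#' diploid state, so the coding is invertible ([decode_biallelic()]).
#'
#' @param states Integer matrix (loci x samples) of states in 0--4, `NA`
#'   allowed, or a `cnvr_set` (its state matrix is used).
#' @return A `cnv_genotypes` object: matrices `a1 <= a2` of haploid alleles
#'   in \{0, 1, 2\} plus locus and sample ids.
#' @export
code_biallelic <- function(states) {
  if (inherits(states, "cnvr_set")) states <- states$states
  stopifnot(is.matrix(states))
  vals <- states[!is.na(states)]
  if (length(vals) > 0L && !all(vals %in% 0:4)) {
    abort("copy-number states must be in 0..4 (or NA).")
  }
  key <- as.character(states)
  a1 <- matrix(unname(allele1_of_state[key]), nrow(states), ncol(states))
  a2 <- matrix(unname(allele2_of_state[key]), nrow(states), ncol(states))
  loci <- rownames(states) %||% sprintf("L%04d", seq_len(nrow(states)))
  samples <- colnames(states) %||% sprintf("S%03d", seq_len(ncol(states)))
  new_cnv_genotypes(a1, a2, loci, samples)
}

#' Decode biallelic genotypes back to diploid copy-number states
#'
#' @param genotypes A `cnv_genotypes` object.
#' @return Integer matrix of states (allele sums), `NA` where missing.
#' @export
decode_biallelic <- function(genotypes) {
  stopifnot(inherits(genotypes, "cnv_genotypes"))
  st <- genotypes$a1 + genotypes$a2
  storage.mode(st) <- "integer"
  st
}

#' @export
print.cnv_genotypes <- function(x, ...) {
  cat(sprintf("<cnv_genotypes> %d loci x %d samples, %.1f%% missing\n",
              length(x$loci), length(x$samples),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Long tidy view of a genotype matrix
#'
#' @param x A `cnv_genotypes` object.
#' @param ... Unused.
#' @return A tibble with one row per (locus, sample): haploid alleles
#'   `a1`, `a2` and the diploid `cn_state` (NA where missing).
#' @export
tidy.cnv_genotypes <- function(x, ...) {
  tibble(
    locus_id = rep(x$loci, times = length(x$samples)),
    sample_id = rep(x$samples, each = length(x$loci)),
    a1 = as.vector(x$a1), a2 = as.vector(x$a2),
    cn_state = as.vector(x$a1 + x$a2)
  )
}

#' Mask low-quality genotype calls by their confidence value
#'
#' Calls with confidence strictly below the threshold are high quality and
#' retained; calls with confidence strictly above it are set missing. Calls
#' exactly at the threshold are retained (the retention-favouring reading
#' of the exclusive comparators).
#'
#' @param genotypes A `cnv_genotypes` object.
#' @param confidence Numeric matrix of non-negative confidence values, same
#'   shape as the genotype matrices (lower = more confident).
#' @param threshold Confidence cut-off; default 0.1.
#' @return The genotypes with masked cells set missing.
#' @export
filter_genotype_confidence <- function(genotypes, confidence, threshold = 0.1) {
  stopifnot(inherits(genotypes, "cnv_genotypes"))
  if (!is.matrix(confidence) ||
      !all(dim(confidence) == dim(genotypes$a1))) {
    abort("`confidence` must be a matrix matching the genotype dimensions.")
  }
  if (any(confidence < 0, na.rm = TRUE)) abort("confidence values must be non-negative.")
  mask <- !is.na(confidence) & confidence > threshold
  genotypes$a1[mask] <- NA_integer_
  genotypes$a2[mask] <- NA_integer_
  genotypes
}
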