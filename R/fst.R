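# Weir-Cockerham (1984) theta for multi-allelic loci, via per-allele
# indicator decomposition: each allele is treated as biallelic
# presence/absence, the three variance components a (among populations),
# b (among individuals within populations) and c (within individuals) are
# computed per locus and allele, and theta is the ratio of sums over all
# loci and alleles. An individual is heterozygous for allele A at a locus
# if exactly one of its two haploid copies is A.

# Vectorised over loci: variance components for one allele treated as
# presence/absence, r = 2 populations. All arguments are per-locus vectors
# (sample sizes n1/n2, allele frequencies p1/p2, heterozygote proportions
# h1/h2); returns per-locus a, b, c.
wc_components_allele <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  list(
    a = (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1)),
    b = (nbar / (nbar - 1)) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar),
    c = hbar / 2
  )
}

#' Pairwise Weir--Cockerham F_ST between two populations
#'
#' Computes the multi-allelic Weir--Cockerham theta between two populations
#' from biallelic CNV genotypes: per-locus, per-allele variance components
#' are summed over all loci and alleles and theta is the ratio of sums.
#' Individuals missing a locus are excluded locus-wise; loci leaving fewer
#' than two genotyped individuals in either population are skipped. Small
#' negative estimates are a normal property of the estimator.
#'
#' @param genotypes A `cnv_genotypes` object.
#' @param manifest Sample manifest.
#' @param pop_a,pop_b Population labels to compare.
#' @return An `fst_estimate`: `theta`, `pop_a`, `pop_b`, `n_loci_used`,
#'   and `components` (tibble of per-locus, per-allele a, b, c sums for
#'   audit).
#' @export
pairwise_fst <- function(genotypes, manifest, pop_a, pop_b) {
  stopifnot(inherits(genotypes, "cnv_genotypes"))
  pop <- manifest$population[match(genotypes$samples, manifest$sample_id)]
  if (anyNA(pop)) abort("every genotyped sample must appear in the manifest.")
  sel <- pop %in% c(pop_a, pop_b)
  if (sum(pop == pop_a) < 2L || sum(pop == pop_b) < 2L) {
    abort("both populations need at least 2 genotyped samples.")
  }
  a1 <- genotypes$a1[, sel, drop = FALSE]
  a2 <- genotypes$a2[, sel, drop = FALSE]
  psel <- pop[sel]
  obs <- !is.na(a1) & !is.na(a2)
  in_a <- psel == pop_a
  n1 <- rowSums(obs[, in_a, drop = FALSE])
  n2 <- rowSums(obs[, !in_a, drop = FALSE])
  valid <- n1 >= 2L & n2 >= 2L # individuals missing the locus are excluded
  comps <- purrr::map_dfr(0:2, function(al) {
    cnt <- (a1 == al) + (a2 == al)
    cnt[!obs] <- 0L
    het <- (cnt == 1L) & obs
    p1 <- rowSums(cnt[, in_a, drop = FALSE]) / (2 * n1)
    p2 <- rowSums(cnt[, !in_a, drop = FALSE]) / (2 * n2)
    h1 <- rowSums(het[, in_a, drop = FALSE]) / n1
    h2 <- rowSums(het[, !in_a, drop = FALSE]) / n2
    wc <- wc_components_allele(n1[valid], n2[valid], p1[valid], p2[valid],
                               h1[valid], h2[valid])
    tibble(locus_id = genotypes$loci[valid], allele = al,
           a = wc$a, b = wc$b, c = wc$c)
  }) |>
    dplyr::arrange(.data$locus_id, .data$allele)
  denom <- sum(comps$a + comps$b + comps$c)
  if (nrow(comps) == 0L || denom <= 0) {
    abort(sprintf("no shared polymorphic locus between %s and %s.", pop_a, pop_b))
  }
  structure(list(
    theta = sum(comps$a) / denom,
    pop_a = pop_a, pop_b = pop_b,
    n_loci_used = length(unique(comps$locus_id[comps$a + comps$b + comps$c > 0])),
    components = comps
  ), class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("<fst_estimate> F_ST(%s, %s) = %.4f over %d loci\n",
              x$pop_a, x$pop_b, x$theta, x$n_loci_used))
  invisible(x)
}

#' @export
glance.fst_estimate <- function(x, ...) {
  tibble(pop_a = x$pop_a, pop_b = x$pop_b, theta = x$theta,
         n_loci_used = x$n_loci_used,
         sum_a = sum(x$components$a), sum_b = sum(x$components$b),
         sum_c = sum(x$components$c))
}

#' All pairwise F_ST estimates among the manifest's populations
#'
#' @param genotypes A `cnv_genotypes` object.
#' @param manifest Sample manifest.
#' @return An `fst_matrix`: symmetric `matrix` of theta (zero diagonal)
#'   and `pairs`, a tibble of the pairwise estimates.
#' @export
fst_all_pairs <- function(genotypes, manifest) {
  pops <- unique(manifest$population[match(genotypes$samples,
                                           manifest$sample_id)])
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  pairs <- tidyr::expand_grid(pop_a = pops, pop_b = pops) |>
    dplyr::filter(match(.data$pop_a, pops) < match(.data$pop_b, pops))
  pairs$theta <- purrr::map2_dbl(pairs$pop_a, pairs$pop_b, function(a, b) {
    pairwise_fst(genotypes, manifest, a, b)$theta
  })
  for (i in seq_len(nrow(pairs))) {
    m[pairs$pop_a[i], pairs$pop_b[i]] <- pairs$theta[i]
    m[pairs$pop_b[i], pairs$pop_a[i]] <- pairs$theta[i]
  }
  structure(list(matrix = m, pairs = pairs), class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("<fst_matrix>\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' @export
tidy.fst_matrix <- function(x, ...) x$pairs

#' Per-CNVR carrier frequencies for ancestry-informativeness analysis
#'
#' Builds, for every deletion- or duplication-class CNVR, the carrier
#' frequency in the admixed population (`f_og`), in the putative Indian
#' ancestor(s) (`f_ind`, mean over `ancestral_indian` populations) and in
#' each putative African ancestor population (`f_afr_<pop>`). Deletion
#' CNVRs use the deletion-frequency matrix, duplication CNVRs the
#' duplication-frequency matrix; gain--loss CNVRs are excluded as
#' ambiguous.
#'
#' @param cnvrs A `cnvr_set`.
#' @param manifest Sample manifest with `admixed`, `ancestral_indian` and
#'   `ancestral_african` roles assigned.
#' @return A tibble: `cnvr_id`, `class`, `f_og`, `f_ind`, one
#'   `f_afr_<pop>` column per African ancestral population.
#' @export
cnvr_ancestry_freqs <- function(cnvrs, manifest) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  role_pops <- function(role) {
    unique(manifest$population[manifest$role == role])
  }
  og <- role_pops("admixed")
  ind <- role_pops("ancestral_indian")
  afr <- role_pops("ancestral_african")
  if (length(og) != 1L) abort("exactly one admixed population expected.")
  if (length(ind) < 1L || length(afr) < 1L) {
    abort("need at least one ancestral_indian and one ancestral_african population.")
  }
  keep <- cnvrs$regions$class != "gain_loss"
  ids <- cnvrs$regions$cnvr_id[keep]
  cls <- cnvrs$regions$class[keep]
  freq_of <- function(pop) {
    f <- ifelse(cls == "del", cnvrs$del_freq[ids, pop], cnvrs$dup_freq[ids, pop])
    unname(f)
  }
  out <- tibble(cnvr_id = ids, class = cls,
                f_og = freq_of(og),
                f_ind = rowMeans(vapply(ind, freq_of, numeric(length(ids)))))
  for (p in afr) out[[paste0("f_afr_", p)]] <- freq_of(p)
  out
}

#' Classify CNVRs into ancestry-informativeness classes
#'
#' Bins each deletion/duplication CNVR of the admixed population into one
#' of three classes by comparing its carrier frequency in the admixed
#' group with the putative Indian and African ancestors: `unique` if the
#' region is at least `rare` frequent in the admixed group but below
#' `rare` in both ancestors; otherwise `indian_close` if the frequency
#' distance to the Indian ancestor is below `delta` while the African
#' distance is not (and symmetrically `african_close`); `unassigned` when
#' neither side is resolved. The African ancestor frequency is summarised
#' over the African reference populations by `afr_summary`.
#'
#' @param freqs A tibble from [cnvr_ancestry_freqs()] (or any table with
#'   `f_og`, `f_ind` and one or more `f_afr_*` columns, frequencies in
#'   [0, 1]).
#' @param delta Frequency-distance threshold (default 0.2).
#' @param rare Rarity threshold for the `unique` class (default 0.05, the
#'   same floor used for CNVR construction).
#' @param afr_summary `"mean"` (default) or `"max"` over the African
#'   reference populations.
#' @return The input with `f_afr`, `d_ind`, `d_afr` and `class`
#'   (`indian_close` | `african_close` | `unique` | `unassigned`) columns
#'   appended; thresholds recorded in attributes `delta` and `rare`.
#' @export
classify_aic <- function(freqs, delta = 0.2, rare = 0.05,
                         afr_summary = c("mean", "max")) {
  afr_summary <- match.arg(afr_summary)
  assert_columns(freqs, c("f_og", "f_ind"), "frequency table")
  afr_cols <- grep("^f_afr", names(freqs), value = TRUE)
  if (length(afr_cols) == 0L) abort("no African ancestor frequency column (f_afr_*).")
  fm <- as.matrix(freqs[, c("f_og", "f_ind", afr_cols)])
  if (any(fm < 0 | fm > 1, na.rm = TRUE)) abort("frequencies must be in [0, 1].")
  f_afr <- if (afr_summary == "mean") {
    rowMeans(fm[, afr_cols, drop = FALSE])
  } else {
    apply(fm[, afr_cols, drop = FALSE], 1L, max)
  }
  d_ind <- abs(freqs$f_og - freqs$f_ind)
  d_afr <- abs(freqs$f_og - f_afr)
  class <- dplyr::case_when(
    freqs$f_og >= rare & freqs$f_ind < rare & f_afr < rare ~ "unique",
    d_ind < delta & d_afr >= delta ~ "indian_close",
    d_afr < delta & d_ind >= delta ~ "african_close",
    TRUE ~ "unassigned"
  )
  out <- dplyr::mutate(as_tibble(freqs), f_afr = f_afr, d_ind = d_ind,
                       d_afr = d_afr, class = class)
  attr(out, "delta") <- delta
  attr(out, "rare") <- rare
  out
}

#' CNVRs specific to one population
#'
#' `specific_ids`: CNVRs carried by at least one sample of the target
#' population and by no sample of any designated ancestral population
#' (`ancestral_indian` / `ancestral_african` roles). Of these,
#' `strictly_private_ids` are additionally absent from every other studied
#' population.
#'
#' @param cnvrs A `cnvr_set`.
#' @param manifest Sample manifest.
#' @param target_population Population label (default: the admixed
#'   population).
#' @return A list with `specific_ids` and `strictly_private_ids`
#'   (character vectors; the second is always a subset of the first).
#' @export
og_specific_cnvrs <- function(cnvrs, manifest, target_population = NULL) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  target_population <- target_population %||%
    unique(manifest$population[manifest$role == "admixed"])
  if (length(target_population) != 1L ||
      !target_population %in% manifest$population) {
    abort("`target_population` must name one population in the manifest.")
  }
  pop_of <- manifest$population[match(cnvrs$samples, manifest$sample_id)]
  ancestral <- unique(manifest$population[manifest$role %in%
                                            c("ancestral_indian", "ancestral_african")])
  called <- cnvrs$states != 2L
  in_target <- rowSums(called[, pop_of == target_population, drop = FALSE]) > 0L
  in_ancestral <- rowSums(called[, pop_of %in% ancestral, drop = FALSE]) > 0L
  others <- setdiff(unique(pop_of), c(target_population, ancestral))
  in_other <- rowSums(called[, pop_of %in% others, drop = FALSE]) > 0L
  specific <- in_target & !in_ancestral
  private <- specific & !in_other
  list(specific_ids = rownames(cnvrs$states)[specific],
       strictly_private_ids = rownames(cnvrs$states)[private])
}
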