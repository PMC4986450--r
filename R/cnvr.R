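#' Build copy number variable regions (CNVRs) from filtered segments
#'
#' Merges quality-filtered CNV segments into CNVRs by single-linkage,
#' any-base overlap within each chromosome (intervals are half-open, so
#' abutting segments share no base and do not merge), assigns each sample a
#' per-CNVR copy-number state, applies the cohort sample-frequency
#' threshold, and computes per-population deletion and duplication
#' frequency matrices.
#'
#' Per-sample state when a sample contributes several member segments with
#' conflicting states: the state of the widest member segment wins; ties go
#' to the state most deviant from the normal copy number 2, then to the
#' loss (smaller) state. Samples with no member segment are at the normal
#' state 2. Candidate regions carried by fewer than `min_freq` of all
#' manifest samples are discarded (singleton/rare-call control).
#'
#' @param kept Filtered segment tibble.
#' @param manifest Sample manifest (defines the cohort for the frequency
#'   threshold and the populations of the frequency matrices).
#' @param min_freq Minimum fraction of cohort samples carrying the region.
#' @param genome Optional genome table; required when `check_filtered` to
#'   verify the autosome rule.
#' @param check_filtered When `TRUE` (default), error if any input segment
#'   violates the default [filter_policy()]; set `FALSE` to build CNVRs
#'   from deliberately unfiltered calls.
#' @return A `cnvr_set`: `regions` (tibble `cnvr_id`, `chrom`, `start`,
#'   `end`, `n_carriers`, `carrier_freq`, `class`), `states` (CNVR x sample
#'   integer matrix, 2 = no call), `del_freq`/`dup_freq` (CNVR x population
#'   matrices of within-population carrier fractions), `samples`,
#'   `populations`, `min_freq`, `n_candidates` (pre-threshold region
#'   count).
#' @export
build_cnvrs <- function(kept, manifest, min_freq = 0.05, genome = NULL,
                        check_filtered = TRUE) {
  assert_scalar_number(min_freq, "min_freq", 0, 1)
  validate_manifest(manifest)
  unknown <- setdiff(unique(kept$sample_id), manifest$sample_id)
  if (length(unknown) > 0L) {
    abort(sprintf("segment sample(s) absent from manifest: %s.",
                  paste(unknown, collapse = ", ")))
  }
  if (check_filtered && nrow(kept) > 0L) {
    pol <- filter_policy(autosomes_only = !is.null(genome))
    g <- genome %||% tibble(chrom = unique(kept$chrom),
                            length = Inf, is_autosome = TRUE)
    rep <- filter_segments(kept, pol, g)
    if (nrow(rep$rejected) > 0L) {
      abort(sprintf(
        "%d input segment(s) violate the default filter policy (first rule: %s); run filter_segments() first or set check_filtered = FALSE.",
        nrow(rep$rejected), rep$rejected$rule[1L]
      ))
    }
  }
  if (nrow(kept) == 0L) abort("no segments to merge.")

  seg <- dplyr::mutate(kept, .row = dplyr::row_number())
  cand <- seg |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(d, key) {
      m <- merge_halfopen(d$start, d$end)
      tibble(chrom = key$chrom[[1L]],
             start = m$merged$start, end = m$merged$end,
             members = split(d$.row, m$group)[as.character(seq_len(nrow(m$merged)))])
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$chrom, .data$start)
  n_candidates <- nrow(cand)

  samples <- manifest$sample_id
  n_samples <- length(samples)
  # per-candidate, per-sample state by the widest-segment precedence rule
  state_rows <- lapply(cand$members, function(rows) {
    d <- seg[rows, ]
    st <- rep(2L, n_samples)
    picked <- d |>
      dplyr::mutate(width = .data$end - .data$start,
                    extremity = abs(.data$cn_state - 2L)) |>
      dplyr::arrange(.data$sample_id, dplyr::desc(.data$width),
                     dplyr::desc(.data$extremity), .data$cn_state) |>
      dplyr::distinct(.data$sample_id, .keep_all = TRUE)
    st[match(picked$sample_id, samples)] <- picked$cn_state
    st
  })
  states_all <- do.call(rbind, state_rows)
  colnames(states_all) <- samples

  carriers <- rowSums(states_all != 2L)
  keep <- (carriers / n_samples) >= min_freq
  if (!any(keep)) abort("no CNVR passes the sample-frequency threshold.")
  regions <- cand[keep, c("chrom", "start", "end")]
  states <- states_all[keep, , drop = FALSE]
  ids <- sprintf("R%04d", seq_len(nrow(regions)))
  regions <- dplyr::mutate(regions,
                           cnvr_id = ids,
                           n_carriers = as.integer(unname(carriers[keep])),
                           carrier_freq = unname(carriers[keep]) / n_samples,
                           .before = 1L)
  rownames(states) <- ids
  regions$class <- unname(apply(states, 1L, classify_cnvr))

  pops <- unique(manifest$population)
  pop_of <- manifest$population[match(samples, manifest$sample_id)]
  del_freq <- vapply(pops, function(p) {
    rowMeans(states[, pop_of == p, drop = FALSE] < 2L)
  }, numeric(nrow(states)))
  dup_freq <- vapply(pops, function(p) {
    rowMeans(states[, pop_of == p, drop = FALSE] > 2L)
  }, numeric(nrow(states)))
  if (nrow(states) == 1L) { # vapply drops to vector-compatible dims
    del_freq <- matrix(del_freq, 1L, dimnames = list(ids, pops))
    dup_freq <- matrix(dup_freq, 1L, dimnames = list(ids, pops))
  } else {
    rownames(del_freq) <- rownames(dup_freq) <- ids
  }

  structure(list(
    regions = regions[, c("cnvr_id", "chrom", "start", "end", "n_carriers",
                          "carrier_freq", "class")],
    states = states, del_freq = del_freq, dup_freq = dup_freq,
    samples = samples, populations = pops, min_freq = min_freq,
    n_candidates = n_candidates
  ), class = "cnvr_set")
}

#' Classify a CNVR by the copy-number states it harbours
#'
#' `del` if every non-normal state is a loss (< 2), `dup` if every
#' non-normal state is a gain (> 2), `gain_loss` if both occur.
#'
#' @param states Integer vector of per-sample states (0--4).
#' @return `"del"`, `"dup"` or `"gain_loss"`.
#' @export
classify_cnvr <- function(states) {
  states <- states[!is.na(states)]
  has_del <- any(states < 2L)
  has_dup <- any(states > 2L)
  if (!has_del && !has_dup) {
    abort("cannot classify a region with no non-normal call.")
  }
  if (has_del && has_dup) "gain_loss" else if (has_del) "del" else "dup"
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat(sprintf(
    "<cnvr_set> %d CNVRs (%d candidates before %.0f%% frequency threshold), %d samples, %d populations\n",
    nrow(x$regions), x$n_candidates, 100 * x$min_freq,
    length(x$samples), length(x$populations)))
  print(dplyr::count(x$regions, .data$class))
  invisible(x)
}

#' Long tidy view of a CNVR set
#'
#' One row per (CNVR, population) with the region's interval, class and the
#' within-population deletion and duplication carrier frequencies.
#'
#' @param x A `cnvr_set`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cnvr_set <- function(x, ...) {
  freqs <- dplyr::bind_rows(
    as_tibble(x$del_freq, rownames = "cnvr_id") |>
      tidyr::pivot_longer(-"cnvr_id", names_to = "population",
                          values_to = "del_freq"),
    as_tibble(x$dup_freq, rownames = "cnvr_id") |>
      tidyr::pivot_longer(-"cnvr_id", names_to = "population",
                          values_to = "dup_freq")
  ) |>
    dplyr::group_by(.data$cnvr_id, .data$population) |>
    dplyr::summarise(del_freq = sum(.data$del_freq, na.rm = TRUE),
                     dup_freq = sum(.data$dup_freq, na.rm = TRUE),
                     .groups = "drop")
  dplyr::left_join(x$regions, freqs, by = "cnvr_id")
}

#' Keep the points that fall inside any of a set of genomic regions
#'
#' Half-open inclusion: a point at a region's start is inside, a point at
#' its end is not. Regions are merged per chromosome and membership is
#' resolved by a sorted-interval search; input order is preserved.
#'
#' @param points Tibble with columns `chrom`, `pos` (0-based positions).
#' @param regions Tibble with columns `chrom`, `start`, `end`, or a
#'   `cnvr_set`.
#' @return The rows of `points` falling inside any region, input order
#'   preserved, with attribute `n_inside`.
#' @export
intersect_points <- function(points, regions) {
  if (inherits(regions, "cnvr_set")) regions <- regions$regions
  assert_columns(points, c("chrom", "pos"), "points")
  assert_columns(regions, c("chrom", "start", "end"), "regions")
  inside <- rep(FALSE, nrow(points))
  for (ch in unique(points$chrom)) {
    r <- regions[regions$chrom == ch, ]
    if (nrow(r) == 0L) next
    m <- merge_halfopen(r$start, r$end)$merged
    pi <- which(points$chrom == ch)
    idx <- findInterval(points$pos[pi], m$start)
    hit <- idx >= 1L & points$pos[pi] < m$end[pmax(idx, 1L)]
    inside[pi] <- hit
  }
  out <- points[inside, , drop = FALSE]
  attr(out, "n_inside") <- sum(inside)
  out
}
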