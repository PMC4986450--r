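#' Segment quality-filter policy
#'
#' The five segment-level quality rules applied to array-caller CNV calls,
#' in their conventional order: (1) autosomes only, (2) at least
#' `min_probes` contiguous probes, (3) all inter-probe gaps below
#' `max_probe_gap` (the segment's maximum gap must be strictly less),
#' (4) LOD score at least `min_lod` (inclusive), (5) segment size strictly
#' below `max_size`.
#'
#' @param autosomes_only Drop segments on non-autosomal chromosomes.
#' @param min_probes Minimum probe count (inclusive).
#' @param max_probe_gap Maximum allowed inter-probe gap in bp (exclusive:
#'   a segment whose largest gap equals this value is rejected).
#' @param min_lod Minimum LOD score (inclusive).
#' @param max_size Maximum segment size in bp (exclusive: a segment of
#'   exactly this size is rejected).
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(autosomes_only = TRUE, min_probes = 5L,
                          max_probe_gap = 10000L, min_lod = 10,
                          max_size = 1000000L) {
  assert_scalar_number(min_probes, "min_probes", 1)
  assert_scalar_number(max_probe_gap, "max_probe_gap", 0, strict_lower = TRUE)
  assert_scalar_number(min_lod, "min_lod", 0, strict_lower = TRUE)
  assert_scalar_number(max_size, "max_size", 0, strict_lower = TRUE)
  structure(list(autosomes_only = isTRUE(autosomes_only),
                 min_probes = as.integer(min_probes),
                 max_probe_gap = as.numeric(max_probe_gap),
                 min_lod = as.numeric(min_lod),
                 max_size = as.numeric(max_size)),
            class = "filter_policy")
}

#' Apply the five segment quality filters
#'
#' A segment is kept iff it is autosomal AND `n_probes >= min_probes` AND
#' `max_gap < max_probe_gap` AND `lod >= min_lod` AND
#' `end - start < max_size`. Rejected segments are tagged with the first
#' rule they violate, testing rules in the listed order.
#'
#' @param segments Validated segment tibble (internal coordinates).
#' @param policy A [filter_policy()].
#' @param genome Genome table covering every chromosome in `segments`.
#' @return A `filter_report` list: `kept` (segment tibble), `rejected`
#'   (segment tibble with a `rule` column), `counts` (tibble of per-rule
#'   rejection counts), and the `policy` applied.
#' @export
filter_segments <- function(segments, policy = filter_policy(), genome) {
  stopifnot(inherits(policy, "filter_policy"))
  validate_segments(segments, genome)
  autosomes <- genome$chrom[genome$is_autosome]
  rule <- rep(NA_character_, nrow(segments))
  fail <- function(current, cond, name) ifelse(is.na(current) & cond, name, current)
  if (policy$autosomes_only) {
    rule <- fail(rule, !segments$chrom %in% autosomes, "autosomes_only")
  }
  rule <- fail(rule, segments$n_probes < policy$min_probes, "min_probes")
  rule <- fail(rule, segments$max_gap >= policy$max_probe_gap, "max_probe_gap")
  rule <- fail(rule, segments$lod < policy$min_lod, "min_lod")
  rule <- fail(rule, (segments$end - segments$start) >= policy$max_size, "max_size")
  kept <- segments[is.na(rule), , drop = FALSE]
  rejected <- segments[!is.na(rule), , drop = FALSE]
  rejected$rule <- rule[!is.na(rule)]
  rule_order <- c("autosomes_only", "min_probes", "max_probe_gap", "min_lod",
                  "max_size")
  counts <- tibble(
    rule = rule_order,
    n_rejected = vapply(rule_order, function(r) sum(rejected$rule == r), 0L)
  )
  structure(list(kept = kept, rejected = rejected, counts = counts,
                 policy = policy),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d kept, %d rejected of %d segments\n",
              nrow(x$kept), nrow(x$rejected), nrow(x$kept) + nrow(x$rejected)))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$kept, rule = NA_character_, kept = TRUE),
    dplyr::mutate(x$rejected, kept = FALSE)
  )
}

#' Per-sample and per-population CNV call summaries
#'
#' For each sample: number of calls, deletions (state < 2), duplications
#' (state > 2), total base pairs under CNV (union of that sample's
#' segments, overlaps counted once), and the fraction of the autosomal
#' genome covered. Per population: arithmetic means of the per-sample
#' values. By construction deletions + duplications = calls for every
#' sample.
#'
#' @param kept Filtered segment tibble (e.g. `filter_segments(...)$kept`).
#' @param manifest Sample manifest; every segment's sample must appear.
#' @param genome Genome table; the autosomal total is the fraction
#'   denominator.
#' @return A list of two tibbles: `by_sample` and `by_population`. Samples
#'   with no kept calls appear with zero counts.
#' @export
summarize_calls <- function(kept, manifest, genome) {
  unknown <- setdiff(unique(kept$sample_id), manifest$sample_id)
  if (length(unknown) > 0L) {
    abort(sprintf("segment sample(s) absent from manifest: %s.",
                  paste(unknown, collapse = ", ")))
  }
  autosomal_bp <- sum(genome$length[genome$is_autosome])
  per_sample <- kept |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_calls = dplyr::n(),
      n_deletions = sum(.data$cn_state < 2L),
      n_duplications = sum(.data$cn_state > 2L),
      bp_under_cnv = sum(vapply(
        split(dplyr::pick("chrom", "start", "end"),
              dplyr::pick("chrom", "start", "end")$chrom),
        function(d) union_width(d$start, d$end), numeric(1))),
      .groups = "drop"
    )
  by_sample <- manifest |>
    dplyr::select("sample_id", "population") |>
    dplyr::left_join(per_sample, by = "sample_id") |>
    dplyr::mutate(dplyr::across(c("n_calls", "n_deletions", "n_duplications",
                                  "bp_under_cnv"),
                                ~tidyr::replace_na(.x, 0)),
                  genome_fraction = .data$bp_under_cnv / autosomal_bp)
  by_population <- by_sample |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     dplyr::across(c("n_calls", "n_deletions", "n_duplications",
                                     "bp_under_cnv", "genome_fraction"), mean),
                     .groups = "drop")
  list(by_sample = by_sample, by_population = by_population)
}
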