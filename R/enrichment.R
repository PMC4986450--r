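#' Map CNVRs to overlapping genes
#'
#' A gene (longest-transcript interval) is included if it shares at least
#' one base with at least one CNVR (half-open overlap; abutting intervals
#' do not count). Each gene is reported once regardless of how many CNVRs
#' it overlaps.
#'
#' @param cnvrs A `cnvr_set`, its `regions` tibble, or any tibble with
#'   `chrom`, `start`, `end` (optionally restricted to an id subset first).
#' @param genes Gene tibble from [read_gene_table()] (one interval per
#'   gene).
#' @param ids Optional character vector of CNVR ids to restrict to.
#' @return Character vector of overlapping gene ids (annotation order).
#' @export
map_cnvr_to_genes <- function(cnvrs, genes, ids = NULL) {
  regions <- if (inherits(cnvrs, "cnvr_set")) cnvrs$regions else as_tibble(cnvrs)
  assert_columns(regions, c("chrom", "start", "end"), "CNVR regions")
  if (!is.null(ids)) regions <- regions[regions$cnvr_id %in% ids, ]
  orphan <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(orphan) > 0L) {
    warn(sprintf("no gene annotation on chromosome(s): %s.",
                 paste(orphan, collapse = ", ")))
  }
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    r <- regions[regions$chrom == genes$chrom[i], ]
    any(r$start < genes$end[i] & genes$start[i] < r$end)
  }, logical(1))
  genes$gene_id[hit]
}

#' Hypergeometric gene-set over-representation test
#'
#' For each gene set with K members in a background universe of size N,
#' and a query of size n overlapping the set in k genes, computes the
#' upper-tail hypergeometric probability P(X >= k) and applies Bonferroni
#' correction. By default the correction is applied within each set
#' category separately (matching per-category reporting of enrichment
#' tables); `by_category = FALSE` corrects globally over all sets tested.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   the background).
#' @param collection Long gene-set tibble from [read_gmt()] (`set_name`,
#'   `category`, `gene_id`).
#' @param background Character vector: the gene universe (conventionally
#'   all genes in the annotation table).
#' @param alpha Significance level on the Bonferroni-corrected p-value.
#' @param by_category Correct within category (default) or globally.
#' @return An `enrichment_result` tibble, sorted by raw p-value: one row
#'   per tested set with `set_name`, `category`, `hit_count_query` (k),
#'   `hit_count_genome` (K), `query_size` (n), `background_size` (N),
#'   `raw_p`, `bonferroni_p`, `significant`, `hit_genes` (list column).
#'   Sets empty after intersection with the background are skipped (ids in
#'   attribute `skipped_sets`).
#' @export
hypergeom_enrich <- function(query, collection, background, alpha = 0.05,
                             by_category = TRUE) {
  query <- unique(query)
  background <- unique(background)
  if (length(query) == 0L) abort("query gene set is empty.")
  stray <- setdiff(query, background)
  if (length(stray) > 0L) {
    abort(sprintf("query gene(s) outside the background universe: %s.",
                  paste(head(stray, 5L), collapse = ", ")))
  }
  assert_columns(collection, c("set_name", "category", "gene_id"), "collection")
  N <- length(background)
  n <- length(query)
  sets <- collection |>
    dplyr::filter(.data$gene_id %in% background) |>
    dplyr::distinct(.data$set_name, .data$category, .data$gene_id) |>
    dplyr::group_by(.data$set_name, .data$category) |>
    dplyr::summarise(members = list(.data$gene_id), .groups = "drop")
  skipped <- setdiff(unique(collection$set_name), sets$set_name)
  if (nrow(sets) == 0L) abort("no gene set overlaps the background universe.")
  res <- sets |>
    dplyr::mutate(
      hit_genes = purrr::map(.data$members, ~intersect(query, .x)),
      hit_count_query = lengths(.data$hit_genes),
      hit_count_genome = lengths(.data$members),
      query_size = n, background_size = N,
      raw_p = phyper(.data$hit_count_query - 1L, .data$hit_count_genome,
                     N - .data$hit_count_genome, n, lower.tail = FALSE)
    ) |>
    dplyr::select(-"members")
  res <- if (by_category) {
    res |>
      dplyr::group_by(.data$category) |>
      dplyr::mutate(bonferroni_p = pmin(1, .data$raw_p * dplyr::n())) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(res, bonferroni_p = pmin(1, .data$raw_p * dplyr::n()))
  }
  res <- res |>
    dplyr::mutate(significant = .data$bonferroni_p <= alpha) |>
    dplyr::arrange(.data$raw_p) |>
    dplyr::relocate("hit_genes", .after = dplyr::last_col())
  attr(res, "skipped_sets") <- skipped
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Bar plot of the most enriched gene sets
#'
#' @param object An `enrichment_result`.
#' @param top Number of sets to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top = 15L, ...) {
  d <- head(as_tibble(object), top) |>
    dplyr::mutate(set_name = factor(.data$set_name, levels = rev(.data$set_name)))
  ggplot2::ggplot(d, ggplot2::aes(-log10(pmax(.data$bonferroni_p, 1e-300)),
                                  .data$set_name, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = expression(-log[10] ~ "Bonferroni p"), y = NULL,
                  fill = "Category") +
    ggplot2::theme_minimal()
}
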