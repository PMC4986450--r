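#' Read per-sample CNV segment calls
#'
#' Reads a tab-delimited table of array-caller CNV segments (one row per
#' called segment in one sample). The file must carry a header naming the
#' eight required fields `sample_id`, `chrom`, `start`, `end`, `cn_state`,
#' `n_probes`, `max_gap`, `lod`; an optional ninth column `confidence`
#' defaults to 0. On-disk coordinates are 1-based inclusive (the array-caller
#' convention) and are converted on read to the package-internal 0-based
#' half-open convention.
#'
#' @param path Path to a tab-delimited segment file.
#' @param genome A genome table as returned by [read_genome()]; segments on
#'   chromosomes absent from the table are rejected.
#' @return A tibble of validated segments with internal coordinates, in file
#'   order: columns `sample_id`, `chrom`, `start`, `end`, `cn_state`,
#'   `n_probes`, `max_gap`, `lod`, `confidence`.
#' @seealso [write_segments()], [filter_segments()]
#' @export
read_segments <- function(path, genome) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("sample_id", "chrom", "start", "end", "cn_state",
                "n_probes", "max_gap", "lod")
  assert_columns(raw, required, "segment file")
  if (!"confidence" %in% names(raw)) raw$confidence <- "0"
  num_cols <- c("start", "end", "cn_state", "n_probes", "max_gap", "lod",
                "confidence")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0L) {
      abort(sprintf("Malformed value in column `%s` at data line %d of %s.",
                    col, bad[1L], path))
    }
    raw[[col]] <- v
  }
  seg <- tibble(
    sample_id = raw$sample_id,
    chrom = raw$chrom,
    start = as.integer(raw$start) - 1L, # 1-based inclusive -> 0-based half-open
    end = as.integer(raw$end),
    cn_state = as.integer(raw$cn_state),
    n_probes = as.integer(raw$n_probes),
    max_gap = as.integer(raw$max_gap),
    lod = raw$lod,
    confidence = raw$confidence
  )
  validate_segments(seg, genome)
}

#' Validate a segment tibble against its invariants
#'
#' Checks the segment-record invariants: `end > start`, copy-number state in
#' 0--4 and never the normal state 2 (a call is by definition a deviation
#' from 2), at least one probe, non-negative confidence, and all chromosomes
#' present in the genome table (if supplied).
#'
#' @param segments A segment tibble (internal 0-based half-open coordinates).
#' @param genome Optional genome table; when given, unknown chromosomes are
#'   rejected.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_segments <- function(segments, genome = NULL) {
  assert_columns(segments, c("sample_id", "chrom", "start", "end", "cn_state",
                             "n_probes", "max_gap", "lod", "confidence"),
                 "segment table")
  bad_state <- which(!segments$cn_state %in% c(0L, 1L, 3L, 4L))
  if (length(bad_state) > 0L) {
    abort(sprintf(
      "Invalid cn_state %s at row %d: calls must be in {0,1,3,4} (2 = normal copy is never emitted as a call).",
      segments$cn_state[bad_state[1L]], bad_state[1L]
    ))
  }
  bad_iv <- which(segments$end <= segments$start)
  if (length(bad_iv) > 0L) {
    abort(sprintf("Empty or inverted interval at row %d (end <= start).", bad_iv[1L]))
  }
  if (any(segments$n_probes < 1L)) abort("n_probes must be >= 1 for every segment.")
  if (any(segments$confidence < 0)) abort("confidence must be non-negative.")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(segments$chrom), genome$chrom)
    if (length(unknown) > 0L) {
      abort(sprintf("Unknown chromosome(s) not in genome table: %s.",
                    paste(unknown, collapse = ", ")))
    }
  }
  segments
}

#' Write CNV segments to a tab-delimited file
#'
#' Inverse of [read_segments()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive on write, so a write/read round trip
#' is the identity.
#'
#' @param segments Segment tibble with internal coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- segments
  out$start <- out$start + 1L
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Three tab-delimited columns: `sample_id`, `population`, `role`. Roles are
#' one of `admixed`, `ancestral_indian`, `ancestral_african`, `other` and
#' mark how a population enters the ancestry analyses (which populations are
#' putative ancestors of the admixed group).
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with columns `sample_id`, `population`, `role`.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  assert_columns(m, c("sample_id", "population", "role"), "manifest")
  validate_manifest(m)
}

valid_roles <- c("admixed", "ancestral_indian", "ancestral_african", "other")

validate_manifest <- function(manifest) {
  if (anyDuplicated(manifest$sample_id)) {
    abort("manifest sample_ids must be unique.")
  }
  bad <- setdiff(unique(manifest$role), valid_roles)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown role(s): %s. Valid roles: %s.",
                  paste(bad, collapse = ", "), paste(valid_roles, collapse = ", ")))
  }
  if (nrow(manifest) == 0L) abort("manifest is empty.")
  manifest
}

#' Write a sample manifest
#' @param manifest Manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest[, c("sample_id", "population", "role")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Tab-delimited columns `chrom`, `length`, `is_autosome` (logical or 0/1).
#' The autosomal total is the denominator of per-sample genome-fraction
#' summaries.
#'
#' @param path Path to the genome TSV.
#' @return A tibble with columns `chrom`, `length`, `is_autosome`.
#' @export
read_genome <- function(path) {
  g <- readr::read_tsv(path, col_types = "cdl", progress = FALSE)
  assert_columns(g, c("chrom", "length", "is_autosome"), "genome table")
  validate_genome(g)
}

validate_genome <- function(genome) {
  if (any(genome$length <= 0)) abort("chromosome lengths must be positive.")
  if (!any(genome$is_autosome)) abort("genome table must contain at least one autosome.")
  if (anyDuplicated(genome$chrom)) abort("duplicate chromosome in genome table.")
  genome
}

#' Write a chromosome-length table
#' @param genome Genome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  readr::write_tsv(genome[, c("chrom", "length", "is_autosome")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a transcript table and reduce to one interval per gene
#'
#' Reads a refFlat-like tab-delimited transcript table (`gene_id`,
#' `transcript_id`, `chrom`, `start`, `end`, `strand`; coordinates 0-based
#' half-open as in refFlat) and keeps, for each gene, the coordinates of its
#' longest transcript. Ties are broken deterministically: smaller start
#' first, then lexicographically smaller transcript_id.
#'
#' @param path Path to the transcript TSV.
#' @return A tibble with one row per gene: `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_table <- function(path) {
  tx <- readr::read_tsv(path, col_types = "cccddc", progress = FALSE)
  assert_columns(tx, c("gene_id", "transcript_id", "chrom", "start", "end", "strand"),
                 "gene table")
  if (nrow(tx) == 0L) abort("gene table is empty.")
  if (any(tx$end <= tx$start)) abort("gene table has an empty/inverted transcript interval.")
  longest_transcript(tx)
}

#' Reduce a transcript tibble to the longest transcript per gene
#'
#' @param transcripts Tibble with `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @return One row per gene (longest transcript; ties to smaller start then
#'   transcript_id).
#' @export
longest_transcript <- function(transcripts) {
  multi_chrom <- transcripts |>
    dplyr::distinct(.data$gene_id, .data$chrom) |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi_chrom) > 0L) {
    abort(sprintf("gene(s) with transcripts on multiple chromosomes: %s.",
                  paste(multi_chrom$gene_id, collapse = ", ")))
  }
  transcripts |>
    dplyr::mutate(.len = .data$end - .data$start) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$.len), .data$start,
                   .data$transcript_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::select(-".len") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-delimited `name`, `description`,
#' then member gene ids. The description field is used as the set's category
#' label (e.g. molecular function vs pathway), which controls the grouping
#' of the Bonferroni correction in [hypergeom_enrich()].
#'
#' @param path Path to a .gmt file.
#' @return A long tibble: `set_name`, `category`, `gene_id`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("GMT file is empty.")
  purrr::map_dfr(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) abort("GMT line with fewer than 3 fields.")
    tibble(set_name = f[1L], category = f[2L], gene_id = f[-(1:2)])
  })
}

#' Write a CNVR set to an extended BED file
#'
#' BED-style output, 0-based half-open, sorted by (chrom, start): columns
#' `chrom`, `start`, `end`, `name`, then `class` (del|dup|gain_loss) and one
#' deletion-frequency plus one duplication-frequency column per population
#' (`del_freq_<pop>`, `dup_freq_<pop>`). A commented header line names the
#' columns.
#'
#' @param cnvrs A [build_cnvrs()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnvr_bed <- function(cnvrs, path) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  if (nrow(cnvrs$regions) == 0L) {
    abort("refusing to write an empty CNVR set.")
  }
  pops <- colnames(cnvrs$del_freq)
  tab <- cnvrs$regions |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select("chrom", "start", "end", name = "cnvr_id", "class")
  ord <- match(tab$name, rownames(cnvrs$del_freq))
  for (p in pops) tab[[paste0("del_freq_", p)]] <- unname(cnvrs$del_freq[ord, p])
  for (p in pops) tab[[paste0("dup_freq_", p)]] <- unname(cnvrs$dup_freq[ord, p])
  header <- paste0("#", paste(names(tab), collapse = "\t"))
  body <- do.call(paste, c(lapply(tab, format_bed_col), sep = "\t"))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

format_bed_col <- function(x) {
  if (is.double(x)) formatC(x, format = "fg", digits = 15) else as.character(x)
}

#' Read back an extended CNVR BED file
#'
#' Reads intervals and frequency columns written by [write_cnvr_bed()];
#' used for round-trip checks and resuming pipelines. Returns a tibble, not
#' a full CNVR set (per-sample states are not stored in BED).
#'
#' @param path Path to the BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `class`
#'   and the per-population frequency columns.
#' @export
read_cnvr_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) < 1L || !startsWith(lines[1L], "#")) {
    abort("CNVR BED file must start with a commented header line.")
  }
  cols <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  body <- paste(lines[-1L], collapse = "\n")
  tab <- readr::read_tsv(I(body), col_names = cols,
                         col_types = readr::cols(
                           chrom = "c", start = "i", end = "i",
                           name = "c", class = "c", .default = "d"
                         ), progress = FALSE)
  as_tibble(tab)
}

#' Write a loci-by-samples integer state matrix as TSV
#' @param states Integer matrix (rownames = locus ids, colnames = sample ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_matrix <- function(states, path) {
  df <- as_tibble(states, rownames = "cnvr_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a loci-by-samples integer state matrix from TSV
#' @param path Path written by [write_state_matrix()].
#' @return Integer matrix with dimnames.
#' @export
read_state_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(cnvr_id = "c", .default = "i"),
                        progress = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$cnvr_id
  m
}

#' Write biallelic CNV genotypes as TSV
#'
#' Loci in rows, samples in columns; each cell is the unordered haploid
#' allele pair `"a/b"` (alleles in 0,1,2 copies) or `"."` for missing.
#'
#' @param genotypes A [code_biallelic()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "cnv_genotypes"))
  cells <- matrix(".", nrow = length(genotypes$loci), ncol = length(genotypes$samples))
  ok <- !is.na(genotypes$a1)
  cells[ok] <- paste0(genotypes$a1[ok], "/", genotypes$a2[ok])
  df <- as_tibble(cells, .name_repair = ~genotypes$samples)
  df <- dplyr::bind_cols(tibble(locus_id = genotypes$loci), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read biallelic CNV genotypes from TSV
#' @param path Path written by [write_genotypes()].
#' @return A `cnv_genotypes` object.
#' @export
read_genotypes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  assert_columns(df, "locus_id", "genotype file")
  loci <- df$locus_id
  cells <- as.matrix(df[, -1L, drop = FALSE])
  a1 <- matrix(NA_integer_, nrow(cells), ncol(cells))
  a2 <- a1
  filled <- cells != "." & !is.na(cells)
  parts <- strsplit(cells[filled], "/", fixed = TRUE)
  a1[filled] <- as.integer(vapply(parts, `[`, "", 1L))
  a2[filled] <- as.integer(vapply(parts, `[`, "", 2L))
  new_cnv_genotypes(a1, a2, loci, colnames(cells))
}

#' Export genotypes in a STRUCTURE-like two-rows-per-individual format
#'
#' Writes one pair of rows per individual (one row per haploid allele copy),
#' columns = loci, missing coded `-9`; first column the sample id, second
#' the population label when a manifest is given. This is the conventional
#' integer layout consumed by population-clustering software.
#'
#' @param genotypes A `cnv_genotypes` object.
#' @param path Output path.
#' @param manifest Optional manifest for population labels.
#' @return `path`, invisibly.
#' @export
write_structure_format <- function(genotypes, path, manifest = NULL) {
  stopifnot(inherits(genotypes, "cnv_genotypes"))
  pops <- if (is.null(manifest)) rep("1", length(genotypes$samples)) else
    manifest$population[match(genotypes$samples, manifest$sample_id)]
  code <- function(m, j) {
    v <- m[, j]
    v[is.na(v)] <- -9L
    paste(v, collapse = "\t")
  }
  lines <- character(2L * length(genotypes$samples))
  for (j in seq_along(genotypes$samples)) {
    prefix <- paste(genotypes$samples[j], pops[j], sep = "\t")
    lines[2L * j - 1L] <- paste(prefix, code(genotypes$a1, j), sep = "\t")
    lines[2L * j] <- paste(prefix, code(genotypes$a2, j), sep = "\t")
  }
  readr::write_lines(lines, path)
  invisible(path)
}
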