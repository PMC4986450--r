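#' Configuration for a full pipeline run
#'
#' Collects every input path, threshold and seed the end-to-end analysis
#' needs. Either point `segments`/`manifest`/`genome` at existing TSV
#' files, or supply a [sim_config()] as `simulate` to generate them as the
#' first stage. One global `seed` fans out deterministically to per-stage
#' seeds (stage-name hash), so any stage can be re-run in isolation with
#' identical results.
#'
#' @param out_dir Directory for all stage artifacts (created if needed).
#' @param simulate Optional [sim_config()]; when given, stage 1 writes the
#'   synthetic inputs into `out_dir`.
#' @param segments,manifest,genome Paths to input TSVs (ignored when
#'   `simulate` is given).
#' @param genes Optional transcript-table path for gene annotation.
#' @param gene_sets Optional GMT path for enrichment.
#' @param policy A [filter_policy()].
#' @param min_freq CNVR sample-frequency threshold.
#' @param n_trees,dims Random-forest and MDS parameters.
#' @param K,n_restarts,tol Admixture-EM parameters.
#' @param delta,rare Ancestry-informativeness thresholds.
#' @param alpha Enrichment significance level.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            simulate = NULL,
                            segments = NULL, manifest = NULL, genome = NULL,
                            genes = NULL, gene_sets = NULL,
                            policy = filter_policy(),
                            min_freq = 0.05,
                            n_trees = 5000L, dims = 3L,
                            K = 3L, n_restarts = 5L, tol = 1e-5,
                            delta = 0.2, rare = 0.05,
                            alpha = 0.05,
                            seed = 1L) {
  if (is.null(simulate) &&
      (is.null(segments) || is.null(manifest) || is.null(genome))) {
    abort("provide either `simulate` or all of `segments`, `manifest`, `genome`.")
  }
  structure(list(
    out_dir = out_dir, simulate = simulate,
    segments = segments, manifest = manifest, genome = genome,
    genes = genes, gene_sets = gene_sets,
    policy = policy, min_freq = min_freq,
    n_trees = as.integer(n_trees), dims = as.integer(dims),
    K = as.integer(K), n_restarts = as.integer(n_restarts), tol = tol,
    delta = delta, rare = rare, alpha = alpha, seed = as.integer(seed)
  ), class = "pipeline_config")
}

read_run_state <- function(out_dir) {
  p <- file.path(out_dir, "run_state.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else list()
}

write_run_state <- function(out_dir, state) {
  jsonlite::write_json(state, file.path(out_dir, "run_state.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the full CNV admixture pipeline
#'
#' Executes the stages simulate (optional), filter, cnvr, genotypes,
#' structure, admix, fst, aic and enrich (the last only when gene inputs
#' are configured) in dependency order, writing plain-text artifacts into
#' `config$out_dir`. A stage is skipped on re-run when its recorded input
#' checksums are unchanged and its outputs are intact; a corrupted
#' intermediate raises an error naming the stage. A failed stage leaves
#' the artifacts of earlier stages (and a partial report) in place.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` tibble (one row per stage: `stage`, `status`,
#'   `n_in`, `n_out`, `seconds`), also written to `report.json` with the
#'   config echo and package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  state <- read_run_state(out)
  report <- tibble(stage = character(), status = character(),
                   n_in = integer(), n_out = integer(), seconds = numeric())
  art <- function(...) file.path(out, ...)

  flush_report <- function() {
    jsonlite::write_json(
      list(stages = report,
           seed = config$seed,
           version = as.character(utils::packageVersion("cnvadmix"))),
      art("report.json"), auto_unbox = TRUE, digits = NA
    )
  }

  run_stage <- function(name, inputs, outputs, n_in, fn) {
    t0 <- Sys.time()
    cur_in <- unname(tools::md5sum(inputs))
    st <- state[[name]]
    if (!is.null(st) && all(file.exists(outputs)) &&
        identical(as.character(unlist(st$inputs)), as.character(cur_in))) {
      cur_out <- unname(tools::md5sum(outputs))
      if (!identical(as.character(unlist(st$outputs)), as.character(cur_out))) {
        abort(sprintf("checksum mismatch in outputs of stage `%s`; remove %s to force a re-run.",
                      name, paste(outputs, collapse = ", ")))
      }
      report <<- dplyr::add_row(report, stage = name, status = "skipped",
                                n_in = n_in(), n_out = st$n_out,
                                seconds = 0)
      flush_report()
      return(invisible(NULL))
    }
    n_out <- fn()
    state[[name]] <<- list(inputs = unname(tools::md5sum(inputs)),
                           outputs = unname(tools::md5sum(outputs)),
                           n_out = n_out)
    write_run_state(out, state)
    report <<- dplyr::add_row(report, stage = name, status = "ran",
                              n_in = n_in(), n_out = n_out,
                              seconds = as.numeric(difftime(Sys.time(), t0,
                                                            units = "secs")))
    flush_report()
    invisible(NULL)
  }

  # --- stage: simulate (or ingest provided inputs) -------------------------
  if (!is.null(config$simulate)) {
    seg_path <- art("segments.tsv"); man_path <- art("manifest.tsv")
    gen_path <- art("genome.tsv")
    run_stage("simulate", character(), c(seg_path, man_path, gen_path),
              function() 0L, function() {
                sim <- simulate_cnv_study(config$simulate)
                write_sim_study(sim, out)
                nrow(sim$segments)
              })
  } else {
    seg_path <- config$segments; man_path <- config$manifest
    gen_path <- config$genome
  }
  genome <- read_genome(gen_path)
  manifest <- read_manifest(man_path)

  # --- stage: filter -------------------------------------------------------
  run_stage("filter", seg_path, c(art("kept.tsv"), art("filter_report.json")),
            function() nrow(readr::read_tsv(seg_path, col_types = readr::cols(),
                                            progress = FALSE)),
            function() {
              segs <- read_segments(seg_path, genome)
              rep <- filter_segments(segs, config$policy, genome)
              write_segments(rep$kept, art("kept.tsv"))
              jsonlite::write_json(list(counts = rep$counts,
                                        policy = unclass(rep$policy)),
                                   art("filter_report.json"),
                                   auto_unbox = TRUE, digits = NA)
              nrow(rep$kept)
            })

  # --- stage: cnvr ---------------------------------------------------------
  run_stage("cnvr", c(art("kept.tsv"), man_path),
            c(art("cnvr.bed"), art("states.tsv")),
            function() nrow(readr::read_tsv(art("kept.tsv"),
                                            col_types = readr::cols(),
                                            progress = FALSE)),
            function() {
              kept <- read_segments(art("kept.tsv"), genome)
              cnvrs <- build_cnvrs(kept, manifest, min_freq = config$min_freq,
                                   genome = genome)
              write_cnvr_bed(cnvrs, art("cnvr.bed"))
              write_state_matrix(cnvrs$states, art("states.tsv"))
              nrow(cnvrs$regions)
            })

  # --- stage: genotypes ----------------------------------------------------
  run_stage("genotypes", art("states.tsv"),
            c(art("genotypes.tsv"), art("genotypes.structure.txt")),
            function() nrow(read_state_matrix(art("states.tsv"))),
            function() {
              states <- read_state_matrix(art("states.tsv"))
              geno <- code_biallelic(states)
              write_genotypes(geno, art("genotypes.tsv"))
              write_structure_format(geno, art("genotypes.structure.txt"),
                                     manifest)
              length(geno$loci)
            })

  # --- stage: structure ----------------------------------------------------
  run_stage("structure", c(art("states.tsv"), man_path),
            c(art("mds.tsv"), art("confusion.tsv")),
            function() nrow(read_state_matrix(art("states.tsv"))),
            function() {
              states <- read_state_matrix(art("states.tsv"))
              ps <- population_structure(states, manifest,
                                         n_trees = config$n_trees,
                                         dims = config$dims,
                                         seed = derive_seed(config$seed, "structure"))
              readr::write_tsv(ps$points, art("mds.tsv"), progress = FALSE)
              readr::write_tsv(as_tibble(ps$forest$confusion,
                                         rownames = "true"),
                               art("confusion.tsv"), progress = FALSE)
              nrow(ps$points)
            })

  # --- stage: admix --------------------------------------------------------
  run_stage("admix", art("genotypes.tsv"),
            c(art("Q.tsv"), art("ancestry_by_population.tsv")),
            function() length(read_genotypes(art("genotypes.tsv"))$loci),
            function() {
              geno <- read_genotypes(art("genotypes.tsv"))
              fit <- fit_admixture(geno, K = config$K,
                                   n_restarts = config$n_restarts,
                                   tol = config$tol,
                                   seed = derive_seed(config$seed, "admix"))
              q <- as_tibble(fit$Q, rownames = "sample_id")
              q$population <- manifest$population[match(q$sample_id,
                                                        manifest$sample_id)]
              readr::write_tsv(dplyr::relocate(q, "population",
                                               .after = "sample_id"),
                               art("Q.tsv"), progress = FALSE)
              readr::write_tsv(mean_ancestry_by_population(fit, manifest),
                               art("ancestry_by_population.tsv"),
                               progress = FALSE)
              nrow(q)
            })

  # --- stage: fst ----------------------------------------------------------
  run_stage("fst", art("genotypes.tsv"), art("fst.tsv"),
            function() length(read_genotypes(art("genotypes.tsv"))$loci),
            function() {
              geno <- read_genotypes(art("genotypes.tsv"))
              fst <- fst_all_pairs(geno, manifest)
              readr::write_tsv(fst$pairs, art("fst.tsv"), progress = FALSE)
              nrow(fst$pairs)
            })

  # --- stage: aic ----------------------------------------------------------
  has_roles <- any(manifest$role == "admixed") &&
    any(manifest$role == "ancestral_indian") &&
    any(manifest$role == "ancestral_african")
  if (has_roles) {
    run_stage("aic", c(art("cnvr.bed"), art("states.tsv"), man_path),
              art("aic.tsv"),
              function() nrow(read_state_matrix(art("states.tsv"))),
              function() {
                kept <- read_segments(art("kept.tsv"), genome)
                cnvrs <- build_cnvrs(kept, manifest,
                                     min_freq = config$min_freq,
                                     genome = genome)
                aic <- classify_aic(cnvr_ancestry_freqs(cnvrs, manifest),
                                    delta = config$delta, rare = config$rare)
                readr::write_tsv(aic, art("aic.tsv"), progress = FALSE)
                nrow(aic)
              })
  }

  # --- stage: enrich -------------------------------------------------------
  if (!is.null(config$genes) && !is.null(config$gene_sets)) {
    run_stage("enrich", c(art("cnvr.bed"), config$genes, config$gene_sets),
              art("enrichment.tsv"),
              function() nrow(read_cnvr_bed(art("cnvr.bed"))),
              function() {
                regions <- read_cnvr_bed(art("cnvr.bed"))
                genes <- read_gene_table(config$genes)
                query <- map_cnvr_to_genes(regions, genes)
                res <- hypergeom_enrich(query, read_gmt(config$gene_sets),
                                        genes$gene_id, alpha = config$alpha)
                readr::write_tsv(dplyr::select(as_tibble(res), -"hit_genes"),
                                 art("enrichment.tsv"), progress = FALSE)
                nrow(res)
              })
  }

  class(report) <- c("run_report", class(report))
  report
}
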