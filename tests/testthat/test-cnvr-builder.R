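two_sample_manifest <- function(n = 20) {
  manifest_for(sprintf("S%02d", seq_len(n)), "P1")
}

test_that("any-base overlap merges; abutting half-open intervals do not", {
  man <- two_sample_manifest(2)
  segs <- dplyr::bind_rows(
    seg_row(sample_id = "S01", start = 100L, end = 200L),
    seg_row(sample_id = "S02", start = 150L, end = 300L)
  )
  cn <- build_cnvrs(segs, man, min_freq = 0)
  expect_identical(nrow(cn$regions), 1L)
  expect_identical(cn$regions$start, 100L)
  expect_identical(cn$regions$end, 300L)

  segs2 <- dplyr::bind_rows(
    seg_row(sample_id = "S01", start = 100L, end = 200L),
    seg_row(sample_id = "S02", start = 200L, end = 300L)
  )
  cn2 <- build_cnvrs(segs2, man, min_freq = 0)
  expect_identical(nrow(cn2$regions), 2L)
})

test_that("the sample-frequency threshold discards rare candidate regions", {
  man <- two_sample_manifest(30)
  segs <- dplyr::bind_rows(
    seg_row(sample_id = "S01", start = 100L, end = 5000L), # 1/30 = 3.3%
    purrr::map_dfr(sprintf("S%02d", 1:5),
                   ~seg_row(sample_id = .x, start = 50000L, end = 60000L))
  )
  cn <- build_cnvrs(segs, man, min_freq = 0.05)
  expect_identical(cn$n_candidates, 2L)
  expect_identical(nrow(cn$regions), 1L)
  expect_identical(cn$regions$start, 50000L)
  expect_equal(cn$regions$carrier_freq, 5 / 30)
})

test_that("merging is order-independent and idempotent", {
  sim <- simulate_cnv_study(sim_config(n_loci = 60, seed = 8))
  kept <- filter_segments(sim$segments, filter_policy(), sim$genome)$kept
  cn1 <- build_cnvrs(kept, sim$manifest, genome = sim$genome)
  set.seed(42)
  shuffled <- kept[sample.int(nrow(kept)), ]
  cn2 <- build_cnvrs(shuffled, sim$manifest, genome = sim$genome)
  expect_identical(as.data.frame(cn1$regions), as.data.frame(cn2$regions))
  expect_identical(cn1$states, cn2$states)
  expect_identical(cn1$del_freq, cn2$del_freq)

  # rebuilding from the CNVR intervals returns the same intervals
  as_segments <- cn1$regions |>
    dplyr::transmute(sample_id = "S0", chrom, start, end, cn_state = 1L,
                     n_probes = 10L, max_gap = 100L, lod = 50,
                     confidence = 0)
  man0 <- manifest_for("S0")
  cn3 <- build_cnvrs(as_segments, man0, min_freq = 0, check_filtered = FALSE)
  expect_identical(cn3$regions[, c("chrom", "start", "end")],
                   cn1$regions[order(cn1$regions$chrom, cn1$regions$start),
                               c("chrom", "start", "end")])
})

test_that("merging agrees with GenomicRanges reduce on random intervals", {
  skip_if_not_installed("GenomicRanges")
  set.seed(99)
  for (rep in 1:5) {
    n <- 40
    start <- sample.int(10000, n)
    end <- start + sample.int(500, n)
    m <- cnvadmix:::merge_halfopen(start, end)$merged
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      "c", IRanges::IRanges(start = start + 1L, end = end)
    ), min.gapwidth = 0L)
    expect_identical(m$start, GenomicRanges::start(gr) - 1L)
    expect_identical(m$end, GenomicRanges::end(gr))
  }
})

test_that("per-sample state uses widest-segment precedence with documented ties", {
  man <- two_sample_manifest(2)
  # S01 has two overlapping member segments: wider one (state 3) must win
  segs <- dplyr::bind_rows(
    seg_row(sample_id = "S01", start = 100L, end = 200L, cn_state = 1L),
    seg_row(sample_id = "S01", start = 150L, end = 400L, cn_state = 3L),
    seg_row(sample_id = "S02", start = 300L, end = 390L, cn_state = 1L)
  )
  cn <- build_cnvrs(segs, man, min_freq = 0)
  expect_identical(unname(cn$states[1, "S01"]), 3L)
  # equal widths: more extreme deviation from 2 wins
  segs2 <- dplyr::bind_rows(
    seg_row(sample_id = "S01", start = 100L, end = 200L, cn_state = 1L),
    seg_row(sample_id = "S01", start = 150L, end = 250L, cn_state = 0L),
    seg_row(sample_id = "S02", start = 100L, end = 150L, cn_state = 1L)
  )
  cn2 <- build_cnvrs(segs2, man, min_freq = 0)
  expect_identical(unname(cn2$states[1, "S01"]), 0L)
  # equal widths, equal extremity (0 vs 4): loss wins
  segs3 <- dplyr::bind_rows(
    seg_row(sample_id = "S01", start = 100L, end = 200L, cn_state = 4L),
    seg_row(sample_id = "S01", start = 150L, end = 250L, cn_state = 0L),
    seg_row(sample_id = "S02", start = 100L, end = 150L, cn_state = 1L)
  )
  cn3 <- build_cnvrs(segs3, man, min_freq = 0)
  expect_identical(unname(cn3$states[1, "S01"]), 0L)
})

test_that("CNVR classification covers del, dup, gain_loss and rejects empty", {
  expect_identical(classify_cnvr(c(0L, 1L, 2L)), "del")
  expect_identical(classify_cnvr(c(2L, 3L, 4L)), "dup")
  expect_identical(classify_cnvr(c(1L, 2L, 3L)), "gain_loss")
  expect_error(classify_cnvr(c(2L, 2L)), "classify")
})

test_that("unfiltered input is rejected unless overridden", {
  man <- two_sample_manifest(2)
  bad <- seg_row(sample_id = "S01", lod = 2)
  expect_error(build_cnvrs(bad, man, min_freq = 0), "filter")
  expect_silent(build_cnvrs(bad, man, min_freq = 0, check_filtered = FALSE))
})

test_that("per-population frequency matrices count carriers over population size", {
  man <- dplyr::bind_rows(manifest_for(c("A1", "A2", "A3", "A4"), "PA"),
                          manifest_for(c("B1", "B2"), "PB"))
  segs <- dplyr::bind_rows(
    seg_row(sample_id = "A1", cn_state = 1L),
    seg_row(sample_id = "A2", cn_state = 0L),
    seg_row(sample_id = "B1", cn_state = 3L)
  )
  cn <- build_cnvrs(segs, man, min_freq = 0)
  expect_equal(unname(cn$del_freq[1, "PA"]), 0.5)   # 2 of 4
  expect_equal(unname(cn$dup_freq[1, "PA"]), 0)
  expect_equal(unname(cn$dup_freq[1, "PB"]), 0.5)   # 1 of 2
  expect_identical(cn$regions$class, "gain_loss")
})

test_that("point-in-region uses half-open inclusion and matches brute force", {
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(100L, 500L), end = c(200L, 900L))
  pts <- tibble::tibble(chrom = "chr1", pos = c(100L, 199L, 200L, 899L, 900L))
  kept <- intersect_points(pts, regions)
  expect_identical(kept$pos, c(100L, 199L, 899L))

  set.seed(7)
  n_reg <- 50
  regions <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n_reg, TRUE),
    start = sample.int(100000, n_reg)
  ) |> dplyr::mutate(end = start + sample.int(2000, n_reg))
  pts <- tibble::tibble(chrom = sample(c("chr1", "chr2", "chr3"), 10000, TRUE),
                        pos = sample.int(105000, 10000, replace = TRUE))
  fast <- intersect_points(pts, regions)
  brute <- vapply(seq_len(nrow(pts)), function(i) {
    any(regions$chrom == pts$chrom[i] & regions$start <= pts$pos[i] &
          pts$pos[i] < regions$end)
  }, logical(1))
  expect_identical(fast$chrom, pts$chrom[brute])
  expect_identical(fast$pos, pts$pos[brute])
  expect_identical(attr(fast, "n_inside"), sum(brute))
})
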