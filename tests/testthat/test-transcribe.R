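rna_fixture <- function() cached("rna_fixture", {
  cfg <- transcription_study_config()
  g <- sim_genome(cfg, seed = 401)
  cc <- excise_circles(g, cfg, seed = 402)
  rna <- sim_rnaseq(g, cc, seed = 403)
  ies_cc <- cc[cc$category %in% c("non_scrambled_ies", "scrambled_ies"), ]
  list(genome = g, circles = cc, rna = rna,
       intervals = tibble::tibble(contig = ies_cc$origin_contig,
                                  start = ies_cc$left_cut,
                                  end = ies_cc$right_cut,
                                  circle_id = ies_cc$circle_id))
})

test_that("length-normalized interval counts match an exhaustive intersection oracle", {
  segs <- dplyr::bind_rows(
    seg(sprintf("a%02d", 1:10), "c1", seq(0, 900, by = 100), seq(75, 975, by = 100), 0, 75)
  )
  iv <- tibble::tibble(contig = "c1", start = 0L, end = 1000L)
  out <- count_reads_in_intervals(segs, iv)
  expect_equal(out$n_reads, 10L)
  expect_equal(out$norm_count, 0.01)
  expect_equal(count_reads_in_intervals(segs,
    tibble::tibble(contig = "c2", start = 0L, end = 100L))$n_reads, 0L)
  expect_error(count_reads_in_intervals(segs,
    tibble::tibble(contig = "c1", start = 5L, end = 5L)), "zero")
  # exhaustive oracle on random intervals
  set.seed(44)
  rs <- tibble::tibble(
    read_id = sprintf("r%03d", 1:300),
    contig = sample(c("c1", "c2"), 300, replace = TRUE),
    start = as.integer(sample(0:2000, 300, replace = TRUE))
  ) |> dplyr::mutate(end = start + 75L)
  ivs <- tibble::tibble(
    contig = sample(c("c1", "c2"), 100, replace = TRUE),
    start = as.integer(sample(0:1800, 100, replace = TRUE))
  ) |> dplyr::mutate(end = start + as.integer(sample(50:400, 100, replace = TRUE)))
  got <- count_reads_in_intervals(rs, ivs)
  brute <- vapply(seq_len(nrow(ivs)), function(i) {
    sum(rs$contig == ivs$contig[i] & rs$end > ivs$start[i] &
          rs$start < ivs$end[i])
  }, numeric(1))
  expect_equal(got$n_reads, as.integer(brute))
  expect_equal(got$norm_count, brute / (ivs$end - ivs$start))
})

test_that("mid-rearrangement circle transcription beats the IES-restricted null", {
  fx <- rna_fixture()
  mid <- fx$rna$segments[fx$rna$segments$timepoint == "mid", ]
  nd <- permutation_percentile(fx$intervals, mid, "ies_only",
                               genome = fx$genome, n = 500, seed = 405)
  expect_s3_class(nd, "ecc_null")
  expect_equal(nd$n_shuffles, 500L)
  expect_gte(nd$percentile, 0.95)
  # pre-rearrangement signal is compatible with the null
  pre <- fx$rna$segments[fx$rna$segments$timepoint == "pre", ]
  nd_pre <- permutation_percentile(fx$intervals, pre, "ies_only",
                                   genome = fx$genome, n = 500, seed = 406)
  expect_gte(nd_pre$percentile, 0.2)
  expect_lte(nd_pre$percentile, 0.8)
  # genome-wide shuffles include genic space and swamp the circle signal
  nd_gw <- permutation_percentile(fx$intervals, mid, "genome_wide",
                                  genome = fx$genome, n = 500, seed = 407)
  expect_lt(nd_gw$percentile, nd$percentile)
})

test_that("permutation machinery is deterministic and error-checked", {
  fx <- rna_fixture()
  mid <- fx$rna$segments[fx$rna$segments$timepoint == "mid", ]
  a <- permutation_percentile(fx$intervals[1:10, ], mid, "ies_only",
                              genome = fx$genome, n = 50, seed = 9)
  b <- permutation_percentile(fx$intervals[1:10, ], mid, "ies_only",
                              genome = fx$genome, n = 50, seed = 9)
  expect_identical(a$replicates, b$replicates)
  expect_error(permutation_percentile(fx$intervals, mid, "ies_only",
                                      genome = fx$genome, n = 0), ">= 1")
  expect_error(permutation_percentile(fx$intervals, mid, "ies_only"), "genome")
  # observed mean of zero with nonzero background sits at percentile 0
  empty <- tibble::tibble(contig = fx$genome$mds$contig[1],
                          start = 0L, end = 10L) # edge region with no reads
  nd0 <- permutation_percentile(empty, mid, genome_domain(fx$genome),
                                genome = fx$genome, n = 100, seed = 10)
  expect_equal(nd0$percentile, 0)
  # percentile is invariant under global scaling of counts
  mid3 <- dplyr::bind_rows(mid, mid |> dplyr::mutate(read_id = paste0(read_id, "b")),
                           mid |> dplyr::mutate(read_id = paste0(read_id, "c")))
  a3 <- permutation_percentile(fx$intervals[1:10, ], mid3, "ies_only",
                               genome = fx$genome, n = 50, seed = 9)
  expect_equal(a3$percentile, a$percentile)
})

test_that("horizontal RNA coverage separates transcribed from silent circles", {
  fx <- rna_fixture()
  # single libraries: pooling replicates saturates the basal floor
  mid <- fx$rna$segments[fx$rna$segments$library == "mid_1", ]
  pre <- fx$rna$segments[fx$rna$segments$library == "pre_1", ]
  hr_mid <- horizontal_rna_coverage(fx$intervals, mid)
  hr_pre <- horizontal_rna_coverage(fx$intervals, pre)
  expect_true(all(hr_mid$per_circle$rna_coverage >= 0 &
                    hr_mid$per_circle$rna_coverage <= 1))
  expect_lt(hr_mid$summary$fraction_zero, hr_pre$summary$fraction_zero)
  # transcribed circles are near-fully tiled; a known silent circle is not
  tx <- hr_mid$per_circle$circle_id %in% fx$rna$transcribed
  expect_gt(mean(hr_mid$per_circle$rna_coverage[tx] > 0.8), 0.9)
  untiled <- tibble::tibble(contig = "absent", start = 0L, end = 100L)
  expect_equal(horizontal_rna_coverage(untiled, mid)$per_circle$rna_coverage, 0)
})

test_that("RNA reads across the circle junction map as permuted chimeras", {
  fx <- rna_fixture()
  tx_id <- fx$rna$transcribed[1]
  circ <- fx$circles[fx$circles$circle_id == tx_id, ]
  rd <- fx$rna$reads[!is.na(fx$rna$reads$circle_id) &
                       fx$rna$reads$circle_id == tx_id, ]
  truth_chim <- fx$rna$segments |>
    dplyr::filter(read_id %in% rd$read_id, chimeric)
  expect_gt(nrow(truth_chim), 0)
  segs <- map_reads(rd[, c("read_id", "seq")], fx$genome)
  calls <- detect_split_junctions(segs, nchar(fx$genome$contigs),
                                  library = "rna", genome = fx$genome)
  expect_gt(nrow(calls), 0)
  key <- paste(calls$contig, calls$circle_start, calls$circle_end)
  expect_true(all(key == paste(circ$origin_contig, circ$canon_start,
                               circ$canon_end)))
})

test_that("library subsampling equalizes depths binomially", {
  set.seed(45)
  segs <- tibble::tibble(
    library = rep(c("small", "big"), c(1000, 2000)),
    read_id = c(sprintf("s%04d", 1:1000), sprintf("b%04d", 1:2000)),
    contig = "c1", start = 0L, end = 75L
  )
  out <- subsample_normalize(segs, seed = 46)
  expect_equal(out$factors$factor[out$factors$library == "small"], 1)
  expect_equal(sum(out$segments$library == "small"), 1000L)
  kept_big <- sum(out$segments$library == "big")
  expect_lt(abs(kept_big - 1000), 3 * sqrt(2000 * 0.5 * 0.5))
  expect_true(all(out$factors$factor > 0 & out$factors$factor <= 1))
  # equal libraries pass unchanged
  eq <- segs |> dplyr::mutate(library = rep(c("a", "b"), each = 1500))
  expect_equal(nrow(subsample_normalize(eq, seed = 47)$segments), 3000L)
})
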