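mini_genome <- function() cached("mini_annot_genome", {
  cfg <- sim_config(cut_offset_sd = 0, fraction_scrambled = 0.5,
                    p_excise = c(non_scrambled = 1, scrambled = 1,
                                 intergenic = 1),
                    circles_per_ies = 1L)
  g <- sim_genome(cfg, seed = 301)
  list(genome = g, circles = excise_circles(g, cfg, seed = 302))
})

test_that("distance to the nearest MDS boundary handles exact hits and bare contigs", {
  mds <- tibble::tibble(contig = "c1", start = c(100L, 500L),
                        end = c(300L, 700L))
  circ <- tibble::tibble(contig = c("c1", "c1", "c2"),
                         start = c(300L, 555L, 40L),
                         end = c(460L, 590L, 90L))
  d <- distance_to_mds(circ, mds)
  expect_equal(d$dist_mds, c(0, 55, Inf))
  expect_equal(d$dist_start[2], 55)
  expect_equal(d$dist_end[2], 90)
})

test_that("distance bins cover the axis, sum to one, and bin Inf as none", {
  b <- bin_distances(c(0, 0, 0))
  expect_equal(as.numeric(b$freq), c(1, 0, 0, 0, 0))
  expect_error(bin_distances(numeric(0)), "empty")
  b2 <- bin_distances(c(10, 49, 50, 249, 250, 999, 1000, 2000, 2001, Inf))
  expect_equal(b2$n, c(2L, 2L, 2L, 2L, 2L))
  expect_equal(sum(b2$freq), 1)
  # multinomial oracle on uniform distances
  set.seed(62)
  u <- runif(6000, 0, 3000)
  b3 <- bin_distances(u)
  p <- c(50, 200, 750, 1001, 999) / 3001
  for (i in 1:5) {
    expect_lt(abs(b3$n[i] - 6000 * p[i]), 3 * sqrt(6000 * p[i] * (1 - p[i])))
  }
})

test_that("observed-vs-shuffled distance bins expose MDS proximity enrichment", {
  mg <- mini_genome()
  circ <- mg$circles[mg$circles$category == "non_scrambled_ies",
                     c("origin_contig", "left_cut", "right_cut")]
  names(circ) <- c("contig", "start", "end")
  db <- mds_distance_bins(circ, mg$genome, n = 60, seed = 63)
  expect_s3_class(db, "ecc_distance_bins")
  expect_equal(sum(db$observed), 1)
  # all real circles flank MDSs; shuffled ones mostly do not
  expect_equal(db$observed[1], 1)
  expect_gt(db$observed[1], db$null_mean[1] + 3 * db$null_sd[1])
})

test_that("cut sites classify into pointer/IES/MDS with signed pointer offsets", {
  mg <- mini_genome()
  g <- mg$genome
  ns <- mg$circles[mg$circles$category == "non_scrambled_ies", ]
  circ <- tibble::tibble(contig = ns$origin_contig, start = ns$left_cut,
                         end = ns$right_cut)
  cs <- classify_cut_sites(circ, g)
  # zero-noise cuts sit on the two pointer copies (start of copy 1, start of
  # copy 2 = its IES-facing edge)
  expect_equal(nrow(cs), 2L * nrow(circ))
  expect_true(all(cs$compartment == "pointer"))
  expect_true(all(cs$offset_from_pointer[cs$side == "right"] == 0L))
  el <- g$eliminated[match(ns$source_id, g$eliminated$elim_id), ]
  expect_identical(cs$offset_from_pointer[cs$side == "left"],
                   -el$pointer_len)
  # constructed offsets: 6 bp into the IES, 4 bp into the MDS
  p1 <- g$pointers[g$pointers$copy == 1, ][1, ]
  probe <- tibble::tibble(contig = p1$contig,
                          start = c(p1$end + 6L, p1$end - nchar(p1$seq) - 4L),
                          end = c(p1$end + 6L, p1$end - nchar(p1$seq) - 4L) + 200L)
  cs2 <- classify_cut_sites(probe, g) |> dplyr::filter(side == "left")
  expect_equal(cs2$compartment, c("IES", "MDS"))
  expect_equal(cs2$offset_from_pointer, c(6L, -(nchar(p1$seq) + 4L)))
})

test_that("flanking direct repeats match a brute-force per-base oracle", {
  # planted 7 bp repeat flanking both cuts
  set.seed(64)
  rep7 <- "GATTACA"
  left_flank <- random_dna_test(50)
  body <- random_dna_test(80)
  right_tail <- random_dna_test(50)
  gen <- c(p = paste0(left_flank, rep7, body, rep7, right_tail))
  circ <- tibble::tibble(contig = "p", start = 50L + 7L, end = 50L + 7L + 80L + 7L)
  fr <- flanking_direct_repeat(gen, circ)
  expect_gte(fr$repeat_len, 7L)
  expect_gte(fr$repeat_left, 7L)
  # junction with no shared sequence
  gen2 <- c(q = paste0(strrep("A", 30), strrep("C", 30), strrep("G", 30)))
  fr2 <- flanking_direct_repeat(gen2, tibble::tibble(contig = "q", start = 30L,
                                                     end = 60L))
  expect_equal(fr2$repeat_len, 0L)
  # brute-force oracle over random circles
  oracle <- function(seq, s, e, cap = 25L) {
    L <- 0L
    while (L < cap && s - L - 1 >= 0 &&
           substr(seq, s - L, s - L) == substr(seq, e - L, e - L)) L <- L + 1L
    R <- 0L
    while (R < cap && e + R + 1 <= nchar(seq) &&
           substr(seq, s + R + 1, s + R + 1) == substr(seq, e + R + 1, e + R + 1)) R <- R + 1L
    min(L + R, cap)
  }
  gen3 <- c(r = random_dna_test(4000))
  circ3 <- tibble::tibble(contig = "r",
                          start = as.integer(sample(100:1800, 200)),
                          end = 0L) |>
    dplyr::mutate(end = start + as.integer(sample(100:1500, 200, replace = TRUE)))
  fr3 <- flanking_direct_repeat(gen3, circ3)
  expected <- mapply(oracle, gen3, circ3$start, circ3$end)
  expect_equal(fr3$repeat_len, unname(as.integer(expected)))
})

test_that("eliminated-sequence categories follow MAC adjacency of flanking MDSs", {
  mg <- mini_genome()
  g <- mg$genome
  cc <- mg$circles
  circ <- tibble::tibble(contig = cc$origin_contig, start = cc$left_cut,
                         end = cc$right_cut, truth = cc$category)
  ce <- classify_eliminated_type(circ, g)
  expect_identical(ce$category[ce$truth == "non_scrambled_ies"],
                   rep("non_scrambled_ies", sum(ce$truth == "non_scrambled_ies")))
  expect_identical(ce$category[ce$truth == "scrambled_ies"],
                   rep("scrambled_ies", sum(ce$truth == "scrambled_ies")))
  expect_identical(ce$category[ce$truth == "intergenic"],
                   rep("intergenic", sum(ce$truth == "intergenic")))
  # invariant under swapping the circle's ends
  swapped <- circ |> dplyr::mutate(tmp = start, start = end, end = tmp)
  expect_identical(classify_eliminated_type(swapped, g)$category, ce$category)
  # a circle spanning a complete MDS is flagged mds_bearing
  m <- g$mds[1, ]
  big <- tibble::tibble(contig = m$contig, start = m$start - 60L,
                        end = m$end + 60L)
  expect_true(classify_eliminated_type(big, g)$mds_bearing)
})

test_that("eliminated-site summary reproduces reported percentages and chi-squared", {
  counts <- eliminated_site_counts() |>
    dplyr::select(category, sites_with_eccdna, total_sites)
  out <- eliminated_site_summary(counts)
  expect_equal(out$summary$pct_with_eccdna, c(0.46, 0.04, 0.10))
  expect_lt(out$chisq_p, 1e-9)
  # closed-form Pearson statistic oracle on the 2x2 table
  o <- matrix(c(555, 119613 - 555, 4, 10151 - 4), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(out$chisq_statistic, sum((o - e)^2 / e))
})

test_that("two-sample KS equals a brute-force ECDF scan", {
  expect_equal(ks_two_sample(1:10, 1:10)$statistic, 0)
  expect_equal(ks_two_sample(1:10, 101:110)$statistic, 1)
  set.seed(65)
  for (i in 1:5) {
    a <- rnorm(sample(10:40, 1))
    b <- rnorm(sample(10:40, 1), mean = runif(1, -1, 1))
    grid <- sort(c(a, b))
    d_brute <- max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x),
                              numeric(1))))
    expect_equal(ks_two_sample(a, b)$statistic, d_brute)
  }
})

test_that("cut-distance KS rejects under real spread differences at nominal type-I rate", {
  # wider cut spread inside IESs than MDSs: reject at n = 500
  set.seed(66)
  ies_d <- abs(rnorm(500, 0, 14))
  mds_d <- abs(rnorm(500, 0, 5))
  expect_lt(ks_two_sample(ies_d, mds_d)$p_value, 0.01)
  # identical distributions: rejection rate near alpha over 200 runs
  rej <- vapply(1:200, function(i) {
    ks_two_sample(rnorm(500), rnorm(500))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("interval shuffles preserve lengths and place uniformly", {
  g <- fix_genome()
  circ <- tibble::tibble(contig = "MIC_01",
                         start = c(1000L, 3000L, 5000L),
                         end = c(1400L, 3100L, 5900L))
  sh <- shuffle_intervals(circ, genome_domain(g), n = 50, seed = 67)
  expect_equal(nrow(sh), 150L)
  lens_by_rep <- sh |>
    dplyr::group_by(rep) |>
    dplyr::summarise(lens = list(sort(end - start)))
  expect_true(all(vapply(lens_by_rep$lens, identical,
                         logical(1), sort(circ$end - circ$start))))
  dom <- genome_domain(g)
  j <- dplyr::left_join(sh, dom, by = "contig", suffix = c("", ".d"))
  expect_true(all(j$start >= j$start.d & j$end <= j$end.d))
  expect_identical(shuffle_intervals(circ, dom, n = 3, seed = 9),
                   shuffle_intervals(circ, dom, n = 3, seed = 9))
  # uniform placement: one interval on one contig, 10000 draws
  one <- tibble::tibble(contig = "z", start = 0L, end = 50L)
  dom1 <- c(z = 1050L)
  draws <- shuffle_intervals(one, dom1, n = 10000, seed = 11)
  counts <- tabulate(draws$start %/% 100 + 1L, nbins = 10)
  expect_gt(chisq.test(counts)$p.value, 0.01)
  expect_error(shuffle_intervals(tibble::tibble(start = 0L, end = 5000L),
                                 c(z = 1000L)), "fits in no domain")
})

test_that("null-distribution objects summarise and tidy coherently", {
  nd <- null_distribution(5, c(1, 2, 3, 4, 6))
  expect_equal(nd$percentile, 0.8)
  expect_equal(glance(nd)$null_mean, 3.2)
  expect_equal(nrow(tidy(nd)), 5L)
  # ties count as not-below
  expect_equal(null_distribution(3, c(3, 3, 3))$percentile, 0)
  p <- autoplot(nd)
  expect_s3_class(p, "ggplot")
})
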