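test_that("the TBE junction pattern is matched, classified and strand-symmetric", {
  hit <- paste0("ACGTAC", "GGTTTTGGGGTTTTGAATCAAAACCCCAAAACC", "GTACGT")
  out <- count_tbe_junction_reads(c(hit))
  expect_equal(out$n_reads[out$class == "GANTC"], 1L)
  expect_equal(sum(out$n_reads), 1L)
  none <- count_tbe_junction_reads(c("ACGTACGTACGTACGTACGTACGTACGTACGTACGT"))
  expect_equal(sum(none$n_reads), 0L)
  # reverse complement of every read leaves all counts unchanged
  mixed <- c(hit, revcomp(hit),
             paste0("AA", "GGTTTTGGGGTTTTGACTTAAAACCCCAAAACC", "TT"), # GANTT -> other
             "ACGTACGTACGTACGT")
  fwd <- count_tbe_junction_reads(mixed)
  rc <- count_tbe_junction_reads(revcomp(mixed))
  expect_identical(fwd$n_reads, rc$n_reads)
  expect_equal(fwd$n_reads[fwd$class == "other"], 1L)
  # a read matching twice still counts once
  twice <- count_tbe_junction_reads(c(paste0(hit, hit)))
  expect_equal(sum(twice$n_reads), 1L)
})

test_that("junction-read classes over constructed junctions equal the truth tally", {
  set.seed(91)
  n <- 10000
  tirL14 <- "AAAACCCCAAAACC"
  tirR14 <- "GGTTTTGGGGTTTT"
  x <- sample(c("C", "G", "A", "T"), n, replace = TRUE,
              prob = c(0.19, 0.52, 0.22, 0.07))
  nbase <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  reads <- paste0("G", vapply(seq_len(n), function(i) random_dna_test(20), ""),
                  tirR14, "GA", nbase, "T", x, tirL14,
                  vapply(seq_len(n), function(i) random_dna_test(20), ""))
  flip <- runif(n) < 0.5
  reads[flip] <- revcomp(reads[flip])
  out <- count_tbe_junction_reads(reads)
  truth <- table(factor(ifelse(x == "T", "other", paste0("GANT", x)),
                        levels = c("GANTC", "GANTG", "GANTA", "other")))
  expect_equal(out$n_reads, as.integer(truth))
  # class frequencies match the configured composition (chi-squared GoF)
  gof <- chisq.test(as.integer(truth), p = c(0.19, 0.52, 0.22, 0.07))
  expect_gt(gof$p.value, 0.01)
})

test_that("permuted split alignments yield junction calls; ordinary splits do not", {
  lens <- c(c1 = 2000L)
  permuted <- dplyr::bind_rows(
    seg("r1", "c1", 800, 840, 0, 40),                       # prefix downstream
    seg("r1", "c1", 300, 337, 40, 77, supplementary = TRUE) # suffix upstream
  )
  call <- detect_split_junctions(permuted, lens)
  expect_equal(nrow(call), 1L)
  expect_equal(call$circle_start, 300L)
  expect_equal(call$circle_end, 840L)
  expect_equal(call$evidence, "split_read")
  # deletion-like split (prefix upstream) is not circular
  ordinary <- dplyr::bind_rows(
    seg("r2", "c1", 300, 340, 0, 40),
    seg("r2", "c1", 800, 837, 40, 77, supplementary = TRUE)
  )
  expect_equal(nrow(detect_split_junctions(ordinary, lens)), 0L)
  expect_error(detect_split_junctions(permuted, c(other = 100L)),
               "unknown contig")
})

test_that("retained split calls respect every stated filter (fuzzed)", {
  set.seed(92)
  lens <- c(c1 = 3000L, c2 = 2500L)
  rows <- list()
  for (i in 1:150) {
    ctg <- sample(names(lens), 1)
    a <- sample(0:2800, 1); b <- sample(0:2800, 1)
    w1 <- sample(20:40, 1); w2 <- 75 - w1
    rows[[i]] <- dplyr::bind_rows(
      seg(sprintf("f%03d", i), ctg, a, min(a + w1, lens[[ctg]]), 0, w1,
          strand = sample(c("+", "-"), 1),
          mapq = sample(c(0L, 4L, 60L), 1),
          duplicate = runif(1) < 0.2),
      seg(sprintf("f%03d", i), sample(names(lens), 1), b,
          min(b + w2, lens[[ctg]]), w1, 75,
          strand = sample(c("+", "-"), 1),
          mapq = sample(c(0L, 60L), 1), supplementary = TRUE)
    )
  }
  segs <- dplyr::bind_rows(rows)
  calls <- detect_split_junctions(segs, lens)
  if (nrow(calls) > 0) {
    expect_true(all(calls$circle_end > calls$circle_start))
    expect_true(all(calls$circle_start >= 150))
    expect_true(all(calls$circle_end <= lens[calls$contig] - 150))
    for (id in calls$read_id) {
      pair <- segs[segs$read_id == id, ]
      expect_true(all(pair$mapq >= 5))
      expect_false(any(pair$duplicate))
      expect_equal(length(unique(pair$contig)), 1L)
      expect_equal(length(unique(pair$strand)), 1L)
    }
  }
})

test_that("planted circles with precise cuts are recovered at exact coordinates", {
  cfg <- recovery_config(cut_offset_sd = 0)
  g <- sim_genome(cfg, seed = 201)
  cc <- excise_circles(g, cfg, seed = 202)
  expect_gte(nrow(cc), 50)
  mol <- as_molecules(cc)
  rp <- tagment_and_read(mol, config = cfg, library = "mid_1", depth = cfg$depth,
                         seed = 203)
  idx <- build_genome_index(g)
  segs <- map_pairs(rp, g, idx)
  calls <- detect_split_junctions(segs, nchar(g$contigs), library = "mid_1",
                                  genome = g)
  tkey <- paste(cc$origin_contig, cc$canon_start, cc$canon_end)
  ckey <- paste(calls$contig, calls$circle_start, calls$circle_end)
  expect_true(all(ckey %in% tkey))             # no false junctions
  expect_gte(sum(unique(tkey) %in% ckey), 45)  # >= 45 of ~52 recovered exactly
})

test_that("9 bp duplication geometry requires exactly nine bases of 5' overlap", {
  lens <- c(c1 = 2000L)
  mk <- function(offset) {
    dplyr::bind_rows(
      seg("p", "c1", 500, 575, 0, 75, "+", mate = 1L),
      seg("p", "c1", 500 + offset - 75, 500 + offset, 0, 75, "-", mate = 2L)
    )
  }
  reads <- tibble::tibble(pair_id = "p",
                          mate1_seq = strrep("A", 75),
                          mate2_seq = strrep("T", 75))
  expect_equal(nrow(detect_9bp_duplications(reads, mk(9), lens)), 1L)
  expect_equal(nrow(detect_9bp_duplications(reads, mk(8), lens)), 0L)
  expect_equal(nrow(detect_9bp_duplications(reads, mk(10), lens)), 0L)
  # concordant inward-facing pair from linear DNA
  inward <- dplyr::bind_rows(
    seg("p", "c1", 500, 575, 0, 75, "+", mate = 1L),
    seg("p", "c1", 800, 875, 0, 75, "-", mate = 2L)
  )
  expect_equal(nrow(detect_9bp_duplications(reads, inward, lens)), 0L)
  expect_error(detect_9bp_duplications(tibble::tibble(pair_id = "p"),
                                       mk(9), lens), "paired")
})

test_that("forced single-cut circles are detected at the recorded cut", {
  g <- fix_genome(); idx <- fix_index()
  cc <- cached("circles", excise_circles(fix_genome(), seed = 102))
  circ <- cc[cc$category != "tbe" & cc$length >= 200 & cc$length <= 320, ][1:8, ]
  mol <- as_molecules(circ)
  rp <- tagment_and_read(mol, config = g$config, library = "L",
                         force_single_cut = TRUE, seed = 204)
  segs <- map_pairs(rp, g, idx)
  calls <- detect_9bp_duplications(rp, segs, nchar(g$contigs), library = "L")
  expect_equal(nrow(calls), nrow(rp))
  # cut locus = molecule cut position mapped to the genome
  expected_cut <- mol$start[match(rp$molecule_id, mol$molecule_id)] + rp$frag_start
  got <- calls$cut_start[match(rp$pair_id, calls$read_id)]
  expect_identical(got, as.integer(expected_cut))
})

test_that("TIR consensus recovers flank composition and skips unanchorable elements", {
  set.seed(93)
  n <- 100
  arm <- paste0("AAAACCCCAAAACCCC", random_dna_test(14))
  flank4 <- sample(c("G", "A", "C"), n, replace = TRUE,
                   prob = c(0.5, 0.25, 0.25))
  nbase <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    paste0(random_dna_test(3), flank4[i], "A", nbase[i], "T", arm,
           random_dna_test(60), revcomp(arm), "A", nbase[i], "T",
           random_dna_test(4))
  }, character(1))
  out <- tir_consensus(seqs, max_mismatch = 0)
  expect_equal(attr(out, "n_used"), n)
  expect_equal(attr(out, "n_skipped"), 0L)
  # positions 5 and 7 read A and T on both sides, always
  expect_equal(out$freq[out$position == 5 & out$base == "A"], c(1, 1))
  expect_equal(out$freq[out$position == 7 & out$base == "T"], c(1, 1))
  # left position 4 recovers the constructed composition within 3 binomial sd
  p4 <- out[out$side == "left" & out$position == 4, ]
  for (b in c("G", "A", "C")) {
    p_true <- c(G = 0.5, A = 0.25, C = 0.25)[[b]]
    obs <- ifelse(b %in% p4$base, p4$n[p4$base == b], 0)
    expect_lt(abs(obs - n * p_true), 3 * sqrt(n * p_true * (1 - p_true)) + 1e-9)
  }
  # two mismatches in the anchor motif are tolerated; five are not
  drifted <- sub("AAAACCCCAAAACCCC", "AAAACCGCAAATCCCC", seqs[2], fixed = TRUE)
  broken <- sub("AAAACCCCAAAACCCC", "AAAACTGCATAACCGC", seqs[1], fixed = TRUE)
  out2 <- tir_consensus(c(drifted, broken), max_mismatch = 2)
  expect_equal(attr(out2, "n_used"), 1L)
  expect_equal(attr(out2, "n_skipped"), 1L)
})
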