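test_that("exact, chimeric and reverse-complement reads map as specified", {
  g <- fix_genome(); idx <- fix_index()
  s <- g$contigs[["MIC_01"]]
  m <- map_reads(c(a = substr(s, 101, 175)), g, index = idx)
  expect_equal(m[, c("contig", "ref_start", "ref_end", "mapq", "strand")],
               tibble::tibble(contig = "MIC_01", ref_start = 100L,
                              ref_end = 175L, mapq = 60L, strand = "+"))
  # permuted-order chimera: prefix from 500, suffix from 200
  r2 <- paste0(substr(s, 501, 540), substr(s, 201, 235))
  m2 <- map_reads(c(b = r2), g, index = idx)
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$read_start, c(0L, 40L))
  expect_equal(m2$read_end, c(40L, 75L))
  expect_equal(m2$ref_start, c(500L, 200L))
  expect_equal(sum(m2$supplementary), 1L)
  m3 <- map_reads(c(c = revcomp(substr(s, 101, 175))), g, index = idx)
  expect_equal(m3$strand, "-")
  expect_equal(m3$ref_start, 100L)
  expect_error(map_reads(tibble::tibble(read_id = character(), seq = character()),
                         g, index = idx), "no reads")
  expect_error(build_genome_index(character(0)), "empty genome")
})

test_that("ambiguous placements get mapq 0 with deterministic tie-breaking", {
  dup <- random_dna_test(120)
  gen <- c(c1 = paste0(random_dna_test(200), dup, random_dna_test(200), dup,
                       random_dna_test(100)))
  m <- map_reads(c(r = substr(dup, 11, 90)), gen)
  expect_equal(m$mapq, 0L)
  expect_equal(m$ref_start, 210L) # leftmost of the tied placements
  m2 <- map_reads(c(r = substr(dup, 11, 90)), gen) # rerun: identical
  expect_identical(m, m2)
})

test_that("primary placements match a brute-force substring oracle on a small genome", {
  set.seed(71)
  gen <- c(tig1 = random_dna_test(6000), tig2 = random_dna_test(4000))
  reads <- lapply(1:80, function(i) {
    ctg <- sample(names(gen), 1)
    n <- sample(40:90, 1)
    st <- sample(nchar(gen[[ctg]]) - n, 1)
    x <- substr(gen[[ctg]], st + 1, st + n)
    if (runif(1) < 0.5) x <- revcomp(x)
    x
  })
  reads <- stats::setNames(unlist(reads), sprintf("r%03d", 1:80))
  m <- map_reads(reads, gen)
  expect_true(all(!m$unmapped))
  for (i in seq_len(nrow(m))) {
    r <- reads[[m$read_id[i]]]
    oriented <- if (m$strand[i] == "-") revcomp(r) else r
    # exhaustive scan: all exact placements of the full read
    hits <- lapply(names(gen), function(ctg) {
      h <- Biostrings::start(Biostrings::matchPattern(oriented, gen[[ctg]]))
      if (length(h)) tibble::tibble(contig = ctg, pos = h - 1L)
    })
    hits <- dplyr::bind_rows(hits)
    expect_equal(m$ref_start[i], hits$pos[1])
    expect_equal(m$contig[i], hits$contig[1])
    expect_equal(m$mapq[i], if (nrow(hits) == 1L) 60L else 0L)
  }
})

test_that("no segment extends past its contig end", {
  g <- fix_genome(); idx <- fix_index()
  lens <- nchar(g$contigs)
  set.seed(72)
  # reads hugging contig ends and random junk
  reads <- c(
    substr(g$contigs[["MIC_02"]], 1, 60),
    substr(g$contigs[["MIC_02"]], lens[["MIC_02"]] - 59, lens[["MIC_02"]]),
    replicate(20, random_dna_test(75))
  )
  names(reads) <- sprintf("e%02d", seq_along(reads))
  m <- map_reads(reads, g, index = idx)
  mm <- m[!m$unmapped, ]
  expect_true(all(mm$ref_start >= 0))
  expect_true(all(mm$ref_end <= lens[mm$contig]))
})

test_that("simulated non-junction reads map back to their true coordinates", {
  g <- fix_genome(); idx <- fix_index()
  cc <- cached("circles", excise_circles(fix_genome(), seed = 102))
  mol <- as_molecules(cc)
  rp <- tagment_and_read(mol, config = g$config, library = "mid_1", seed = 73)
  rp <- rp[rp$category != "tbe", ][1:500, ]
  segs <- map_pairs(rp, g, idx)
  truth <- truth_alignments(rp, mol)
  lin <- truth[!truth$chimeric, ]
  prim <- segs[!segs$supplementary & !segs$unmapped, ]
  j <- dplyr::inner_join(lin, prim, by = c("pair_id" = "read_id", "mate"))
  expect_gt(nrow(j), 600)
  ok <- j$contig.x == j$contig.y & j$start == j$ref_start &
    j$end == j$ref_end & j$strand.x == j$strand.y
  expect_gte(mean(ok), 0.99)
})

test_that("duplicate marking keeps one representative, independent of input order", {
  s <- dplyr::bind_rows(
    seg("p1", "c", 100, 175, 0, 75, "+", mate = 1L),
    seg("p1", "c", 300, 375, 0, 75, "-", mate = 2L),
    seg("p2", "c", 100, 175, 0, 75, "+", mate = 1L),
    seg("p2", "c", 300, 375, 0, 75, "-", mate = 2L),
    seg("p3", "c", 101, 176, 0, 75, "+", mate = 1L),
    seg("p3", "c", 300, 375, 0, 75, "-", mate = 2L)
  )
  out <- mark_duplicates(s)
  expect_setequal(unique(out$read_id[out$duplicate]), "p2")
  shuffled <- s[rev(seq_len(nrow(s))), ]
  out2 <- mark_duplicates(shuffled)
  expect_setequal(unique(out2$read_id[out2$duplicate]), "p2")
  # ten copies -> nine flagged
  many <- dplyr::bind_rows(lapply(sprintf("q%02d", 1:10), function(id) {
    dplyr::bind_rows(seg(id, "c", 10, 85, 0, 75, "+", mate = 1L),
                     seg(id, "c", 200, 275, 0, 75, "-", mate = 2L))
  }))
  out3 <- mark_duplicates(many)
  expect_equal(length(unique(out3$read_id[out3$duplicate])), 9L)
  expect_false("q01" %in% out3$read_id[out3$duplicate])
  # all-unique input unchanged
  uni <- dplyr::bind_rows(seg("u1", "c", 1, 70, 0, 69, "+", mate = 1L),
                          seg("u1", "c", 90, 160, 0, 70, "-", mate = 2L))
  expect_false(any(mark_duplicates(uni)$duplicate))
})
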