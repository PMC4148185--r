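# Gene annotation of islands and positional structure tests.

mk_islands <- function(chrom, start, end) {
  out <- data.frame(chrom = chrom, start = start, end = end,
                    criterion = rep("both", length(chrom)),
                    n_windows = rep(1L, length(chrom)),
                    size_bp = end - start)
  class(out) <- c("island_set", "data.frame")
  out
}

two_chrom_meta <- function(fragments = NULL) {
  read_genome_meta(
    data.frame(chrom = c("chr1", "chrX"), length = c(2e7, 1e6),
               is_x = c(FALSE, TRUE)),
    centromeres = data.frame(chrom = c("chr1", "chrX"),
                             position = c(1e7, 5e5)),
    fragments = fragments)
}

test_that("gene overlap counting matches a brute-force interval scan", {
  isl <- mk_islands("chr1", 0, 200000)
  genes <- data.frame(chrom = "chr1", start = c(50000, 190000, 300000),
                      end = c(60000, 210000, 310000),
                      id = c("g1", "g2", "g3"))
  ann <- annotate_islands(isl, genes)
  expect_equal(ann$per_island$n_genes, 2L)
  expect_equal(ann$per_island$genes, "g1,g2")

  single <- annotate_islands(mk_islands("chr1", 40000, 70000), genes)
  expect_true(single$per_island$single_gene)
  none <- annotate_islands(mk_islands("chr1", 500000, 600000), genes)
  expect_equal(none$per_island$n_genes, 0L)

  set.seed(77)
  for (rep in 1:40) {
    n_i <- sample(1:8, 1); n_g <- sample(1:25, 1)
    is <- sort(sample(0:500, n_i)) * 1000
    isl <- mk_islands(sample(c("chr1", "chr2"), n_i, TRUE), is,
                      is + sample(1:50, n_i, TRUE) * 1000)
    gs <- sort(sample(0:500, n_g)) * 1000
    genes <- data.frame(chrom = sample(c("chr1", "chr2"), n_g, TRUE),
                        start = gs, end = gs + sample(1:30, n_g, TRUE) * 1000,
                        id = paste0("g", seq_len(n_g)))
    got <- annotate_islands(isl, genes)$per_island$n_genes
    want <- vapply(seq_len(n_i), function(k)
      sum(genes$chrom == isl$chrom[k] & genes$start < isl$end[k] &
            genes$end > isl$start[k]), integer(1))
    expect_equal(got, want)
  }
})

test_that("malformed gene annotation is fatal with a line number", {
  expect_error(
    read_genome_meta(data.frame(chrom = "chr1", length = 1e6),
                     genes = data.frame(chrom = "chr1", start = 5e5,
                                        end = 2e6, id = "g1")),
    "line 1")
})

test_that("partition enrichment matches the exact binomial tail", {
  meta <- two_chrom_meta()
  isl <- mk_islands(c(rep("chrX", 20), rep("chr1", 20)),
                    rep(0, 40), rep(100000, 40))
  res <- partition_enrichment(isl, meta, "X", expected = "genome")
  expect_equal(res$expected_fraction, 1e6 / 2.1e7)
  expect_equal(res$p_value,
               oracle_binom_tail(20, 40, 1e6 / 2.1e7), tolerance = 1e-12)
  expect_lt(res$p_value, 1e-10)

  # observed equal to expectation: not significant
  res2 <- partition_enrichment(mk_islands(c("chrX", rep("chr1", 20)),
                                          rep(0, 21), rep(1e5, 21)),
                               meta, "X", expected = "genome")
  expect_gt(res2$p_value, 0.3)

  # all islands in the partition with expected fraction 1 -> p = 1
  metaX <- read_genome_meta(data.frame(chrom = "chrX", length = 1e6,
                                       is_x = TRUE))
  resX <- partition_enrichment(mk_islands(rep("chrX", 5), rep(0, 5),
                                          rep(1e5, 5)),
                               metaX, "X", expected = "genome")
  expect_equal(resX$p_value, 1)

  # zero islands -> undefined
  expect_true(is.na(partition_enrichment(mk_islands(character(0),
                                                    integer(0), integer(0)),
                                         meta, "X",
                                         expected = "genome")$p_value))
})

test_that("surveyed-fraction mode uses target fragments", {
  frags <- data.frame(chrom = c(rep("chr1", 8), rep("chrX", 2)),
                      start = seq(0, by = 1e5, length.out = 10),
                      end = seq(0, by = 1e5, length.out = 10) + 1200,
                      id = paste0("f", 1:10))
  meta <- two_chrom_meta(fragments = frags)
  res <- partition_enrichment(mk_islands("chrX", 0, 1e5), meta, "X",
                              expected = "surveyed")
  expect_equal(res$expected_fraction, 0.2)
})

test_that("centromere proximity uses the 5 Mb midpoint rule", {
  meta <- two_chrom_meta()
  near <- mk_islands("chr1", 1e7 - 3e6, 1e7 - 2.9e6)   # midpoint ~2.95 Mb away
  far <- mk_islands("chr1", 0, 1e5)
  isl <- rbind(near, far)
  class(isl) <- c("island_set", "data.frame")
  res <- partition_enrichment(isl, meta, "centromere", expected = "genome")
  expect_equal(res$observed, 1L)
})

test_that("island size contrast reproduces the exact rank test", {
  meta <- two_chrom_meta()
  isl <- mk_islands(c("chr1", "chr1", "chrX", "chrX"),
                    c(0, 2e5, 0, 2e5) ,
                    c(0, 2e5, 0, 2e5) + c(100000, 110000, 500000, 510000))
  res <- compare_island_sizes(isl, meta, "X")
  expect_equal(res$mean_in, 505000)
  expect_equal(res$mean_out, 105000)
  expect_equal(res$p_value,
               oracle_mannwhitney(c(500000, 510000), c(100000, 110000)),
               tolerance = 1e-12)

  set.seed(88)
  for (rep in 1:30) {
    nx <- sample(2:6, 1); na <- sample(2:6, 1)
    sx <- sample(1:1000, nx) * 1000; sa <- sample(1001:2000, na) * 1000
    isl <- mk_islands(c(rep("chrX", nx), rep("chr1", na)),
                      rep(0, nx + na), c(sx, sa))
    res <- compare_island_sizes(isl, meta, "X")
    expect_equal(res$p_value, oracle_mannwhitney(sx, sa),
                 tolerance = 1e-12)
  }

  # single island in a stratum -> undefined
  res1 <- compare_island_sizes(mk_islands(c("chrX", "chr1", "chr1"),
                                          rep(0, 3), c(1e5, 2e5, 3e5)),
                               meta, "X")
  expect_true(is.na(res1$p_value))
})

test_that("fragment contrasts split by overlap and handle edge cases", {
  fs <- data.frame(chrom = rep("chr1", 6),
                   start = seq(0, by = 1e6, length.out = 6),
                   end = seq(0, by = 1e6, length.out = 6) + 1200,
                   rnd = c(0.9, 0.85, 0.2, 0.25, 0.22, 0.21))
  isl <- mk_islands("chr1", 0, 1.2e6)  # covers fragments 1 and 2
  res <- contrast_fragments(fs, isl, "rnd", test = "t")
  expect_equal(res$n_inside, 2L)
  expect_equal(res$mean_inside, 0.875)
  expect_lt(res$p_value, 0.05)

  # all fragments outside -> undefined
  res0 <- contrast_fragments(fs, mk_islands("chr2", 0, 1e5), "rnd")
  expect_true(is.na(res0$p_value))

  # identical values -> Mann-Whitney p = 1
  fs$rnd <- rep(0.5, 6)
  res1 <- contrast_fragments(fs, isl, "rnd", test = "mannwhitney")
  expect_equal(res1$p_value, 1)
  expect_error(contrast_fragments(fs, isl, "nope"), "unknown")
})
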