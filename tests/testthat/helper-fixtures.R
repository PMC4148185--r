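# In-code fixtures: a hand-written miniature VCF and direct site_table
# constructors, plus random haplotype-pool generators for the oracle
# equivalence checks.

test_popmap <- function(n1 = 6, n2 = 6, outgroup = TRUE) {
  df <- data.frame(
    sample = c(paste0("p1_", seq_len(n1)), paste0("p2_", seq_len(n2)),
               if (outgroup) "outgroup"),
    population = c(rep("pop1", n1), rep("pop2", n2),
                   if (outgroup) "outgroup"),
    stringsAsFactors = FALSE)
  pop_spec(df, outgroup = if (outgroup) "outgroup" else NULL)
}

write_popmap <- function(popmap, path = tempfile(fileext = ".tsv")) {
  write.table(popmap, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# records: data.frame chrom, pos, ref, alt + genotype columns (strings)
write_test_vcf <- function(records, samples,
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- apply(records, 1, function(r) {
    paste(c(r[["chrom"]], r[["pos"]], ".", r[["ref"]], r[["alt"]], ".",
            ".", ".", "GT", unlist(r[samples])), collapse = "\t")
  })
  writeLines(c(hdr, body), path)
  path
}

# build a site_table directly from count vectors (no VCF round trip)
make_site_table <- function(chrom, pos, ac1, an1, ac2, an2,
                            og = NA_character_, n_dip = c(6L, 6L)) {
  n <- length(pos)
  tab <- data.frame(chrom = chrom, pos = as.integer(pos),
                    ref = rep("A", n), alt = rep("G", n),
                    ac1 = ac1, an1 = an1, miss1 = (2L * n_dip[1L] - an1) %/% 2L,
                    ac2 = ac2, an2 = an2, miss2 = (2L * n_dip[2L] - an2) %/% 2L,
                    og = og, stringsAsFactors = FALSE)
  structure(tab,
            popmap = test_popmap(n_dip[1L], n_dip[2L]),
            n_dip = n_dip, dropped = c(non_biallelic_or_indel = 0L),
            filters = list(), gt = NULL,
            class = c("site_table", "data.frame"))
}

# random haplotype pools for one fragment; returns haplotype matrices and
# the equivalent polarized site_table rows (complete data, ref ancestral)
random_fragment <- function(n1 = 8, n2 = 8, n_sites = 12, L = 500,
                            chrom = "chr1", offset = 0,
                            og_random = FALSE) {
  repeat {
    h <- matrix(rbinom((n1 + n2) * n_sites, 1,
                       rep(runif(n_sites, 0.05, 0.95), each = n1 + n2)),
                nrow = n1 + n2)
    keep <- colSums(h) > 0 & colSums(h) < (n1 + n2)
    if (any(keep)) break
  }
  h <- h[, keep, drop = FALSE]
  h1 <- h[seq_len(n1), , drop = FALSE]
  h2 <- h[n1 + seq_len(n2), , drop = FALSE]
  pos <- offset + sort(sample.int(L, ncol(h)))
  og <- if (og_random) sample(c("A", "G"), ncol(h), TRUE) else "A"
  tab <- make_site_table(chrom, pos,
                         ac1 = colSums(h1), an1 = n1,
                         ac2 = colSums(h2), an2 = n2,
                         og = og, n_dip = c(n1 %/% 2, n2 %/% 2))
  tab <- polarize(tab)
  list(h1 = h1, h2 = h2, og = as.integer(og == "G"), table = tab, L = L,
       fragment = data.frame(chrom = chrom, start = offset,
                             end = offset + L, id = "f1",
                             outgroup_span = L))
}

# read a synth_genome's VCF back through the package reader
read_sites_from_genome <- function(g) {
  path <- tempfile(fileext = ".vcf")
  on.exit(unlink(path))
  diffscan:::.write_vcf_plain(g$vcf, path)
  read_sites(path, pop_spec(g$popmap))
}

# small synthetic genome config shared by scan/context tests
small_synth <- function(islands = TRUE, n_islands = 3, seed = 1, ...) {
  cfg <- synth_config(...)
  if (islands)
    cfg <- synth_config(islands = place_islands(cfg, n_islands = n_islands),
                        ...)
  generate_genome(cfg, seed = seed)
}

# run the scan stages on an in-memory synthetic genome (default thresholds)
scan_islands <- function(g, n_perm = 0, seed = 1) {
  tab <- read_sites_from_genome(g)
  tab <- site_stats(filter_maf(filter_missingness(polarize(tab))))
  w <- make_windows(g$genome_meta)
  tr <- window_scan(tab, w)
  totals <- c(sum(tab$class == "fixed", na.rm = TRUE),
              sum(tab$class == "shared", na.rm = TRUE))
  tr <- z_scores(fisher_scan(tr, totals))
  perm <- if (n_perm > 0)
    permutation_clustering_test(tab, w, n_perm = n_perm, seed = seed)
  list(table = tab, track = tr, totals = totals, permutation = perm,
       islands = intersect_islands(call_islands(tr, "zscore"),
                                   call_islands(tr, "fisher")))
}
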