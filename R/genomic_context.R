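# Annotation of islands with genes and tests of positional structure:
# sex-chromosome and centromere enrichment, island-size contrasts, and
# island-vs-background contrasts of fragment statistics.

#' Overlap islands with gene annotation
#'
#' @param islands An `island_set`.
#' @param genes Gene intervals (data.frame `chrom`, `start`, `end`, `id`),
#'   typically `genome_meta$genes`.
#' @return List with `per_island` (data.frame `island`, `chrom`, `start`,
#'   `end`, `n_genes`, `genes` — comma-separated ids, `single_gene` flag)
#'   and `summary` (islands with 0, exactly 1, <=3 and >10 genes).
#' @export
annotate_islands <- function(islands, genes) {
  n_genes <- integer(nrow(islands))
  gene_ids <- character(nrow(islands))
  if (nrow(islands) > 0 && nrow(genes) > 0) {
    gi <- GenomicRanges::GRanges(islands$chrom,
                                 IRanges::IRanges(islands$start + 1L,
                                                  islands$end))
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gi, gg))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    for (k in seq_len(nrow(islands))) {
      ids <- genes$id[si[qi == k]]
      n_genes[k] <- length(ids)
      gene_ids[k] <- paste(ids, collapse = ",")
    }
  }
  per_island <- data.frame(island = seq_len(nrow(islands)),
                           chrom = islands$chrom, start = islands$start,
                           end = islands$end, n_genes = n_genes,
                           genes = gene_ids,
                           single_gene = n_genes == 1L,
                           stringsAsFactors = FALSE)
  list(per_island = per_island,
       summary = list(n_islands = nrow(islands),
                      total_genes = sum(n_genes),
                      zero_genes = sum(n_genes == 0L),
                      single_gene = sum(n_genes == 1L),
                      up_to_three_genes = sum(n_genes <= 3L),
                      over_ten_genes = sum(n_genes > 10L)))
}

.island_partition <- function(islands, genome_meta,
                              partition = c("X", "centromere"),
                              radius = 5e6,
                              centromere_mode = c("midpoint", "span")) {
  partition <- match.arg(partition)
  centromere_mode <- match.arg(centromere_mode)
  chroms <- genome_meta$chroms
  if (partition == "X") {
    islands$chrom %in% chroms$chrom[chroms$is_x]
  } else {
    cen <- chroms$centromere[match(islands$chrom, chroms$chrom)]
    if (centromere_mode == "midpoint") {
      mid <- (islands$start + islands$end) / 2
      !is.na(cen) & abs(mid - cen) <= radius
    } else {
      !is.na(cen) & islands$start <= cen + radius &
        islands$end >= cen - radius
    }
  }
}

.partition_fraction <- function(genome_meta, partition, radius,
                                expected = c("surveyed", "genome")) {
  expected <- match.arg(expected)
  chroms <- genome_meta$chroms
  if (expected == "surveyed") {
    fr <- genome_meta$fragments
    if (is.null(fr))
      stop("expected = 'surveyed' needs target fragments in genome_meta")
    if (partition == "X") {
      in_part <- fr$chrom %in% chroms$chrom[chroms$is_x]
    } else {
      cen <- chroms$centromere[match(fr$chrom, chroms$chrom)]
      mid <- (fr$start + fr$end) / 2
      in_part <- !is.na(cen) & abs(mid - cen) <= radius
    }
    sum(fr$end[in_part] - fr$start[in_part]) / sum(fr$end - fr$start)
  } else {
    len <- as.numeric(chroms$length)
    if (partition == "X") {
      sum(len[chroms$is_x]) / sum(len)
    } else {
      span <- pmin(chroms$centromere + radius, len) -
        pmax(chroms$centromere - radius, 0)
      span[is.na(span)] <- 0
      sum(span) / sum(len)
    }
  }
}

#' Positional enrichment of islands
#'
#' One-sided exact binomial test of the number of islands falling in a
#' genomic partition (the X chromosome, or within `radius` of a
#' centromere — island midpoint distance by default) against the fraction
#' of territory the partition represents. That fraction is computed from
#' the surveyed target fragments by default (sampling density varies along
#' the genome), or from raw chromosome lengths with `expected = "genome"`.
#'
#' @param islands An `island_set`.
#' @param genome_meta A `genome_meta`.
#' @param partition `"X"` or `"centromere"`.
#' @param expected `"surveyed"` (default) or `"genome"`.
#' @param radius Centromere distance in bp (default 5 Mb).
#' @param centromere_mode `"midpoint"` (island midpoint within `radius`,
#'   default) or `"span"` (any overlap of the island span with the
#'   centromeric window).
#' @return List: `partition`, `n_islands`, `observed` (count in
#'   partition), `observed_fraction`, `expected_fraction`, `p_value`
#'   (one-sided, enrichment), `test`.
#' @export
partition_enrichment <- function(islands, genome_meta,
                                 partition = c("X", "centromere"),
                                 expected = c("surveyed", "genome"),
                                 radius = 5e6,
                                 centromere_mode = c("midpoint", "span")) {
  partition <- match.arg(partition)
  in_part <- .island_partition(islands, genome_meta, partition, radius,
                               centromere_mode)
  frac <- .partition_fraction(genome_meta, partition, radius, expected)
  n <- nrow(islands)
  obs <- sum(in_part)
  p <- if (n == 0) NA_real_ else
    binom.test(obs, n, p = frac, alternative = "greater")$p.value
  list(partition = partition, n_islands = n, observed = obs,
       observed_fraction = if (n > 0) obs / n else NA_real_,
       expected_fraction = frac, p_value = p,
       test = "one-sided exact binomial")
}

#' Compare island sizes between strata
#'
#' Two-sided Mann-Whitney U test of island sizes inside versus outside a
#' partition (X vs autosomes by default).
#'
#' @inheritParams partition_enrichment
#' @return List with stratum means, counts and the p-value (`NA` when a
#'   stratum has fewer than 2 islands).
#' @export
compare_island_sizes <- function(islands, genome_meta,
                                 partition = c("X", "centromere"),
                                 radius = 5e6) {
  partition <- match.arg(partition)
  in_part <- .island_partition(islands, genome_meta, partition, radius)
  a <- islands$size_bp[in_part]
  b <- islands$size_bp[!in_part]
  p <- if (length(a) < 2 || length(b) < 2) NA_real_ else
    suppressWarnings(wilcox.test(a, b))$p.value
  list(partition = partition,
       n_in = length(a), n_out = length(b),
       mean_in = if (length(a)) mean(a) else NA_real_,
       mean_out = if (length(b)) mean(b) else NA_real_,
       p_value = p, test = "two-sided Mann-Whitney U")
}

#' Contrast a fragment statistic inside vs outside islands
#'
#' Assigns fragments to the island stratum by >= 1 bp overlap with any
#' island and compares the chosen statistic (RND or Fay & Wu's H, any
#' numeric column of the fragment table) between strata with a t-test or
#' Mann-Whitney U test. Low RND reflects reduced between-population
#' divergence relative to the outgroup — ongoing gene exchange — so
#' fragments inside islands of differentiation are expected to show
#' *higher* RND than the freely introgressing background.
#'
#' @param frag_stats Output of [fragment_stats()].
#' @param islands An `island_set`.
#' @param statistic Column name, e.g. `"rnd"` (default) or
#'   `"fay_wu_h_p1"`.
#' @param test `"t"` or `"mannwhitney"`.
#' @return List with group means, sizes and two-sided p-value (`NA` when
#'   either stratum has fewer than 2 defined values).
#' @export
contrast_fragments <- function(frag_stats, islands, statistic = "rnd",
                               test = c("t", "mannwhitney")) {
  test <- match.arg(test)
  if (!statistic %in% names(frag_stats))
    stop("unknown fragment statistic: ", statistic)
  inside <- rep(FALSE, nrow(frag_stats))
  if (nrow(islands) > 0) {
    gf <- GenomicRanges::GRanges(frag_stats$chrom,
                                 IRanges::IRanges(frag_stats$start + 1L,
                                                  frag_stats$end))
    gi <- GenomicRanges::GRanges(islands$chrom,
                                 IRanges::IRanges(islands$start + 1L,
                                                  islands$end))
    inside <- suppressWarnings(IRanges::overlapsAny(gf, gi))
  }
  x <- frag_stats[[statistic]][inside]
  y <- frag_stats[[statistic]][!inside]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  p <- if (length(x) < 2 || length(y) < 2) NA_real_
  else if (length(unique(c(x, y))) == 1L) 1  # no variation at all
  else if (test == "t") t.test(x, y)$p.value
  else suppressWarnings(wilcox.test(x, y))$p.value
  list(statistic = statistic, test = test,
       n_inside = length(x), n_outside = length(y),
       mean_inside = if (length(x)) mean(x) else NA_real_,
       mean_outside = if (length(y)) mean(y) else NA_real_,
       p_value = p)
}
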