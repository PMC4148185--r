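# Reading, validating, filtering and polarizing the SNP table.
#
# A site_table is a data.frame (one row per bi-allelic SNP, sorted by
# chromosome then position) with per-population alternate-allele counts and
# called-chromosome totals, plus the outgroup allele where available. The
# original genotype-string matrix is kept as an attribute so a filtered
# table can be written back to VCF losslessly.

#' Read a sample-to-population map
#'
#' The map is a two-column tab-separated file (`sample<TAB>population`,
#' no header). Exactly two ingroup population labels are required; one
#' additional label may designate the outgroup.
#'
#' @param path Path to the TSV file.
#' @param outgroup Label identifying the outgroup population. Default
#'   `"outgroup"`; use `NULL` when no outgroup is present.
#' @return A data.frame with columns `sample` and `population`, of class
#'   `pop_spec`, with attributes `ingroup` (the two ingroup labels, in the
#'   order they first appear) and `outgroup`.
#' @export
read_popmap <- function(path, outgroup = "outgroup") {
  df <- read.delim(path, header = FALSE, col.names = c("sample", "population"),
                   colClasses = "character")
  pop_spec(df, outgroup = outgroup)
}

#' Construct a population specification
#'
#' @param df Data.frame with columns `sample` and `population`.
#' @inheritParams read_popmap
#' @return A `pop_spec` object (see [read_popmap()]).
#' @export
pop_spec <- function(df, outgroup = "outgroup") {
  stopifnot(is.data.frame(df), all(c("sample", "population") %in% names(df)))
  if (anyDuplicated(df$sample))
    stop("duplicated sample ids in population map")
  labels <- unique(df$population)
  og <- if (!is.null(outgroup) && outgroup %in% labels) outgroup else NULL
  ingroup <- setdiff(labels, og)
  if (length(ingroup) != 2L)
    stop("expected exactly two ingroup population labels, got: ",
         paste(ingroup, collapse = ", "))
  for (p in ingroup)
    if (sum(df$population == p) < 2L)
      stop("ingroup population '", p, "' has fewer than 2 samples")
  structure(df[, c("sample", "population")],
            ingroup = ingroup, outgroup = og,
            class = c("pop_spec", "data.frame"))
}

#' Read bi-allelic SNPs from a VCF into a site table
#'
#' Parses a VCF 4.x file (plain or bgzipped) and tabulates, for every
#' retained bi-allelic SNP, the alternate-allele count and the number of
#' called chromosomes in each ingroup population, the number of missing
#' diploid genotypes per population, and the (haploidized) outgroup allele.
#' Indel and multi-allelic records are dropped and counted.
#'
#' @param vcf_path Path to the VCF.
#' @param popmap A `pop_spec` from [read_popmap()] or [pop_spec()]. Every
#'   sample listed must be present in the VCF header (extra VCF samples are
#'   ignored).
#' @return A `site_table`: a data.frame with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `ac1`, `an1`, `miss1`, `ac2`, `an2`, `miss2`,
#'   `og` (outgroup allele or `NA`), plus `dc1`, `dc2`, `anc`,
#'   `ancestral_known` once [polarize()] has run. Attributes: `popmap`,
#'   `n_dip` (diploid sample sizes), `dropped` (records removed at parse
#'   time), `filters` (log of applied filters), `gt` (genotype strings for
#'   VCF round-trips).
#' @export
read_sites <- function(vcf_path, popmap) {
  stopifnot(inherits(popmap, "pop_spec"))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(vcf@gt) == 0L) stop("VCF has no genotype records")
  samples <- colnames(vcf@gt)[-1L]
  missing_samples <- setdiff(popmap$sample, samples)
  if (length(missing_samples))
    stop("samples in population map absent from VCF header: ",
         paste(missing_samples, collapse = ", "))

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p)) stop("VCF is not position-sorted on ", ch)
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_dropped <- sum(!snp)

  gt <- vcf@gt[snp, c("FORMAT", popmap$sample), drop = FALSE]
  chrom <- chrom[snp]; pos <- pos[snp]; ref <- ref[snp]; alt <- alt[snp]

  ingroup <- attr(popmap, "ingroup")
  og_label <- attr(popmap, "outgroup")
  gtm <- gt[, -1L, drop = FALSE]
  gtm[] <- sub(":.*", "", gtm)  # strip non-GT fields
  alt_count <- function(g) {
    g[is.na(g)] <- "./."
    a <- (substr(g, 1, 1) == "1") + (substr(g, 3, 3) == "1")
    a[substr(g, 1, 1) == "." | substr(g, 3, 3) == "."] <- NA_integer_
    a
  }
  counts <- matrix(alt_count(gtm), nrow = nrow(gtm),
                   dimnames = dimnames(gtm))
  pop_of <- popmap$population[match(colnames(counts), popmap$sample)]

  tab_pop <- function(label) {
    m <- counts[, pop_of == label, drop = FALSE]
    miss <- rowSums(is.na(m))
    list(ac = rowSums(m, na.rm = TRUE),
         an = 2L * (ncol(m) - miss),
         miss = miss)
  }
  p1 <- tab_pop(ingroup[1L]); p2 <- tab_pop(ingroup[2L])

  og <- rep(NA_character_, length(pos))
  if (!is.null(og_label)) {
    g <- gtm[, pop_of == og_label, drop = FALSE][, 1L]
    g[is.na(g)] <- "."
    a1 <- substr(g, 1, 1); a2 <- substr(g, 3, 3)
    a2[a2 == ""] <- a1[a2 == ""]  # haploid GT
    hom_ref <- a1 == "0" & a2 == "0"
    hom_alt <- a1 == "1" & a2 == "1"
    og[hom_ref] <- ref[hom_ref]
    og[hom_alt] <- alt[hom_alt]
  }

  tab <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    ac1 = p1$ac, an1 = p1$an, miss1 = p1$miss,
                    ac2 = p2$ac, an2 = p2$an, miss2 = p2$miss,
                    og = og, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  if (anyDuplicated(tab[, c("chrom", "pos")]))
    stop("duplicate chrom/pos records in VCF")
  structure(tab,
            popmap = popmap,
            n_dip = c(sum(pop_of == ingroup[1L]), sum(pop_of == ingroup[2L])),
            dropped = c(non_biallelic_or_indel = n_dropped),
            filters = list(),
            gt = gt,
            class = c("site_table", "data.frame"))
}

.log_filter <- function(tab, name, n_before, n_after, params) {
  f <- attr(tab, "filters")
  f[[length(f) + 1L]] <- list(filter = name, n_before = n_before,
                              n_after = n_after, params = params)
  attr(tab, "filters") <- f
  tab
}

.subset_sites <- function(tab, keep) {
  at <- attributes(tab)
  out <- as.data.frame(tab)[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("popmap", "n_dip", "dropped", "filters"))
    attr(out, a) <- at[[a]]
  if (!is.null(at$gt)) attr(out, "gt") <- at$gt[keep, , drop = FALSE]
  class(out) <- c("site_table", "data.frame")
  out
}

#' Remove SNPs with excessive genotype missingness
#'
#' A SNP is dropped when more than `max_missing` diploid genotypes are
#' missing in *either* ingroup population.
#'
#' @param table A `site_table`.
#' @param max_missing Maximum tolerated missing genotypes per population
#'   (default 2).
#' @return The filtered `site_table`, with the filter logged in its
#'   `filters` attribute.
#' @export
filter_missingness <- function(table, max_missing = 2L) {
  stopifnot(inherits(table, "site_table"), max_missing >= 0)
  keep <- table$miss1 <= max_missing & table$miss2 <= max_missing
  out <- .subset_sites(table, keep)
  .log_filter(out, "missingness", nrow(table), sum(keep),
              list(max_missing = max_missing))
}

#' Remove low minor-allele-frequency SNPs
#'
#' By default the minor-allele frequency is computed on the pooled ingroup
#' sample (both populations' called chromosomes combined); sites with
#' MAF strictly below `threshold` are removed, which also removes sites
#' monomorphic across the ingroup. The per-population mode keeps a site if
#' its within-population MAF reaches the threshold in at least one
#' population or if it is a fixed difference between the populations.
#'
#' @param table A `site_table`.
#' @param threshold MAF cutoff in `[0, 0.5)`; default 0.10.
#' @param mode `"pooled"` (default) or `"per_population"`.
#' @return The filtered `site_table`.
#' @export
filter_maf <- function(table, threshold = 0.10,
                       mode = c("pooled", "per_population")) {
  stopifnot(inherits(table, "site_table"))
  mode <- match.arg(mode)
  if (threshold < 0 || threshold >= 0.5)
    stop("MAF threshold must lie in [0, 0.5)")
  an <- table$an1 + table$an2
  ac <- table$ac1 + table$ac2
  p_pooled <- ifelse(an > 0, ac / an, NA_real_)
  mono <- is.na(p_pooled) | p_pooled == 0 | p_pooled == 1
  if (mode == "pooled") {
    maf <- pmin(p_pooled, 1 - p_pooled)
    keep <- !mono & maf >= threshold
  } else {
    f1 <- ifelse(table$an1 > 0, table$ac1 / table$an1, NA_real_)
    f2 <- ifelse(table$an2 > 0, table$ac2 / table$an2, NA_real_)
    maf1 <- pmin(f1, 1 - f1); maf2 <- pmin(f2, 1 - f2)
    fixed_diff <- (f1 == 1 & f2 == 0) | (f1 == 0 & f2 == 1)
    keep <- !mono &
      (pmax(maf1, maf2, na.rm = TRUE) >= threshold | fixed_diff %in% TRUE)
  }
  keep[is.na(keep)] <- FALSE
  out <- .subset_sites(table, keep)
  .log_filter(out, "maf", nrow(table), sum(keep),
              list(threshold = threshold, mode = mode))
}

#' Polarize alleles into ancestral and derived states
#'
#' Uses the outgroup allele carried in the table (or supplied separately)
#' to orient each SNP: where the outgroup matches one of the two ingroup
#' alleles, that allele is called ancestral and the derived-allele counts
#' `dc1`/`dc2` are set accordingly. Sites with a missing outgroup call, or
#' where the outgroup carries a third state, get `ancestral_known = FALSE`
#' (their `dc` columns default to the alternate-allele counts).
#'
#' @param table A `site_table`.
#' @param outgroup_calls Optional data.frame `chrom`, `pos`, `allele`
#'   overriding the outgroup alleles read from the VCF.
#' @return The `site_table` with columns `anc`, `ancestral_known`, `dc1`,
#'   `dc2` filled in.
#' @export
polarize <- function(table, outgroup_calls = NULL) {
  stopifnot(inherits(table, "site_table"))
  og <- table$og
  if (!is.null(outgroup_calls)) {
    key <- paste(table$chrom, table$pos)
    m <- match(key, paste(outgroup_calls$chrom, outgroup_calls$pos))
    og <- ifelse(is.na(m), NA_character_, outgroup_calls$allele[m])
  }
  anc_is_ref <- !is.na(og) & og == table$ref
  anc_is_alt <- !is.na(og) & og == table$alt
  table$ancestral_known <- anc_is_ref | anc_is_alt
  table$anc <- ifelse(anc_is_ref, table$ref,
                      ifelse(anc_is_alt, table$alt, NA_character_))
  table$dc1 <- ifelse(anc_is_alt, table$an1 - table$ac1, table$ac1)
  table$dc2 <- ifelse(anc_is_alt, table$an2 - table$ac2, table$ac2)
  table
}

#' Write a site table back to VCF
#'
#' Emits the retained records with their original genotype strings, so that
#' reading the file again with [read_sites()] reproduces the table.
#'
#' @param table A `site_table` produced by [read_sites()] (its genotype
#'   attribute must still be present).
#' @param path Output path; written bgzip-compressed if it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(table, path) {
  stopifnot(inherits(table, "site_table"))
  gt <- attr(table, "gt")
  if (is.null(gt)) stop("site_table has lost its genotype attribute")
  n <- nrow(table)
  fix <- cbind(CHROM = table$chrom, POS = as.character(table$pos),
               ID = rep(".", n), REF = table$ref, ALT = table$alt,
               QUAL = rep(".", n), FILTER = rep(".", n), INFO = rep(".", n))
  vcf <- .new_vcfR(
             meta = c("##fileformat=VCFv4.2",
                      "##source=diffscan",
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             fix = fix, gt = gt)
  if (!grepl("\\.gz$", path)) {
    .write_vcf_plain(vcf, path)
  } else {
    vcfR::write.vcf(vcf, file = path)
  }
  invisible(path)
}

.new_vcfR <- function(meta, fix, gt) {
  methods::new(methods::getClassDef("vcfR", package = "vcfR"),
               meta = meta, fix = fix, gt = gt)
}

# vcfR only writes gzipped VCF; plain text goes through a temporary gz file.
.write_vcf_plain <- function(vcf, path) {
  tmp <- tempfile(fileext = ".vcf.gz")
  on.exit(unlink(tmp), add = TRUE)
  vcfR::write.vcf(vcf, file = tmp)
  con_in <- gzfile(tmp, "rb"); on.exit(close(con_in), add = TRUE)
  lines <- readLines(con_in)
  writeLines(lines, path)
}

#' Filter report
#'
#' @param table A `site_table`.
#' @return A list describing records dropped at parse time and each applied
#'   filter (name, parameters, row counts before/after). Suitable for
#'   [jsonlite::write_json()].
#' @export
filter_report <- function(table) {
  stopifnot(inherits(table, "site_table"))
  list(dropped_at_parse = as.list(attr(table, "dropped")),
       n_sites = nrow(table),
       filters = attr(table, "filters"))
}

#' @export
print.site_table <- function(x, ...) {
  nd <- attr(x, "n_dip")
  ing <- attr(attr(x, "popmap"), "ingroup")
  cat("site_table:", nrow(x), "bi-allelic SNPs on",
      length(unique(x$chrom)), "chromosome(s)\n")
  cat("  populations:", ing[1L], paste0("(", nd[1L], " diploids), "),
      ing[2L], paste0("(", nd[2L], " diploids)"),
      if (!is.null(attr(attr(x, "popmap"), "outgroup"))) "+ outgroup" else "",
      "\n")
  for (f in attr(x, "filters"))
    cat("  filter", f$filter, ":", f$n_before, "->", f$n_after, "\n")
  invisible(x)
}
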