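# End-to-end orchestration: filter -> site statistics -> window scan ->
# island demarcation -> genomic context -> report bundle.

#' Build a pipeline configuration
#'
#' Thresholds default to the standard scan settings: 100 kb windows every
#' 10 kb, MAF cutoff 0.10, Z-score threshold 3, Fisher threshold 0.01,
#' 50 kb island merge gap.
#'
#' @param vcf,popmap,chrom_sizes Input paths (required).
#' @param centromeres,genes,fragments Optional input paths.
#' @param out_dir Output directory for the report bundle.
#' @param window_size,step Scan geometry in bp.
#' @param maf Pooled minor-allele-frequency cutoff.
#' @param max_missing Maximum missing genotypes per population per SNP.
#' @param z_threshold,fisher_p Island significance thresholds.
#' @param merge_gap Island merge distance in bp.
#' @param min_snps Minimum SNPs per window.
#' @param min_outgroup_span Minimum aligned outgroup span for RND (bp).
#' @param n_perm Permutation replicates for the clustering test (0 skips
#'   the test).
#' @param seed Integer seed.
#' @param class_source `"maf_filtered"` (default): fixed/shared counts for
#'   the Fisher scan come from the same MAF-filtered table as F_ST;
#'   `"unfiltered"` uses the missingness-filtered table instead (fixed
#'   differences always pass the MAF filter, shared polymorphisms need
#'   not).
#' @param center Z-score centering (`"median"` or `"mean"`).
#' @param alternative Sidedness of the Fisher test.
#' @param outgroup Outgroup label in the population map.
#' @return A `scan_config` list.
#' @export
scan_config <- function(vcf, popmap, chrom_sizes, centromeres = NULL,
                        genes = NULL, fragments = NULL, out_dir = NULL,
                        window_size = 100000, step = 10000, maf = 0.10,
                        max_missing = 2, z_threshold = 3, fisher_p = 0.01,
                        merge_gap = 50000, min_snps = 5,
                        min_outgroup_span = 1000, n_perm = 1000, seed = 1,
                        class_source = c("maf_filtered", "unfiltered"),
                        center = "median",
                        alternative = c("two.sided", "greater"),
                        outgroup = "outgroup") {
  cfg <- list(vcf = vcf, popmap = popmap, chrom_sizes = chrom_sizes,
              centromeres = centromeres, genes = genes,
              fragments = fragments, out_dir = out_dir,
              window_size = window_size, step = step, maf = maf,
              max_missing = max_missing, z_threshold = z_threshold,
              fisher_p = fisher_p, merge_gap = merge_gap,
              min_snps = min_snps,
              min_outgroup_span = min_outgroup_span, n_perm = n_perm,
              seed = seed, class_source = match.arg(class_source),
              center = center, alternative = match.arg(alternative),
              outgroup = outgroup)
  class(cfg) <- "scan_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [scan_config()].
#' @return A `scan_config`.
#' @export
read_scan_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scan_config, y)
}

# order-stable hash of the configuration (file-content independent)
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full differentiation scan
#'
#' Executes the pipeline: read and validate the SNP table, apply the
#' missingness and MAF filters, polarize against the outgroup, compute
#' per-fragment statistics (on the pre-MAF table, which still holds the
#' rare variants and outgroup-divergence sites), scan windows (mean F_ST,
#' Z-scores, Fisher fixed-vs-shared), demarcate and intersect islands,
#' run the permutation clustering test, and annotate genomic context.
#' With `out_dir` set in the config, writes `windows.tsv`,
#' `islands_{zscore,fisher,both}.bed` and `.tsv`, `fragment_stats.tsv`,
#' `filtered.vcf`, and `report.json` (config, config hash, filter report,
#' genome totals, permutation and context results). Outputs contain no
#' timestamps, so a rerun with the same inputs and seed is byte-identical.
#'
#' @param config A `scan_config` or path to a YAML file.
#' @return A `scan_result` list with all intermediate tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_scan_config(config)
  stopifnot(inherits(config, "scan_config"))

  popmap <- read_popmap(config$popmap, outgroup = config$outgroup)
  sites <- read_sites(config$vcf, popmap)
  sites <- filter_missingness(sites, config$max_missing)
  sites <- polarize(sites)
  meta <- read_genome_meta(config$chrom_sizes, config$centromeres,
                           config$genes, config$fragments)

  frag_stats <- NULL
  if (!is.null(meta$fragments))
    frag_stats <- fragment_stats(sites, meta, config$min_outgroup_span)

  prefilter <- site_stats(sites)
  tab <- filter_maf(sites, config$maf)
  tab <- site_stats(tab)

  windows <- make_windows(meta, config$window_size, config$step)
  class_table <- if (config$class_source == "unfiltered") prefilter else NULL
  track <- window_scan(tab, windows, min_snps = config$min_snps,
                       class_table = class_table)
  cls <- if (config$class_source == "unfiltered") prefilter$class else
    tab$class
  totals <- c(fixed = sum(cls == "fixed", na.rm = TRUE),
              shared = sum(cls == "shared", na.rm = TRUE))
  track <- fisher_scan(track, totals, alternative = config$alternative)
  track <- z_scores(track, center = config$center)

  islands_z <- call_islands(track, "zscore",
                            z_threshold = config$z_threshold,
                            merge_gap = config$merge_gap)
  islands_f <- call_islands(track, "fisher",
                            p_threshold = config$fisher_p,
                            merge_gap = config$merge_gap)
  islands_b <- intersect_islands(islands_z, islands_f)

  perm <- NULL
  if (config$n_perm > 0)
    perm <- permutation_clustering_test(tab, windows,
                                        n_perm = config$n_perm,
                                        seed = config$seed,
                                        z_threshold = config$z_threshold,
                                        min_snps = config$min_snps,
                                        center = config$center)

  context <- list()
  if (!is.null(meta$genes))
    context$genes <- annotate_islands(islands_b, meta$genes)
  expected_mode <- if (is.null(meta$fragments)) "genome" else "surveyed"
  if (any(meta$chroms$is_x) && nrow(islands_b) > 0) {
    context$x_enrichment <- partition_enrichment(islands_b, meta, "X",
                                                 expected = expected_mode)
    context$size_contrast <- compare_island_sizes(islands_b, meta, "X")
  }
  if (any(!is.na(meta$chroms$centromere)) && nrow(islands_b) > 0)
    context$centromere_enrichment <-
      partition_enrichment(islands_b, meta, "centromere",
                           expected = expected_mode)
  if (!is.null(frag_stats) && nrow(islands_b) > 0) {
    context$rnd_contrast <- contrast_fragments(frag_stats, islands_b,
                                               "rnd", test = "t")
    context$h_contrast <- contrast_fragments(frag_stats, islands_b,
                                             "fay_wu_h_p1", test = "t")
  }

  result <- structure(list(config = config,
                           config_hash = .config_hash(config),
                           sites = tab, prefilter_sites = prefilter,
                           genome_meta = meta, frag_stats = frag_stats,
                           track = track, genome_totals = totals,
                           islands = list(zscore = islands_z,
                                          fisher = islands_f,
                                          both = islands_b),
                           permutation = perm, context = context),
                      class = "scan_result")
  if (!is.null(config$out_dir)) .write_bundle(result, config$out_dir)
  result
}

.write_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(as.data.frame(result$track), "windows.tsv")
  for (cr in names(result$islands)) {
    isl <- result$islands[[cr]]
    tsv(as.data.frame(isl), paste0("islands_", cr, ".tsv"))
    write_bed(isl, file.path(dir, paste0("islands_", cr, ".bed")))
  }
  if (!is.null(result$frag_stats)) tsv(result$frag_stats,
                                       "fragment_stats.tsv")
  write_sites_vcf(result$sites, file.path(dir, "filtered.vcf"))
  report <- list(
    package_version = as.character(utils::packageVersion("diffscan")),
    config = result$config[!vapply(result$config, is.null, logical(1))],
    config_hash = result$config_hash,
    filter_report = filter_report(result$sites),
    genome_totals = as.list(result$genome_totals),
    n_islands = lapply(result$islands, nrow),
    permutation = if (!is.null(result$permutation))
      result$permutation[c("p_value", "observed", "n_perm", "statistic",
                           "seed")],
    context = result$context[setdiff(names(result$context), "genes")])
  if (!is.null(result$context$genes)) {
    report$gene_summary <- result$context$genes$summary
    tsv(result$context$genes$per_island, "island_genes.tsv")
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result (config", substr(x$config_hash, 1, 8), ")\n")
  cat("  SNPs after filters:", nrow(x$sites), "\n")
  cat("  windows:", nrow(x$track), "(", sum(x$track$defined), "defined )\n")
  cat("  islands: z =", nrow(x$islands$zscore),
      ", fisher =", nrow(x$islands$fisher),
      ", both =", nrow(x$islands$both), "\n")
  if (!is.null(x$permutation))
    cat("  permutation clustering p =", x$permutation$p_value, "\n")
  invisible(x)
}

#' @export
summary.scan_result <- function(object, ...) {
  cls <- table(object$sites$class)
  cat("Site classes (MAF-filtered table):\n")
  print(cls)
  cat("\nMean per-SNP F_ST:",
      format(mean(object$sites$fst, na.rm = TRUE), digits = 3), "\n")
  cat("Genome fixed:shared =", object$genome_totals[1L], ":",
      object$genome_totals[2L], "\n")
  for (nm in names(object$context)) {
    if (nm == "genes") next
    cx <- object$context[[nm]]
    if (!is.null(cx$p_value))
      cat(nm, ": p =", format(cx$p_value, digits = 3), "\n")
  }
  invisible(object)
}
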