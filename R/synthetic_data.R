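# Self-contained synthetic test genomes: two populations of diploid
# genotypes at ~1.2 kb target fragments spread over several chromosomes,
# simulated locus by locus under the structured coalescent with background
# gene flow, planted low-introgression islands, and one outgroup sampled
# from a deeper split.

#' Configure a synthetic genome
#'
#' The background demography is a two-deme isolation-with-migration model
#' whose defaults are the demographic history inferred for the hybridizing
#' rabbit subspecies the package's worked examples target: N1 = 1.6e6,
#' N2 = 7.8e5, N_anc = 4.7e5 diploids, a split 1.8e6 generations ago,
#' migration 2Nm of 1.69 and 0.83, and mu = 1.25e-9 (4*N1*mu = 0.008 per
#' site, the system's intronic diversity scale). Under such porous-isolation
#' histories neutral gene flow makes fixed differences vanishingly rare, so
#' planted islands are modeled as loci *resisting introgression under
#' selection*: zero migration plus locally reduced effective sizes
#' (`ne_scale`, a sweep-mimic for recurrent selection), which yields
#' complete lineage sorting and fixed differences inside islands while the
#' background stays lowly differentiated.
#'
#' Fragments of `fragment_length` bp are laid on a regular grid
#' (`fragment_spacing` apart, mirroring sparse targeted-capture designs)
#' and genes on a second grid for annotation tests. The outgroup is a
#' single chromosome from a lineage isolated since `outgroup_split`
#' generations (default 1.2e7, a deep outgroup divergence giving
#' background relative node depth near 0.2).
#'
#' @param n_chromosomes,chromosome_length Genome layout (bp).
#' @param fragment_length,fragment_spacing Target-fragment grid (bp).
#' @param n_dip1,n_dip2 Diploid individuals per population.
#' @param model Background `im_model`.
#' @param islands Data.frame `chrom`, `start`, `end`, and optionally
#'   `M12`, `M21` (default 0: no gene flow inside the island) and
#'   `ne_scale` (default 0.05: local effective sizes multiplied by this
#'   inside the island). Use [place_islands()] for a standard layout, or
#'   `NULL` for a fully neutral genome.
#' @param outgroup_split Outgroup divergence in generations.
#' @param gene_spacing,gene_length Gene grid (bp).
#' @param x_chromosome Flag the last chromosome as the X (metadata only;
#'   the simulation itself is not rescaled).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_chromosomes = 3, chromosome_length = 12e6,
                         fragment_length = 1200, fragment_spacing = 268000,
                         n_dip1 = 6, n_dip2 = 6,
                         model = im_model(N1 = 1.6e6, N2 = 7.8e5,
                                          N_anc = 4.7e5, T_split = 1.8e6,
                                          M12 = 1.69, M21 = 0.83,
                                          mu = 1.25e-9),
                         islands = NULL,
                         outgroup_split = 1.2e7,
                         gene_spacing = 4e5, gene_length = 2e4,
                         x_chromosome = FALSE) {
  stopifnot(inherits(model, "im_model"), n_chromosomes >= 1,
            chromosome_length > fragment_spacing,
            2 * (n_dip1 + n_dip2) + 1 <= 64,
            outgroup_split > model$T_split)
  cfg <- structure(list(n_chromosomes = n_chromosomes,
                        chromosome_length = chromosome_length,
                        fragment_length = fragment_length,
                        fragment_spacing = fragment_spacing,
                        n_dip1 = n_dip1, n_dip2 = n_dip2, model = model,
                        islands = islands,
                        outgroup_split = outgroup_split,
                        gene_spacing = gene_spacing,
                        gene_length = gene_length,
                        x_chromosome = x_chromosome),
                   class = "synth_config")
  if (!is.null(islands)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(islands)))
    if (is.null(islands$M12)) islands$M12 <- 0
    if (is.null(islands$M21)) islands$M21 <- 0
    if (is.null(islands$ne_scale)) islands$ne_scale <- 0.05
    if (any(islands$M12 > model$M12) || any(islands$M21 > model$M21))
      stop("island migration must not exceed the background rate")
    if (any(islands$ne_scale <= 0 | islands$ne_scale > 1))
      stop("island ne_scale must lie in (0, 1]")
    if (any(islands$start < 0 | islands$end > chromosome_length))
      stop("islands must lie within chromosome bounds")
    cfg$islands <- islands
  }
  cfg
}

#' Standard planted-island layout
#'
#' Places `n_islands` islands deterministically: island j sits on
#' chromosome `(j - 1) %% n_chromosomes + 1`, centred at fraction
#' `j / (n_islands + 1)` of the chromosome (snapped to the fragment grid)
#' and wide enough to contain `n_fragments` consecutive target fragments.
#'
#' @param config A `synth_config` (its `islands` slot is ignored).
#' @param n_islands Number of islands (default 3).
#' @param n_fragments Fragments covered per island (default 2).
#' @param near_centromere Place islands at the chromosome midpoint (the
#'   default centromere position) instead of spreading them out.
#' @return Data.frame suitable for the `islands` argument of
#'   [synth_config()].
#' @export
place_islands <- function(config, n_islands = 3, n_fragments = 2,
                          near_centromere = FALSE) {
  frags <- .fragment_grid(config)
  out <- lapply(seq_len(n_islands), function(j) {
    ch <- paste0("chr", (j - 1L) %% config$n_chromosomes + 1L)
    centre <- if (near_centromere) config$chromosome_length / 2 else
      config$chromosome_length * j / (n_islands + 1)
    f <- frags[frags$chrom == ch, , drop = FALSE]
    k <- which.min(abs((f$start + f$end) / 2 - centre))
    k2 <- min(k + n_fragments - 1L, nrow(f))
    data.frame(chrom = ch, start = max(0, f$start[k] - 1000),
               end = min(config$chromosome_length, f$end[k2] + 1000))
  })
  do.call(rbind, out)
}

.fragment_grid <- function(config) {
  out <- lapply(seq_len(config$n_chromosomes), function(i) {
    starts <- seq(config$fragment_spacing %/% 2,
                  config$chromosome_length - config$fragment_length,
                  by = config$fragment_spacing)
    data.frame(chrom = paste0("chr", i), start = as.integer(starts),
               end = as.integer(starts + config$fragment_length),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$id <- paste0("frag_", seq_len(nrow(out)))
  out
}

.gene_grid <- function(config) {
  out <- lapply(seq_len(config$n_chromosomes), function(i) {
    starts <- seq(config$gene_spacing %/% 2,
                  config$chromosome_length - config$gene_length,
                  by = config$gene_spacing)
    data.frame(chrom = paste0("chr", i), start = as.integer(starts),
               end = as.integer(starts + config$gene_length),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$id <- paste0("gene_", seq_len(nrow(out)))
  out$biotype <- "protein_coding"
  out
}

#' Generate a synthetic genome
#'
#' Simulates every target fragment under the configured model (island
#' fragments under their island's migration rates), pairs haplotypes into
#' diploid genotypes, haploidizes the outgroup, and assembles a VCF plus
#' genome metadata. With `dir` set, writes `genome.vcf`, `popmap.tsv`,
#' `chroms.tsv`, `centromeres.tsv`, `genes.bed` (and `genes.gff3` when
#' \pkg{rtracklayer} is available), `fragments.bed` and `truth.bed` (the
#' planted islands).
#'
#' The reference allele is the ancestral state (`A`), the alternate the
#' derived state (`G`); centromeres sit at the chromosome midpoint.
#'
#' @param config A `synth_config`.
#' @param dir Output directory (created if needed), or `NULL` for an
#'   in-memory genome only.
#' @param seed Integer seed; output is fully reproducible.
#' @return A `synth_genome` list: `config`, `vcf` (vcfR object), `popmap`,
#'   `genome_meta`, `truth` (planted islands), `paths` (when written).
#' @export
generate_genome <- function(config, dir = NULL, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  frags <- .fragment_grid(config)
  islands <- config$islands
  mod <- config$model
  n1 <- 2L * config$n_dip1
  n2 <- 2L * config$n_dip2
  nh <- n1 + n2 + 1L

  if (!is.null(islands)) {
    gi <- GenomicRanges::GRanges(islands$chrom,
                                 IRanges::IRanges(islands$start + 1L,
                                                  islands$end))
    gf <- GenomicRanges::GRanges(frags$chrom,
                                 IRanges::IRanges(frags$start + 1L,
                                                  frags$end))
    hit1 <- suppressWarnings(GenomicRanges::findOverlaps(gi, gf))
    covered <- unique(S4Vectors::queryHits(hit1))
    if (length(covered) < nrow(islands))
      warning("island(s) overlap no target fragment and are undetectable")
    frag_island <- rep(NA_integer_, nrow(frags))
    frag_island[S4Vectors::subjectHits(hit1)] <- S4Vectors::queryHits(hit1)
  } else {
    frag_island <- rep(NA_integer_, nrow(frags))
  }

  recs <- vector("list", nrow(frags))
  for (k in seq_len(nrow(frags))) {
    isl <- frag_island[k]
    M12 <- if (is.na(isl)) mod$M12 else islands$M12[isl]
    M21 <- if (is.na(isl)) mod$M21 else islands$M21[isl]
    nsc <- if (is.na(isl)) 1 else islands$ne_scale[isl]
    sim <- .cpp_sim_locus(n1, n2, 1L, mod$N1 * nsc, mod$N2 * nsc,
                          mod$N_anc, mod$T_split, config$outgroup_split,
                          M12 / (2 * mod$N1 * nsc),
                          M21 / (2 * mod$N2 * nsc),
                          mod$mu, config$fragment_length)
    geno <- sim$genotypes
    if (nrow(geno) == 0L) next
    pos <- frags$start[k] + as.integer(floor(sim$positions *
                                               config$fragment_length)) + 1L
    keep <- !duplicated(pos)  # infinite-sites collisions after discretizing
    ord <- order(pos[keep])
    geno <- geno[keep, , drop = FALSE][ord, , drop = FALSE]
    recs[[k]] <- list(chrom = frags$chrom[k], pos = sort(pos[keep]),
                      geno = geno)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  chrom <- unlist(lapply(recs, function(r) rep(r$chrom, length(r$pos))))
  pos <- unlist(lapply(recs, function(r) r$pos))
  geno <- do.call(rbind, lapply(recs, function(r) r$geno))

  # haplotypes -> diploid genotype strings; outgroup stays haploid
  dip <- function(a, b) paste0(geno[, a], "/", geno[, b])
  gt_cols <- c(lapply(seq_len(config$n_dip1), function(i)
                 dip(2L * i - 1L, 2L * i)),
               lapply(seq_len(config$n_dip2), function(i)
                 dip(n1 + 2L * i - 1L, n1 + 2L * i)),
               list(as.character(geno[, nh])))
  gt <- do.call(cbind, gt_cols)
  samples <- c(paste0("p1_", seq_len(config$n_dip1)),
               paste0("p2_", seq_len(config$n_dip2)), "outgroup")
  colnames(gt) <- samples
  gt <- cbind(FORMAT = rep("GT", nrow(gt)), gt)

  n <- length(pos)
  fix <- cbind(CHROM = chrom, POS = as.character(pos), ID = rep(".", n),
               REF = rep("A", n), ALT = rep("G", n), QUAL = rep(".", n),
               FILTER = rep(".", n), INFO = rep(".", n))
  vcf <- .new_vcfR(
             meta = c("##fileformat=VCFv4.2", "##source=diffscan-synth",
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             fix = fix, gt = gt)

  popmap <- data.frame(
    sample = samples,
    population = c(rep("pop1", config$n_dip1), rep("pop2", config$n_dip2),
                   "outgroup"),
    stringsAsFactors = FALSE)
  chroms <- data.frame(chrom = paste0("chr", seq_len(config$n_chromosomes)),
                       length = config$chromosome_length,
                       stringsAsFactors = FALSE)
  chroms$is_x <- FALSE
  if (config$x_chromosome) chroms$is_x[nrow(chroms)] <- TRUE
  centromeres <- data.frame(chrom = chroms$chrom,
                            position = config$chromosome_length %/% 2)
  meta <- read_genome_meta(chroms, centromeres, genes = .gene_grid(config),
                           fragments = frags)
  truth <- if (is.null(islands))
    data.frame(chrom = character(), start = integer(), end = integer())
  else islands[, c("chrom", "start", "end")]

  out <- structure(list(config = config, seed = seed, vcf = vcf,
                        popmap = popmap, genome_meta = meta, truth = truth),
                   class = "synth_genome")
  if (!is.null(dir)) out$paths <- .write_genome(out, dir)
  out
}

.write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "genome.vcf"),
    popmap = file.path(dir, "popmap.tsv"),
    chroms = file.path(dir, "chroms.tsv"),
    centromeres = file.path(dir, "centromeres.tsv"),
    genes = file.path(dir, "genes.bed"),
    fragments = file.path(dir, "fragments.bed"),
    truth = file.path(dir, "truth.bed"))
  .write_vcf_plain(genome$vcf, paths$vcf)
  write.table(genome$popmap, paths$popmap, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- genome$genome_meta
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  write.table(data.frame(meta$chroms$chrom, fmt(meta$chroms$length)),
              paths$chroms, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(data.frame(meta$chroms$chrom, fmt(meta$chroms$centromere)),
              paths$centromeres, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_bed(meta$genes, paths$genes)
  write_bed(meta$fragments, paths$fragments)
  write_bed(genome$truth, paths$truth)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- GenomicRanges::GRanges(
      meta$genes$chrom,
      IRanges::IRanges(meta$genes$start + 1L, meta$genes$end),
      type = "gene", ID = meta$genes$id, biotype = meta$genes$biotype)
    paths$genes_gff3 <- file.path(dir, "genes.gff3")
    rtracklayer::export(gr, paths$genes_gff3, format = "gff3")
  }
  paths
}

#' Downsample a synthetic genome to a fraction of its fragments
#'
#' Retains a random subset of target fragments (deterministic under
#' `seed`) together with the SNPs falling in them.
#'
#' @param genome A `synth_genome`.
#' @param fraction Fraction of fragments to keep, in (0, 1].
#' @param seed Integer seed.
#' @param dir Optional output directory for the reduced genome.
#' @return A `synth_genome` with the reduced fragment set.
#' @export
downsample_genome <- function(genome, fraction, seed = 1, dir = NULL) {
  stopifnot(inherits(genome, "synth_genome"), fraction > 0, fraction <= 1)
  frags <- genome$genome_meta$fragments
  if (fraction == 1) {
    out <- genome
  } else {
    set.seed(seed)
    keep <- sort(sample.int(nrow(frags), round(fraction * nrow(frags))))
    kept <- frags[keep, , drop = FALSE]
    fix <- genome$vcf@fix
    pos <- as.integer(fix[, "POS"])
    in_kept <- rep(FALSE, nrow(fix))
    for (k in seq_len(nrow(kept)))
      in_kept <- in_kept | (fix[, "CHROM"] == kept$chrom[k] &
                              pos - 1L >= kept$start[k] &
                              pos - 1L < kept$end[k])
    vcf <- genome$vcf
    vcf@fix <- fix[in_kept, , drop = FALSE]
    vcf@gt <- genome$vcf@gt[in_kept, , drop = FALSE]
    out <- genome
    out$vcf <- vcf
    out$genome_meta$fragments <- kept
  }
  if (!is.null(dir)) out$paths <- .write_genome(out, dir)
  out
}

#' @export
print.synth_genome <- function(x, ...) {
  cat("synth_genome:", nrow(x$vcf@fix), "SNPs,",
      nrow(x$genome_meta$fragments), "fragments,",
      x$config$n_chromosomes, "chromosomes,",
      nrow(x$truth), "planted island(s)\n")
  invisible(x)
}
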