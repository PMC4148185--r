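# Genome metadata: chromosome sizes, centromere positions, gene intervals
# and target-fragment definitions. All intervals are handled 0-based
# half-open internally; BED input is taken as-is, GFF3 start is shifted by
# one on import, and BED output is written 0-based half-open.

#' Assemble genome metadata
#'
#' @param chrom_sizes Path to a tab-separated table `chrom<TAB>length`
#'   (no header), or an equivalent data.frame. Chromosomes named `X` or
#'   `chrX` are flagged as the sex chromosome.
#' @param centromeres Optional path/data.frame `chrom<TAB>position` giving
#'   one centromere position (bp) per chromosome.
#' @param genes Optional gene annotation: a GFF3 file (requires
#'   \pkg{rtracklayer}), a BED file (`chrom start end name [score strand]`,
#'   0-based half-open), or a data.frame with columns `chrom`, `start`,
#'   `end` and optionally `id`, `biotype`.
#' @param fragments Optional target-fragment definitions, BED or data.frame
#'   (`chrom`, `start`, `end`, `id`, optional `outgroup_span` in bp).
#' @return A `genome_meta` list with elements `chroms` (data.frame `chrom`,
#'   `length`, `is_x`, `centromere`), `genes` and `fragments`.
#' @export
read_genome_meta <- function(chrom_sizes, centromeres = NULL, genes = NULL,
                             fragments = NULL) {
  chroms <- if (is.data.frame(chrom_sizes)) chrom_sizes else
    read.delim(chrom_sizes, header = FALSE,
               col.names = c("chrom", "length"),
               colClasses = c("character", "numeric"))
  names(chroms)[1:2] <- c("chrom", "length")
  chroms$chrom <- as.character(chroms$chrom)
  if (is.null(chroms$is_x))
    chroms$is_x <- chroms$chrom %in% c("X", "chrX")
  chroms$centromere <- NA_real_
  if (!is.null(centromeres)) {
    cen <- if (is.data.frame(centromeres)) centromeres else
      read.delim(centromeres, header = FALSE,
                 col.names = c("chrom", "position"))
    m <- match(chroms$chrom, as.character(cen[[1L]]))
    chroms$centromere <- as.numeric(cen[[2L]])[m]
  }
  g <- .read_intervals(genes, chroms, kind = "gene")
  f <- .read_intervals(fragments, chroms, kind = "fragment")
  if (!is.null(f) && is.null(f$outgroup_span))
    f$outgroup_span <- f$end - f$start
  structure(list(chroms = chroms, genes = g, fragments = f),
            class = "genome_meta")
}

.read_intervals <- function(x, chroms, kind) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    if (grepl("\\.gff3?(\\.gz)?$", x)) {
      if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("reading GFF3 requires the rtracklayer package")
      gr <- rtracklayer::import(x)
      gr <- gr[as.character(gr$type) %in% c("gene", "pseudogene")]
      x <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      id = if (!is.null(gr$ID)) as.character(gr$ID) else
                        paste0(kind, "_", seq_along(gr)),
                      biotype = if (!is.null(gr$biotype))
                        as.character(gr$biotype) else NA_character_,
                      stringsAsFactors = FALSE)
    } else {
      bed <- read.delim(x, header = FALSE, comment.char = "#")
      x <- data.frame(chrom = as.character(bed[[1L]]),
                      start = as.integer(bed[[2L]]),
                      end = as.integer(bed[[3L]]),
                      id = if (ncol(bed) >= 4L) as.character(bed[[4L]]) else
                        paste0(kind, "_", seq_len(nrow(bed))),
                      stringsAsFactors = FALSE)
    }
  }
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (is.null(x$id)) x$id <- paste0(kind, "_", seq_len(nrow(x)))
  bad <- which(!(x$chrom %in% chroms$chrom) |
                 x$start < 0 |
                 x$end > chroms$length[match(x$chrom, chroms$chrom)] |
                 x$start >= x$end)
  if (length(bad))
    stop("malformed ", kind, " annotation at line ", bad[1L],
         ": interval outside chromosome bounds")
  x[order(x$chrom, x$start), , drop = FALSE]
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df Data.frame with `chrom`, `start`, `end` and optionally a name
#'   column (`id` or `criterion`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  if (nrow(df) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if (!is.null(df$id)) df$id else
    if (!is.null(df$criterion)) as.character(df$criterion) else
      rep(".", nrow(df))
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE), name)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.genome_meta <- function(x, ...) {
  cat("genome_meta:", nrow(x$chroms), "chromosomes,",
      sum(as.numeric(x$chroms$length)) / 1e6, "Mb total\n")
  if (!is.null(x$genes)) cat("  genes:", nrow(x$genes), "\n")
  if (!is.null(x$fragments)) cat("  fragments:", nrow(x$fragments), "\n")
  invisible(x)
}
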