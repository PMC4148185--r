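# Sliding-window differentiation scan, island demarcation, and the
# genome-wide permutation test of clustering.

#' Build sliding windows over the genome
#'
#' Windows start at 0, advance by `step`, and are kept only if fully
#' contained in the chromosome. Chromosomes shorter than `size` get no
#' windows (with a warning).
#'
#' @param genome_meta A `genome_meta`.
#' @param size,step Window size and step in bp (defaults 100 kb / 10 kb).
#' @return Data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
make_windows <- function(genome_meta, size = 100000, step = 10000) {
  stopifnot(size > 0, step > 0)
  if (step > size)
    warning("step larger than window size: windows will not tile the genome")
  chroms <- genome_meta$chroms
  out <- lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    if (len < size) {
      warning("chromosome ", chroms$chrom[i], " (", len,
              " bp) is shorter than the window size; no windows emitted")
      return(NULL)
    }
    starts <- seq(0L, len - size, by = step)
    data.frame(chrom = chroms$chrom[i], start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(), start = integer(),
                                      end = integer())
  rownames(out) <- NULL
  out
}

# windows x SNPs membership as an index list; a SNP at pos (1-based) lies in
# window [start, end) iff start <= pos-1 < end
.window_members <- function(table, windows) {
  gr_w <- GenomicRanges::GRanges(windows$chrom,
                                 IRanges::IRanges(windows$start + 1L,
                                                  windows$end))
  gr_s <- GenomicRanges::GRanges(table$chrom,
                                 IRanges::IRanges(table$pos, table$pos))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_w, gr_s))
  split(S4Vectors::subjectHits(hits),
        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(windows))))
}

#' Windowed differentiation statistics
#'
#' For every window: the number of SNPs, the *mean* of per-SNP F_ST values
#' (NA values skipped), and counts of fixed differences and shared
#' polymorphisms among its classified SNPs. Windows holding fewer than
#' `min_snps` SNPs are flagged undefined and never reach significance.
#'
#' @param table A `site_table` with `fst` and `class` columns (see
#'   [site_stats()]); normally the MAF-filtered table.
#' @param windows Window frame from [make_windows()].
#' @param min_snps Minimum SNPs per window (default 5).
#' @param class_table Optional second `site_table` (already classified)
#'   from which the fixed/shared counts are taken instead, e.g. the
#'   unfiltered table.
#' @return A `window_track` data.frame: windows plus `n_snps`, `mean_fst`,
#'   `n_fixed`, `n_shared`, `defined`.
#' @export
window_scan <- function(table, windows, min_snps = 5, class_table = NULL) {
  if (is.null(table$fst) || is.null(table$class))
    stop("run site_stats() on the table first")
  members <- .window_members(table, windows)
  n_snps <- lengths(members)
  mean_fst <- vapply(members, function(i) {
    v <- table$fst[i]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))

  cls_tab <- if (is.null(class_table)) table else class_table
  cls_members <- if (is.null(class_table)) members else
    .window_members(cls_tab, windows)
  n_fixed <- vapply(cls_members, function(i)
    sum(cls_tab$class[i] == "fixed", na.rm = TRUE), numeric(1))
  n_shared <- vapply(cls_members, function(i)
    sum(cls_tab$class[i] == "shared", na.rm = TRUE), numeric(1))

  out <- windows
  out$n_snps <- n_snps
  out$mean_fst <- mean_fst
  out$n_fixed <- n_fixed
  out$n_shared <- n_shared
  out$defined <- n_snps >= min_snps & !is.na(mean_fst)
  class(out) <- c("window_track", "data.frame")
  attr(out, "min_snps") <- min_snps
  out
}

#' Window Z-scores of mean F_ST
#'
#' `z = (mean_fst - center) / sd`, where the center (median by default,
#' mean as an option) and the plain standard deviation are taken over all
#' defined windows genome-wide.
#'
#' @param track A `window_track`.
#' @param center `"median"` (default) or `"mean"`.
#' @return The track with a `z_score` column (NA for undefined windows).
#' @export
z_scores <- function(track, center = c("median", "mean")) {
  center <- match.arg(center)
  v <- track$mean_fst[track$defined]
  if (length(v) < 2) stop("need at least two defined windows")
  mid <- if (center == "median") median(v) else mean(v)
  s <- sd(v)
  if (s == 0) {
    warning("zero variance across windows; all Z-scores set to 0")
    track$z_score <- ifelse(track$defined, 0, NA_real_)
  } else {
    track$z_score <- ifelse(track$defined, (track$mean_fst - mid) / s,
                            NA_real_)
  }
  track
}

#' Fisher exact test of a window's fixed:shared ratio
#'
#' Compares the fixed-difference / shared-polymorphism composition of one
#' window against the genome-wide totals (which include the focal window
#' by default, matching a comparison against the genome-wide expectation).
#'
#' @param n_fixed,n_shared Window counts.
#' @param genome_fixed,genome_shared Genome-wide totals (these include the
#'   focal window; the 2x2 table contrasts the window against the rest of
#'   the genome, `genome - window`).
#' @param alternative `"two.sided"` (default) or `"greater"` for an
#'   enrichment-only test.
#' @return P-value, or `NA` when the window has no classified sites.
#' @export
fisher_fixed_shared <- function(n_fixed, n_shared, genome_fixed,
                                genome_shared,
                                alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (genome_fixed < n_fixed || genome_shared < n_shared)
    stop("genome totals smaller than window counts")
  if (n_fixed + n_shared == 0) return(NA_real_)
  m <- matrix(c(n_fixed, n_shared,
                genome_fixed - n_fixed, genome_shared - n_shared), nrow = 2)
  fisher.test(m, alternative = alternative)$p.value
}

#' Attach Fisher p-values to a window track
#'
#' @param track A `window_track`.
#' @param genome_totals `c(fixed, shared)` genome-wide counts, normally
#'   taken from the site table the track was built on (overlapping windows
#'   count SNPs repeatedly, so window sums must not be used).
#' @inheritParams fisher_fixed_shared
#' @return The track with a `fisher_p` column.
#' @export
fisher_scan <- function(track, genome_totals,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  # p depends only on (n_fixed, n_shared); windows repeat count pairs
  # heavily, so test each distinct pair once
  key <- paste(track$n_fixed, track$n_shared)
  uniq <- !duplicated(key)
  p_uniq <- vapply(which(uniq), function(i)
    fisher_fixed_shared(track$n_fixed[i], track$n_shared[i],
                        genome_totals[1L], genome_totals[2L],
                        alternative = alternative), numeric(1))
  p <- p_uniq[match(key, key[uniq])]
  track$fisher_p <- ifelse(track$defined, p, NA_real_)
  track
}

#' Demarcate islands of differentiation
#'
#' Selects significant windows (`z_score >= z_threshold` or
#' `fisher_p < p_threshold`, depending on `criterion`) and merges
#' significant windows on the same chromosome whenever the gap between
#' their spans is smaller than `merge_gap` (overlapping or abutting
#' windows always merge). The island span runs from the first window
#' start to the last window end.
#'
#' @param track A `window_track` with the relevant statistic attached.
#' @param criterion `"zscore"` or `"fisher"`.
#' @param z_threshold Z cutoff (default 3).
#' @param p_threshold Fisher p cutoff (default 0.01).
#' @param merge_gap Merge distance in bp (default 50 kb).
#' @return An `island_set` data.frame: `chrom`, `start`, `end`,
#'   `criterion`, `n_windows`, `size_bp`.
#' @export
call_islands <- function(track, criterion = c("zscore", "fisher"),
                         z_threshold = 3, p_threshold = 0.01,
                         merge_gap = 50000) {
  criterion <- match.arg(criterion)
  sig <- if (criterion == "zscore") {
    !is.na(track$z_score) & track$z_score >= z_threshold
  } else {
    !is.na(track$fisher_p) & track$fisher_p < p_threshold
  }
  sig <- sig & track$defined
  w <- track[sig, , drop = FALSE]
  out <- .merge_intervals(w, merge_gap)
  out$criterion <- rep(criterion, nrow(out))
  out <- out[, c("chrom", "start", "end", "criterion", "n_windows")]
  out$size_bp <- out$end - out$start
  class(out) <- c("island_set", "data.frame")
  out
}

.merge_intervals <- function(w, merge_gap) {
  if (nrow(w) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer()))
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  res <- list()
  cur <- list(chrom = w$chrom[1L], start = w$start[1L], end = w$end[1L],
              n_windows = 1L)
  for (i in seq_len(nrow(w))[-1L]) {
    gap <- w$start[i] - cur$end
    if (w$chrom[i] == cur$chrom && gap < merge_gap) {
      cur$end <- max(cur$end, w$end[i])
      cur$n_windows <- cur$n_windows + 1L
    } else {
      res[[length(res) + 1L]] <- cur
      cur <- list(chrom = w$chrom[i], start = w$start[i], end = w$end[i],
                  n_windows = 1L)
    }
  }
  res[[length(res) + 1L]] <- cur
  do.call(rbind, lapply(res, as.data.frame))
}

#' Intersect island sets from two criteria
#'
#' Retains regions supported by both criteria: any Z-score island and
#' Fisher island overlapping by at least 1 bp contribute an island whose
#' span is the union of the overlapping pair (chains of overlaps are
#' collapsed into one region).
#'
#' @param set_z,set_fisher Two `island_set`s over the same genome.
#' @return An `island_set` with `criterion = "both"`.
#' @export
intersect_islands <- function(set_z, set_fisher) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), criterion = character(),
                      n_windows = integer(), size_bp = integer())
  class(empty) <- c("island_set", "data.frame")
  if (nrow(set_z) == 0 || nrow(set_fisher) == 0) return(empty)
  gz <- GenomicRanges::GRanges(set_z$chrom,
                               IRanges::IRanges(set_z$start + 1L, set_z$end))
  gf <- GenomicRanges::GRanges(set_fisher$chrom,
                               IRanges::IRanges(set_fisher$start + 1L,
                                                set_fisher$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gz, gf))
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  pairs <- data.frame(
    chrom = set_z$chrom[qi],
    start = pmin(set_z$start[qi], set_fisher$start[si]),
    end = pmax(set_z$end[qi], set_fisher$end[si]),
    n_windows = set_z$n_windows[qi] + set_fisher$n_windows[si])
  out <- .merge_intervals(pairs, merge_gap = 0L)
  out$criterion <- "both"
  out <- out[, c("chrom", "start", "end", "criterion", "n_windows")]
  out$size_bp <- out$end - out$start
  class(out) <- c("island_set", "data.frame")
  out
}

#' Permutation test of genomic clustering of differentiation
#'
#' Shuffles the per-SNP (F_ST, class) tuples across SNP positions
#' genome-wide, recomputes the window track each time, and compares a
#' clustering statistic — by default the number of windows with
#' `z >= z_threshold` — against its permutation distribution. The p-value
#' uses the add-one estimator `(1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param table A `site_table` with `fst` and `class` columns.
#' @param windows Window frame from [make_windows()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the test is fully reproducible.
#' @param statistic `"n_windows_z"` (count of high-Z windows) or
#'   `"max_mean_fst"`.
#' @param z_threshold Z cutoff for the default statistic.
#' @param min_snps Passed to the internal window aggregation.
#' @param center Z centering, as in [z_scores()].
#' @return List with `p_value`, `observed`, the permuted statistics
#'   `perm`, and the call parameters.
#' @export
permutation_clustering_test <- function(table, windows, n_perm = 1000,
                                        seed = 1,
                                        statistic = c("n_windows_z",
                                                      "max_mean_fst"),
                                        z_threshold = 3, min_snps = 5,
                                        center = "median") {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (is.null(table$fst)) stop("run site_stats() on the table first")
  members <- .window_members(table, windows)
  n_snps <- lengths(members)
  defined <- n_snps >= min_snps
  midx <- unlist(members, use.names = FALSE)
  grp <- rep.int(seq_along(members), n_snps)
  present <- unique(grp)
  def_present <- defined[present]

  stat_fun <- function(fst) {
    v <- fst[midx]
    na <- is.na(v)
    s <- rowsum(ifelse(na, 0, v), grp)[, 1L]
    cnt <- rowsum(as.numeric(!na), grp)[, 1L]
    means <- ifelse(cnt > 0, s / cnt, NA_real_)
    v <- means[def_present & cnt > 0]
    if (statistic == "max_mean_fst") return(if (length(v)) max(v) else 0)
    if (length(v) < 2) return(0)
    mid <- if (center == "median") median(v) else mean(v)
    s <- sd(v)
    if (s == 0) return(0)
    sum((v - mid) / s >= z_threshold)
  }

  observed <- stat_fun(table$fst)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    stat_fun(sample(table$fst)), numeric(1))
  p <- (1 + sum(perm >= observed)) / (1 + n_perm)
  list(p_value = p, observed = observed, perm = perm, n_perm = n_perm,
       statistic = statistic, seed = seed)
}

#' @export
print.island_set <- function(x, ...) {
  cat("island_set:", nrow(x), "islands",
      if (nrow(x)) paste0("(", sum(x$size_bp) / 1e6, " Mb total, criterion ",
                          paste(unique(x$criterion), collapse = "/"), ")"),
      "\n")
  invisible(x)
}
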