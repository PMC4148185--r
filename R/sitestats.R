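# Per-SNP and per-fragment population-genetic statistics.

#' Weir-Cockerham F_ST for one or more bi-allelic SNPs
#'
#' Variance-components estimator for two populations, computed from allele
#' counts (chromosomes treated as the sampling unit). Vectorized over sites.
#' The estimator may be negative; it is `NA` when both populations are
#' monomorphic for the same set of frequencies such that the denominator
#' vanishes, or when fewer than two chromosomes were called in either
#' population.
#'
#' @param ac1,an1 Alternate (or derived) allele count and called chromosomes
#'   in population 1.
#' @param ac2,an2 Same for population 2.
#' @return Numeric vector of per-site F_ST estimates in `[-1, 1]`, `NA`
#'   where undefined.
#' @export
wc_fst <- function(ac1, an1, ac2, an2) {
  ok <- an1 >= 2 & an2 >= 2
  p1 <- ifelse(ok, ac1 / an1, NA_real_)
  p2 <- ifelse(ok, ac2 / an2, NA_real_)
  ntot <- an1 + an2
  # one-way ANOVA on allele indicators: among- and within-population mean
  # squares, with n_c the effective sample size correction
  pbar <- (ac1 + ac2) / ntot
  msp <- an1 * (p1 - pbar)^2 + an2 * (p2 - pbar)^2            # r - 1 = 1 df
  msg <- (an1 * p1 * (1 - p1) + an2 * p2 * (1 - p2)) / (ntot - 2)
  nc <- ntot - (an1^2 + an2^2) / ntot
  denom <- msp + (nc - 1) * msg
  out <- ifelse(ok & denom > 0, (msp - msg) / denom, NA_real_)
  out
}

#' Classify sites as fixed, shared, exclusive or monomorphic
#'
#' Joint classification of each bi-allelic SNP from its two ingroup allele
#' counts: `fixed` — alternate alleles at frequency 1 vs 0; `shared` —
#' segregating within both populations; `exclusive_p1`/`exclusive_p2` —
#' segregating in exactly one; `monomorphic` — the same allele fixed in
#' both. Sites with zero called chromosomes in either population are
#' unclassifiable (`NA`).
#'
#' @param table A `site_table`, or a data.frame with columns `ac1`, `an1`,
#'   `ac2`, `an2`.
#' @return Factor with levels `fixed`, `shared`, `exclusive_p1`,
#'   `exclusive_p2`, `monomorphic`.
#' @export
classify_sites <- function(table) {
  f1 <- ifelse(table$an1 > 0, table$ac1 / table$an1, NA_real_)
  f2 <- ifelse(table$an2 > 0, table$ac2 / table$an2, NA_real_)
  poly1 <- f1 > 0 & f1 < 1
  poly2 <- f2 > 0 & f2 < 1
  lab <- ifelse(is.na(f1) | is.na(f2), NA_character_,
         ifelse(poly1 & poly2, "shared",
         ifelse(poly1, "exclusive_p1",
         ifelse(poly2, "exclusive_p2",
         ifelse(abs(f1 - f2) == 1, "fixed", "monomorphic")))))
  factor(lab, levels = c("fixed", "shared", "exclusive_p1", "exclusive_p2",
                         "monomorphic"))
}

#' Attach per-SNP F_ST and class labels to a site table
#'
#' @param table A `site_table`.
#' @return The table with columns `fst` and `class` added.
#' @export
site_stats <- function(table) {
  stopifnot(inherits(table, "site_table"))
  table$fst <- wc_fst(table$ac1, table$an1, table$ac2, table$an2)
  table$class <- classify_sites(table)
  table
}

#' Site-frequency spectrum of a fragment
#'
#' Tallies derived-allele (unfolded) or minor-allele (folded) counts for
#' the SNPs of one population falling inside a fragment interval. The
#' unfolded spectrum uses only sites with a known ancestral state; by
#' default sites whose called sample size differs from `n` are projected
#' down by hypergeometric sampling, or dropped with `project = FALSE`.
#'
#' @param table A `site_table` (polarized, for the unfolded form).
#' @param fragment List or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param population 1 or 2.
#' @param n Number of chromosomes the spectrum refers to (defaults to the
#'   population's maximum called count within the fragment).
#' @param folded Return the minor-allele spectrum instead.
#' @param project Project sites called at more than `n` chromosomes down to
#'   `n` (expected hypergeometric counts); otherwise drop them.
#' @return Numeric vector `xi` of length `n - 1` (unfolded) or `floor(n/2)`
#'   (folded); entry i is the number of sites at allele count i.
#' @export
fragment_sfs <- function(table, fragment, population = 1, n = NULL,
                         folded = FALSE, project = TRUE) {
  stopifnot(population %in% 1:2)
  idx <- table$chrom == fragment$chrom &
    table$pos - 1L >= fragment$start & table$pos - 1L < fragment$end
  sub <- table[idx, , drop = FALSE]
  dc_col <- paste0("dc", population); an_col <- paste0("an", population)
  if (!folded) {
    if (is.null(sub[[dc_col]]))
      stop("unfolded spectrum requires a polarized table (run polarize())")
    keep <- sub$ancestral_known %in% TRUE
    if (nrow(sub) > 0 && !any(keep))
      warning("no polarizable sites in fragment; returning a zero spectrum")
    sub <- sub[keep, , drop = FALSE]
    counts <- sub[[dc_col]]
  } else {
    counts <- sub[[paste0("ac", population)]]
  }
  an <- sub[[an_col]]
  if (is.null(n)) n <- if (length(an)) max(an) else 0L
  if (n < 2) return(numeric(0))
  xi <- numeric(n - 1L)
  for (j in seq_along(counts)) {
    if (an[j] < 2) next
    if (an[j] == n) {
      d <- counts[j]
      if (d >= 1 && d <= n - 1) xi[d] <- xi[d] + 1
    } else if (project && an[j] > n) {
      # expected downsampled spectrum contribution
      d <- counts[j]
      for (i in seq_len(n - 1L))
        xi[i] <- xi[i] + exp(lchoose(d, i) + lchoose(an[j] - d, n - i) -
                               lchoose(an[j], n))
    } else if (project && an[j] < n) {
      next  # cannot project up
    }
  }
  if (folded) {
    eta <- numeric(floor(n / 2))
    for (i in seq_along(eta)) {
      eta[i] <- xi[i] + if (n - i != i && n - i <= n - 1) xi[n - i] else 0
    }
    return(eta)
  }
  xi
}

# a1 = sum 1/k, a2 = sum 1/k^2 over k = 1..n-1 (Tajima's notation)
.harmonic <- function(n) sum(1 / seq_len(n - 1L))
.harmonic2 <- function(n) sum(1 / seq_len(n - 1L)^2)

#' Diversity estimators and Tajima's D from a frequency spectrum
#'
#' @param sfs Unfolded (or folded) spectrum, entry i = number of sites at
#'   allele count i.
#' @param n Sample size in chromosomes.
#' @param L Surveyed length in bp (monomorphic sites included).
#' @return List with per-site `pi`, `theta_w`, the number of segregating
#'   sites `S`, and `tajima_d` (`NA` when `S = 0`).
#' @export
diversity_stats <- function(sfs, n, L) {
  stopifnot(n >= 2, L > 0)
  S <- sum(sfs)
  i <- seq_along(sfs)
  pi_total <- sum(2 * i * (n - i) * sfs) / (n * (n - 1))
  a1 <- .harmonic(n)
  theta_w_total <- S / a1
  tajima_d <- NA_real_
  if (S > 0) {
    a2 <- .harmonic2(n)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    v <- e1 * S + e2 * S * (S - 1)
    if (v > 0) tajima_d <- (pi_total - theta_w_total) / sqrt(v)
  }
  list(pi = pi_total / L, theta_w = theta_w_total / L, S = S,
       tajima_d = tajima_d)
}

#' Fay and Wu's H from an unfolded frequency spectrum
#'
#' `H = pi - theta_H`, with `theta_H` weighted toward high-frequency
#' derived variants; strongly negative values indicate an excess of
#' high-frequency derived alleles, the footprint of hitchhiking (or of
#' introgression-resistant differentiation when computed within
#' populations flanking a hybrid zone).
#'
#' @inheritParams diversity_stats
#' @return Per-site H, or `NA` when the spectrum is empty.
#' @export
fay_wu_h <- function(sfs, n, L) {
  stopifnot(n >= 2, L > 0)
  if (sum(sfs) == 0) return(NA_real_)
  i <- seq_along(sfs)
  pi_total <- sum(2 * i * (n - i) * sfs) / (n * (n - 1))
  theta_h_total <- sum(2 * sfs * i^2) / (n * (n - 1))
  (pi_total - theta_h_total) / L
}

#' Between-population divergence per site (D_xy)
#'
#' Average pairwise difference per site between haplotype pools, computed
#' from allele frequencies: for each SNP the probability that one
#' chromosome drawn from each pool differs, summed and divided by the
#' surveyed length.
#'
#' @param p1,p2 Allele frequencies of the same allele in the two pools
#'   (vectors over SNPs).
#' @param L Surveyed length in bp.
#' @return Per-site D_xy.
#' @export
dxy <- function(p1, p2, L) {
  ok <- !is.na(p1) & !is.na(p2)
  sum(p1[ok] * (1 - p2[ok]) + p2[ok] * (1 - p1[ok])) / L
}

#' Per-fragment statistics including RND
#'
#' Computes, for every target fragment, within-population diversity
#' (`pi`, `theta_w`), frequency-spectrum statistics (Tajima's D, Fay &
#' Wu's H), the between-population divergence `dxy_in`, the divergence of
#' the pooled ingroup to the outgroup `dxy_out`, and the relative node
#' depth `rnd = dxy_in / dxy_out`. RND is `NA` for fragments whose aligned
#' outgroup span is below `min_outgroup_span` (divergence to the outgroup
#' cannot be estimated reliably from short alignments) or whose `dxy_out`
#' is zero.
#'
#' Run this on the missingness-filtered, polarized table *before* MAF
#' filtering: divergence and spectrum statistics need the rare variants
#' and the ingroup-monomorphic sites at which only the outgroup differs.
#'
#' @param table A polarized `site_table`.
#' @param genome_meta A `genome_meta` whose `fragments` element is set.
#' @param min_outgroup_span Minimum aligned outgroup span (bp) for RND;
#'   default 1000.
#' @return Data.frame with one row per fragment.
#' @export
fragment_stats <- function(table, genome_meta, min_outgroup_span = 1000) {
  frags <- genome_meta$fragments
  if (is.null(frags)) stop("genome_meta carries no fragment definitions")
  n1 <- max(table$an1, 2L); n2 <- max(table$an2, 2L)
  rows <- lapply(seq_len(nrow(frags)), function(k) {
    fr <- frags[k, ]
    L <- fr$end - fr$start
    idx <- table$chrom == fr$chrom &
      table$pos - 1L >= fr$start & table$pos - 1L < fr$end
    sub <- table[idx, , drop = FALSE]

    res <- list(fragment_id = fr$id, chrom = fr$chrom, start = fr$start,
                end = fr$end, n_sites = L, n_snps = nrow(sub))
    for (p in 1:2) {
      n <- if (p == 1) n1 else n2
      xi_f <- fragment_sfs(table, fr, population = p, n = n, folded = TRUE)
      d <- diversity_stats(xi_f, n, L)
      xi_u <- suppressWarnings(
        fragment_sfs(table, fr, population = p, n = n, folded = FALSE))
      h <- if (length(xi_u)) fay_wu_h(xi_u, n, L) else NA_real_
      res[[paste0("S_p", p)]] <- d$S
      res[[paste0("pi_p", p)]] <- d$pi
      res[[paste0("theta_w_p", p)]] <- d$theta_w
      res[[paste0("tajima_d_p", p)]] <- d$tajima_d
      res[[paste0("fay_wu_h_p", p)]] <- h
    }
    f1 <- ifelse(sub$an1 > 0, sub$ac1 / sub$an1, NA_real_)
    f2 <- ifelse(sub$an2 > 0, sub$ac2 / sub$an2, NA_real_)
    res$dxy_in <- dxy(f1, f2, L)
    has_og <- !is.na(sub$og)
    fp <- ifelse((sub$an1 + sub$an2) > 0,
                 (sub$ac1 + sub$ac2) / (sub$an1 + sub$an2), NA_real_)
    fo <- ifelse(sub$og == sub$alt, 1, 0)
    res$dxy_out <- dxy(fp[has_og], fo[has_og], L)
    og_span <- if (!is.null(fr$outgroup_span)) fr$outgroup_span else L
    res$rnd <- if (og_span >= min_outgroup_span && !is.na(res$dxy_out) &&
                     res$dxy_out > 0) res$dxy_in / res$dxy_out else NA_real_
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
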