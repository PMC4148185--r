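# R interface to the structured-coalescent engine: isolation-with-migration
# model objects, simulated datasets, the fixed:shared null distribution,
# and single-deme calibration utilities.

#' Specify a two-population isolation-with-migration model
#'
#' Two demes of diploid effective sizes `N1` and `N2` diverged `T_split`
#' generations ago from an ancestor of size `N_anc`, and have since
#' exchanged migrants. Migration is parameterized as population rates
#' `M12 = 2 * N1 * m12` and `M21 = 2 * N2 * m21` (the familiar 2Nm); the
#' per-lineage backward rates are derived internally. `mu` is the per-site
#' per-generation mutation rate.
#'
#' `im_model_rabbit()` returns the autosomal or X-chromosome model used by
#' the package's worked examples: N1 = 1.6e6, N2 = 7.8e5, N_anc = 4.7e5
#' diploids, a split 1.8e6 generations ago (one-year generations), and
#' 2Nm of 1.69/0.83 (autosomes) or 0.38/0.26 (X). In X mode all effective
#' sizes are multiplied by 3/4.
#'
#' @param N1,N2,N_anc Diploid effective sizes.
#' @param T_split Split time in generations.
#' @param M12,M21 Population migration rates (2Nm) into deme 1 and deme 2.
#' @param mu Mutation rate per site per generation. The default 1.25e-9
#'   gives 4*N1*mu = 0.008 per site for the rabbit-scale N1, matching
#'   intronic diversity in the system the package targets.
#' @param generation_time Generation time in years (bookkeeping only).
#' @return An `im_model` list.
#' @export
im_model <- function(N1, N2, N_anc, T_split, M12 = 0, M21 = 0,
                     mu = 1.25e-9, generation_time = 1) {
  stopifnot(N1 > 0, N2 > 0, N_anc > 0, T_split >= 0, M12 >= 0, M21 >= 0,
            mu > 0, generation_time > 0)
  structure(list(N1 = N1, N2 = N2, N_anc = N_anc, T_split = T_split,
                 M12 = M12, M21 = M21,
                 m12 = M12 / (2 * N1), m21 = M21 / (2 * N2),
                 mu = mu, generation_time = generation_time),
            class = "im_model")
}

#' @rdname im_model
#' @param chromosome `"autosome"` or `"X"`.
#' @export
im_model_rabbit <- function(chromosome = c("autosome", "X"),
                            mu = 1.25e-9) {
  chromosome <- match.arg(chromosome)
  scale <- if (chromosome == "X") 0.75 else 1
  M <- if (chromosome == "X") c(0.38, 0.26) else c(1.69, 0.83)
  im_model(N1 = 1.6e6 * scale, N2 = 7.8e5 * scale, N_anc = 4.7e5 * scale,
           T_split = 1.8e6, M12 = M[1L], M21 = M[2L], mu = mu)
}

#' @export
print.im_model <- function(x, ...) {
  cat("im_model: N1 =", x$N1, ", N2 =", x$N2, ", N_anc =", x$N_anc, "\n")
  cat("  split", x$T_split, "generations ago;  2N1m12 =", x$M12,
      ", 2N2m21 =", x$M21, "\n")
  cat("  mu =", x$mu, "/site/generation  (4N1mu =", 4 * x$N1 * x$mu, ")\n")
  invisible(x)
}

#' Specify the sampled loci
#'
#' @param n_loci Number of independent loci per dataset.
#' @param locus_length Locus length in bp.
#' @param n1,n2 Sampled chromosomes per population (default 12 each: six
#'   diploids per population).
#' @return A `loci_spec` list.
#' @export
loci_spec <- function(n_loci = 4749, locus_length = 1200, n1 = 12, n2 = 12) {
  stopifnot(n_loci >= 1, locus_length > 0, n1 >= 2, n2 >= 2, n1 + n2 <= 64)
  structure(list(n_loci = n_loci, locus_length = locus_length,
                 n1 = n1, n2 = n2), class = "loci_spec")
}

#' Simulate one dataset and classify its mutations
#'
#' Simulates `n_loci` independent genealogies under the IM model, drops
#' infinite-sites mutations on them, and pools the site classification
#' (fixed / shared / exclusive / monomorphic) across loci.
#'
#' @param model An `im_model`.
#' @param spec A `loci_spec`.
#' @param return_counts Also return per-mutation derived-allele counts.
#' @return List of pooled counts (and optionally `derived_p1`,
#'   `derived_p2` vectors).
#' @export
im_simulate_dataset <- function(model, spec, return_counts = FALSE) {
  stopifnot(inherits(model, "im_model"), inherits(spec, "loci_spec"))
  .cpp_im_dataset(spec$n_loci, spec$n1, spec$n2,
                  model$N1, model$N2, model$N_anc, model$T_split,
                  model$m12, model$m21, model$mu, spec$locus_length,
                  return_counts)
}

#' Fixed-to-shared ratio of one simulated dataset
#'
#' @inheritParams im_simulate_dataset
#' @return List with `fixed`, `shared` and `ratio` (`Inf` when no shared
#'   polymorphism arose but fixed differences did; `NA` when neither did).
#' @export
im_dataset_ratio <- function(model, spec) {
  counts <- im_simulate_dataset(model, spec)
  ratio <- if (counts$shared == 0) {
    if (counts$fixed == 0) NA_real_ else Inf
  } else counts$fixed / counts$shared
  list(fixed = counts$fixed, shared = counts$shared, ratio = ratio)
}

#' Null distribution of the fixed:shared ratio under the IM model
#'
#' Simulates `n_replicates` datasets, records each replicate's pooled
#' fixed:shared ratio, and reports the empirical p-value of the observed
#' ratio with the add-one estimator
#' `(1 + #\{ratio_rep >= observed\}) / (1 + n_replicates)`. Replicates
#' with fixed differences but no shared polymorphism count as exceeding
#' any finite observed ratio; replicates with neither are ratio 0 for the
#' comparison (nothing exceeds a positive observation).
#'
#' @inheritParams im_simulate_dataset
#' @param observed_ratio Observed fixed:shared ratio to test.
#' @param n_replicates Number of replicate datasets (>= 100).
#' @param seed Integer seed.
#' @return An `im_null` object: `replicates` (ratio vector), `observed`,
#'   `p_value`, `n_replicates`, `seed`.
#' @export
im_null <- function(model, spec, observed_ratio, n_replicates = 1000,
                    seed = 1) {
  stopifnot(inherits(model, "im_model"), inherits(spec, "loci_spec"))
  if (!is.finite(observed_ratio))
    stop("observed_ratio must be a finite number")
  if (n_replicates < 100) stop("use at least 100 replicates")
  set.seed(seed)
  reps <- .cpp_im_ratio_replicates(n_replicates, spec$n_loci,
                                   spec$n1, spec$n2,
                                   model$N1, model$N2, model$N_anc,
                                   model$T_split, model$m12, model$m21,
                                   model$mu, spec$locus_length)
  cmp <- reps
  cmp[is.na(cmp)] <- 0  # no variation at all: cannot exceed a positive obs
  n_ge <- sum(cmp >= observed_ratio)
  structure(list(replicates = reps, observed = observed_ratio,
                 p_value = (1 + n_ge) / (1 + n_replicates),
                 n_exceeding = n_ge,
                 n_replicates = n_replicates, seed = seed,
                 model = model, spec = spec),
            class = "im_null")
}

#' @export
print.im_null <- function(x, ...) {
  fin <- x$replicates[is.finite(x$replicates)]
  cat("im_null:", x$n_replicates, "replicate datasets of",
      x$spec$n_loci, "loci\n")
  cat("  replicate fixed:shared ratio: mean", format(mean(fin)),
      " max", format(if (length(fin)) max(fin) else NA), "\n")
  cat("  observed ratio", x$observed, ": empirical p =",
      format(x$p_value), "(", x$n_exceeding, "replicates >= observed )\n")
  invisible(x)
}

#' Single-deme coalescent calibration draws
#'
#' Simulates genealogies of `n` chromosomes in one panmictic diploid
#' population and returns the time to the most recent common ancestor of
#' each replicate, in generations. Under X-chromosome scaling the
#' effective size is multiplied by 3/4. The large-sample expectation is
#' `4 N (1 - 1/n)` generations (autosomes) and 3/4 of that for the X.
#'
#' @param N Diploid effective size.
#' @param n Sample size in chromosomes (<= 64).
#' @param n_replicates Number of independent genealogies.
#' @param chromosome `"autosome"` or `"X"`.
#' @param seed Integer seed.
#' @return Numeric vector of TMRCA values in generations.
#' @export
sim_tmrca <- function(N, n, n_replicates = 10000,
                      chromosome = c("autosome", "X"), seed = 1) {
  chromosome <- match.arg(chromosome)
  Ne <- if (chromosome == "X") 0.75 * N else N
  set.seed(seed)
  .cpp_sim_tmrca(n_replicates, n, Ne)
}

#' Single-deme segregating sites and diversity per locus
#'
#' Engine-calibration helper: simulates loci in a single panmictic deme
#' and returns per-locus segregating-site counts and mean pairwise
#' diversity per site, whose expectations are `theta * a_{n-1}` (with
#' `theta = 4 N mu L` per locus) and `4 N mu` per site.
#'
#' @inheritParams sim_tmrca
#' @param n_loci Number of loci.
#' @param mu Mutation rate per site per generation.
#' @param locus_length Locus length in bp.
#' @return Data.frame with columns `S` and `pi`.
#' @export
sim_single_deme <- function(N, n, n_loci = 1000, mu = 1.25e-9,
                            locus_length = 1200, seed = 1) {
  set.seed(seed)
  m <- .cpp_sim_single_deme_stats(n_loci, n, N, mu, locus_length)
  data.frame(S = m[, 1L], pi = m[, 2L])
}
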