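# Synthetic paired GWAS summary statistics with known pleiotropic structure.
#
# The generator draws per-SNP z-scores from a four-component mixture:
# null/null, trait-A-only, trait-B-only, and shared non-null.  Non-null
# z-scores are Normal(0, sigma^2) with sigma > 1 (a symmetric scale mixture:
# enrichment in the tails without asserting effect directions).  Shared SNPs
# use the same component indicator but independent effect draws per trait, so
# the two traits share loci, not effect sizes.

#' Specify the four-component mixture for paired summary statistics
#'
#' @param pi00,pi10,pi01,pi11 Proportions of SNPs that are null for both
#'   traits, non-null for trait A only, non-null for trait B only, and shared
#'   non-null. Must be nonnegative and sum to 1 (tolerance 1e-12).
#' @param sigma_a,sigma_b Standard deviation of non-null z-scores per trait;
#'   must exceed 1 for a non-degenerate alternative (the null draws have
#'   standard deviation 1).
#' @param n_snps Number of SNPs to simulate.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @param n_chr Number of chromosomes over which SNPs are laid out
#'   (default 22); positions are sequential with fixed 10 kb spacing.
#' @return A validated `mixture_spec` object.
#' @export
mixture_spec <- function(pi00 = 0.90, pi10 = 0.04, pi01 = 0.04, pi11 = 0.02,
                         sigma_a = 3, sigma_b = 3, n_snps = 10000L,
                         seed = 1L, n_chr = 22L) {
  pis <- c(pi00 = pi00, pi10 = pi10, pi01 = pi01, pi11 = pi11)
  for (nm in names(pis)) {
    stopifnot_scalar_number(pis[[nm]], nm)
    if (pis[[nm]] < 0)
      validation_error(sprintf("mixture proportion '%s' must be nonnegative", nm))
  }
  if (abs(sum(pis) - 1) > 1e-12)
    validation_error(sprintf(
      "mixture proportions pi00+pi10+pi01+pi11 must sum to 1 (got %.15f)", sum(pis)))
  for (nm in c("sigma_a", "sigma_b")) {
    val <- get(nm)
    stopifnot_scalar_number(val, nm)
    if (val <= 1)
      validation_error(sprintf("'%s' must be > 1 for a non-degenerate alternative", nm))
  }
  stopifnot_scalar_number(n_snps, "n_snps")
  if (n_snps < 1) validation_error("'n_snps' must be >= 1")
  stopifnot_scalar_number(seed, "seed")
  structure(list(pi00 = pi00, pi10 = pi10, pi01 = pi01, pi11 = pi11,
                 sigma_a = sigma_a, sigma_b = sigma_b,
                 n_snps = as.integer(n_snps), seed = as.integer(seed),
                 n_chr = as.integer(n_chr)),
            class = "mixture_spec")
}

#' Specify block-wise LD structure for the simulated SNPs
#'
#' Latent genotype scores within a block are equicorrelated Gaussian with
#' correlation `rho`; per-SNP minor-allele frequencies are drawn uniformly
#' from `maf_range`. The latent score matrix is what [ld_prune()] consumes
#' as its r-squared source.
#'
#' @param block_size SNPs per LD block (>= 1).
#' @param rho Within-block correlation of latent genotype scores. Must
#'   satisfy `-1/(block_size - 1) <= rho < 1` (equicorrelation constraint).
#' @param maf_range Length-2 interval for per-SNP minor-allele frequency,
#'   within (0, 0.5].
#' @param n_samples Latent samples drawn per SNP (rows of the score matrix).
#' @return A validated `ld_block_spec` object.
#' @export
ld_block_spec <- function(block_size = 10L, rho = 0.8,
                          maf_range = c(0.05, 0.5), n_samples = 400L) {
  stopifnot_scalar_number(block_size, "block_size")
  if (block_size < 1) validation_error("'block_size' must be >= 1")
  stopifnot_scalar_number(rho, "rho")
  if (abs(rho) >= 1) validation_error("'rho' must satisfy |rho| < 1")
  if (block_size > 1 && rho < -1 / (block_size - 1))
    validation_error("'rho' below the equicorrelation bound -1/(block_size-1)")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    validation_error("'maf_range' must be an increasing interval within (0, 0.5]")
  stopifnot_scalar_number(n_samples, "n_samples")
  structure(list(block_size = as.integer(block_size), rho = rho,
                 maf_range = as.numeric(maf_range),
                 n_samples = as.integer(n_samples)),
            class = "ld_block_spec")
}

# two-sided p from z, kept strictly positive so -log10 stays finite
z_to_p <- function(z) pmax(2 * pnorm(-abs(z)), 1e-300)

#' Simulate paired GWAS summary statistics with known component labels
#'
#' Draws component labels with the spec's mixture proportions, z-scores per
#' trait (Normal(0,1) under the null, Normal(0, sigma^2) when the trait is
#' non-null for that SNP), converts them to two-sided p-values
#' `2 * pnorm(-|z|)`, and lays SNPs out sequentially over `n_chr`
#' chromosomes. With an [ld_block_spec()], per-SNP MAFs are attached and an
#' equicorrelated latent genotype-score matrix is returned for LD pruning.
#'
#' @param spec A [mixture_spec()].
#' @param ld Optional [ld_block_spec()].
#' @return A list of class `paired_stats_sim` with elements:
#'   `stats` (a `paired_stats` data frame: snp, chr, pos, p_a, p_b and,
#'   with LD, maf), `labels` (factor with levels null/a_only/b_only/shared),
#'   `genotypes` (latent score matrix, samples x SNPs, only with LD), and
#'   `spec`.
#' @export
simulate_paired_stats <- function(spec, ld = NULL) {
  if (!inherits(spec, "mixture_spec"))
    validation_error("'spec' must be a mixture_spec object")
  if (!is.null(ld) && !inherits(ld, "ld_block_spec"))
    validation_error("'ld' must be an ld_block_spec object or NULL")
  n <- spec$n_snps
  set.seed(spec$seed)

  labels <- factor(
    sample(c("null", "a_only", "b_only", "shared"), n, replace = TRUE,
           prob = c(spec$pi00, spec$pi10, spec$pi01, spec$pi11)),
    levels = c("null", "a_only", "b_only", "shared"))

  sd_a <- ifelse(labels %in% c("a_only", "shared"), spec$sigma_a, 1)
  sd_b <- ifelse(labels %in% c("b_only", "shared"), spec$sigma_b, 1)
  z_a <- rnorm(n, 0, sd_a)
  z_b <- rnorm(n, 0, sd_b)

  # sequential positions, fixed 10 kb spacing, SNPs split evenly over chromosomes
  chr_idx <- rep(seq_len(spec$n_chr), length.out = n)
  chr_idx <- sort(chr_idx)
  pos <- unlist(lapply(split(seq_len(n), chr_idx), function(i) seq_along(i) * 10000L),
                use.names = FALSE)
  stats <- data.frame(
    snp = sprintf("rs%07d", seq_len(n)),
    chr = as.character(chr_idx),
    pos = pos,
    p_a = z_to_p(z_a),
    p_b = z_to_p(z_b),
    stringsAsFactors = FALSE)

  genotypes <- NULL
  if (!is.null(ld)) {
    stats$maf <- runif(n, ld$maf_range[1], ld$maf_range[2])
    block <- (seq_len(n) - 1L) %/% ld$block_size   # last block may be short
    r <- ld$rho
    # equicorrelated scores: sqrt(r) * block factor + sqrt(1-r) * noise
    g <- matrix(rnorm(ld$n_samples * n), ld$n_samples, n)
    if (r > 0) {
      for (b in unique(block)) {
        cols <- which(block == b)
        f <- rnorm(ld$n_samples)
        g[, cols] <- sqrt(r) * f + sqrt(1 - r) * g[, cols]
      }
    }
    colnames(g) <- stats$snp
    genotypes <- g
  }

  class(stats) <- c("paired_stats", "data.frame")
  structure(list(stats = stats, labels = labels, genotypes = genotypes,
                 spec = spec),
            class = "paired_stats_sim")
}

#' Specify an instrument-level MR simulation
#'
#' @param n_instruments Number of instruments (>= 3; Egger regression and the
#'   mode estimators are undefined below that).
#' @param true_effect Causal slope of exposure on outcome.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-instrument
#'   direct (pleiotropic) effect on the outcome; mean 0 with positive SD is
#'   balanced pleiotropy, nonzero mean is directional.
#' @param se_exp,se_out Instrument-level standard errors (>= 0).
#' @param seed Integer seed.
#' @return A validated `mr_sim_spec` object.
#' @export
mr_sim_spec <- function(n_instruments = 50L, true_effect = 0.3,
                        pleiotropy_mean = 0, pleiotropy_sd = 0,
                        se_exp = 0.01, se_out = 0.05, seed = 1L) {
  stopifnot_scalar_number(n_instruments, "n_instruments")
  if (n_instruments < 3)
    validation_error("'n_instruments' must be >= 3 (Egger regression needs 3)")
  for (nm in c("true_effect", "pleiotropy_mean", "pleiotropy_sd",
               "se_exp", "se_out")) stopifnot_scalar_number(get(nm), nm)
  if (pleiotropy_sd < 0 || se_exp < 0 || se_out < 0)
    validation_error("'pleiotropy_sd', 'se_exp' and 'se_out' must be >= 0")
  stopifnot_scalar_number(seed, "seed")
  structure(list(n_instruments = as.integer(n_instruments),
                 true_effect = true_effect,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 se_exp = se_exp, se_out = se_out, seed = as.integer(seed)),
            class = "mr_sim_spec")
}

#' Simulate a two-sample MR instrument table
#'
#' Per-instrument exposure effects are drawn away from zero (uniform on
#' 0.05–0.30; instruments are coded with the exposure-increasing allele as
#' effect allele, the usual two-sample MR convention, so directional
#' pleiotropy has a well-defined sign), observed with noise `se_exp`;
#' outcome effects follow
#' `beta_out = true_effect * beta_exp + alpha + Normal(0, se_out)`, with the
#' direct effect `alpha ~ Normal(pleiotropy_mean, pleiotropy_sd)`. Alleles
#' are non-palindromic (A/G) so the table round-trips unchanged through
#' [harmonize_instruments()].
#'
#' @param spec An [mr_sim_spec()].
#' @return An `mr_instruments` data frame with per-instrument columns snp,
#'   beta_exp, se_exp, beta_out, se_out, effect alleles for both traits, and
#'   the true direct effect as column `alpha` (ground truth, dropped by the
#'   estimators).
#' @export
simulate_mr_instruments <- function(spec) {
  if (!inherits(spec, "mr_sim_spec"))
    validation_error("'spec' must be an mr_sim_spec object")
  set.seed(spec$seed)
  n <- spec$n_instruments
  gamma <- runif(n, 0.05, 0.30)
  beta_exp <- gamma + rnorm(n, 0, spec$se_exp)
  alpha <- rnorm(n, spec$pleiotropy_mean, spec$pleiotropy_sd)
  beta_out <- spec$true_effect * beta_exp + alpha + rnorm(n, 0, spec$se_out)
  out <- data.frame(
    snp = sprintf("rs%06d", seq_len(n)),
    beta_exp = beta_exp,
    se_exp = rep(max(spec$se_exp, 1e-8), n),
    beta_out = beta_out,
    se_out = rep(max(spec$se_out, 1e-8), n),
    ea_exp = "A", oa_exp = "G", ea_out = "A", oa_out = "G",
    alpha = alpha,
    stringsAsFactors = FALSE)
  class(out) <- c("mr_instruments", "data.frame")
  out
}
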