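# Two-sample Mendelian randomization from instrument-level summary
# statistics: inverse-variance weighting of Wald ratios, Egger regression,
# the weighted median, and the mode-based (simple / weighted) estimators.
#
# Conventions shared by all estimators:
#   * per-instrument Wald ratio theta_j = beta_out_j / beta_exp_j with
#     first-order SE se_out_j / |beta_exp_j| (the exposure SE is ignored by
#     default, the standard reporting choice; a second-order option exists);
#   * IVW defaults to multiplicative random effects: the fixed-effect SE is
#     scaled by max(1, sqrt(Q / (n - 1))) with Q Cochran's statistic, so
#     heterogeneity can widen but never narrow the interval;
#   * bootstrap SEs (median/mode) are parametric and seeded.

new_mr_result <- function(method, b, se, p, n_snp, ratios = NULL, extra = list()) {
  p <- max(min(p, 1), 1e-300)   # keep p in (0, 1]
  structure(c(list(method = method, b = b, se = se, p = p, n_snp = n_snp,
                   ratios = ratios), extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: b = %.6g, se = %.6g, p = %.3g (n_snp = %d)\n",
              x$method, x$b, x$se, x$p, x$n_snp))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.6g, se = %.6g, p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

is_palindromic <- function(a1, a2) {
  pair <- paste(pmin(toupper(a1), toupper(a2)), pmax(toupper(a1), toupper(a2)))
  pair %in% c("A T", "C G")
}

#' Harmonize exposure and outcome instrument records
#'
#' Intersects on rsID, flips the sign of the outcome effect when its effect
#' allele is the exposure's other allele, drops palindromic (A/T, C/G) SNPs
#' and allele-incompatible SNPs with counts.
#'
#' @param exposure,outcome Data frames with columns snp, beta, se,
#'   effect_allele, other_allele.
#' @return An `mr_instruments` data frame (snp, beta_exp, se_exp, beta_out,
#'   se_out, ea_exp, oa_exp, ea_out, oa_out) with attributes
#'   `n_palindromic_dropped` and `n_incompatible_dropped`.
#' @export
harmonize_instruments <- function(exposure, outcome) {
  req <- c("snp", "beta", "se", "effect_allele", "other_allele")
  for (x in list(exposure, outcome))
    if (!all(req %in% names(x)))
      validation_error("instrument inputs need snp/beta/se/effect_allele/other_allele")
  common <- intersect(exposure$snp, outcome$snp)
  ie <- match(common, exposure$snp); io <- match(common, outcome$snp)
  ea_e <- toupper(exposure$effect_allele[ie]); oa_e <- toupper(exposure$other_allele[ie])
  ea_o <- toupper(outcome$effect_allele[io]);  oa_o <- toupper(outcome$other_allele[io])

  pal <- is_palindromic(ea_e, oa_e)
  aligned <- ea_e == ea_o & oa_e == oa_o
  swapped <- ea_e == oa_o & oa_e == ea_o & !aligned
  keep <- !pal & (aligned | swapped)
  n_pal <- sum(pal)
  n_incompat <- sum(!pal & !aligned & !swapped)

  beta_out <- ifelse(swapped, -outcome$beta[io], outcome$beta[io])
  out <- data.frame(snp = common,
                    beta_exp = exposure$beta[ie], se_exp = exposure$se[ie],
                    beta_out = beta_out, se_out = outcome$se[io],
                    ea_exp = ea_e, oa_exp = oa_e,
                    ea_out = ea_e, oa_out = oa_e,   # post-harmonization alleles
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    empty_input_error("no instruments survive harmonization")
  rownames(out) <- NULL
  structure(out, class = c("mr_instruments", "data.frame"),
            n_palindromic_dropped = n_pal,
            n_incompatible_dropped = n_incompat)
}

check_instruments <- function(set, min_n) {
  req <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(req %in% names(set)))
    validation_error("instrument set needs beta_exp/se_exp/beta_out/se_out")
  if (any(set$se_exp <= 0) || any(set$se_out <= 0))
    validation_error("instrument standard errors must be > 0")
  if (nrow(set) < min_n)
    validation_error(sprintf("at least %d instruments required (got %d)",
                             min_n, nrow(set)))
  invisible(set)
}

#' Per-instrument Wald ratios
#'
#' theta_j = beta_out_j / beta_exp_j with first-order standard error
#' se_out_j / |beta_exp_j| (optionally the second-order form that also
#' propagates the exposure SE). Instrument order is preserved; this is the
#' per-SNP layer of the forest plot.
#'
#' @param set An `mr_instruments` data frame.
#' @param second_order Use the second-order SE
#'   sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2/beta_exp^4)? Default FALSE.
#' @return Data frame (snp, theta, se).
#' @export
wald_ratios <- function(set, second_order = FALSE) {
  check_instruments(set, 1L)
  zero <- set$beta_exp == 0
  if (any(zero))
    validation_error(sprintf("zero exposure effect for instrument(s): %s",
                             paste(set$snp[zero], collapse = ", ")))
  theta <- set$beta_out / set$beta_exp
  se <- if (second_order)
    sqrt(set$se_out^2 / set$beta_exp^2 +
           set$beta_out^2 * set$se_exp^2 / set$beta_exp^4)
  else set$se_out / abs(set$beta_exp)
  data.frame(snp = if (!is.null(set$snp)) set$snp else seq_len(nrow(set)),
             theta = theta, se = se, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted mean of the Wald ratios with weights 1/se^2. The default is
#' multiplicative random effects: the fixed-effect SE is inflated by
#' max(1, sqrt(Q/(n-1))) where Q is Cochran's heterogeneity statistic;
#' `random_effects = FALSE` gives the plain fixed-effect SE.
#'
#' @param set An `mr_instruments` data frame (>= 2 instruments).
#' @param random_effects Multiplicative random-effects SE scaling? Default TRUE.
#' @return An `mr_result` (with `Q` as extra field).
#' @export
mr_ivw <- function(set, random_effects = TRUE) {
  check_instruments(set, 2L)
  wr <- wald_ratios(set)
  w <- 1 / wr$se^2
  b <- sum(w * wr$theta) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (wr$theta - b)^2)
  se <- if (random_effects) se_fixed * max(1, sqrt(q / (nrow(wr) - 1))) else se_fixed
  p <- if (se == 0) as.numeric(b == 0) else 2 * pnorm(-abs(b / se))
  new_mr_result("Inverse variance weighted", b, se, p, nrow(wr), wr,
                extra = list(Q = q, random_effects = random_effects))
}

#' Egger regression
#'
#' Weighted least squares of beta_out on beta_exp with an intercept, weights
#' 1/se_out^2, after orienting every instrument so beta_exp >= 0. The slope
#' is the causal estimate; the intercept estimates directional pleiotropy.
#' SEs carry the multiplicative random-effects scale max(1, sigma); p-values
#' use the t reference with n - 2 degrees of freedom.
#'
#' @param set An `mr_instruments` data frame (>= 3 instruments with variation
#'   in beta_exp).
#' @return An `mr_result` with `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(set, random_effects = TRUE) {
  check_instruments(set, 3L)
  flip <- sign(set$beta_exp)
  flip[flip == 0] <- 1
  x <- set$beta_exp * flip
  y <- set$beta_out * flip
  if (sd(x) == 0)
    validation_error("degenerate design: no variation in |beta_exp|")
  w <- 1 / set$se_out^2
  fit <- lm(y ~ x, weights = w)
  n <- length(x)
  sigma <- summary(fit)$sigma
  scale <- if (random_effects) max(1, sigma) else sigma
  xtwx_inv_sqrt <- summary(fit)$coefficients[, "Std. Error"] /
    ifelse(sigma > 0, sigma, 1)   # unscaled (X'WX)^{-1} diagonal, sqrt
  est <- coef(fit)
  se <- xtwx_inv_sqrt * scale
  tval <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  pval <- 2 * pt(-abs(tval), df = n - 2)
  new_mr_result("MR Egger", est[["x"]], se[["x"]], pval[["x"]], n,
                wald_ratios(set),
                extra = list(intercept = est[["(Intercept)"]],
                             intercept_se = se[["(Intercept)"]],
                             intercept_p = max(min(pval[["(Intercept)"]], 1), 1e-300)))
}

# weighted median of theta with normalized weights: positions at the
# cumulative-weight midpoints, linear interpolation between them
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o] / sum(w)
  pmid <- cumsum(w) - w / 2
  if (0.5 <= pmid[1]) return(theta[1])
  n <- length(theta)
  if (0.5 >= pmid[n]) return(theta[n])
  approx(pmid, theta, xout = 0.5, ties = "ordered")$y
}

boot_resample <- function(set, n_boot, seed, point_fun) {
  set.seed(seed)
  vapply(seq_len(n_boot), function(i) {
    be <- rnorm(nrow(set), set$beta_exp, set$se_exp)
    bo <- rnorm(nrow(set), set$beta_out, set$se_out)
    point_fun(bo / be, 1 / (set$se_out / abs(be))^2)
  }, numeric(1))
}

#' Weighted-median estimate
#'
#' Instruments are ordered by Wald ratio; the estimate is the inverse-
#' variance-weighted median (cumulative weight crossing 0.5, linear
#' interpolation between the straddling ratios). The SE comes from a seeded
#' parametric bootstrap: beta_exp and beta_out are resampled from their
#' normal errors `n_boot` times and the bootstrap SD is reported. Consistent
#' when instruments holding at least half the weight are valid.
#'
#' @param set An `mr_instruments` data frame (>= 3 instruments).
#' @param n_boot Bootstrap replicates (default 1000; below 100 a warning is
#'   issued).
#' @param seed Bootstrap seed (required for reproducibility).
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000L, seed = 1L) {
  check_instruments(set, 3L)
  if (n_boot < 100) warning("n_boot < 100 gives unstable bootstrap SEs")
  wr <- wald_ratios(set)
  b <- weighted_median_point(wr$theta, 1 / wr$se^2)
  boots <- boot_resample(set, n_boot, seed,
                         function(theta, w) weighted_median_point(theta, w))
  se <- sd(boots)
  p <- if (se == 0) as.numeric(b == 0) else 2 * pnorm(-abs(b / se))
  new_mr_result("Weighted median", b, se, p, nrow(wr), wr)
}

# mode of a weighted kernel density over theta; bandwidth via the modified
# Silverman rule h = factor * 0.9 * min(sd, mad) * n^(-1/5) (mad falls back
# to sd when zero, e.g. >50% ties)
mode_point <- function(theta, w, bandwidth_factor) {
  if (max(theta) == min(theta)) return(theta[1])
  s_mad <- mad(theta)
  s <- 0.9 * min(sd(theta), if (s_mad > 0) s_mad else sd(theta)) *
    length(theta)^(-1 / 5)
  h <- bandwidth_factor * s
  if (h <= 0) validation_error("zero kernel bandwidth for the mode estimator")
  d <- density(theta, weights = w / sum(w), bw = h, n = 1024)
  d$x[which.max(d$y)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The estimate is the argmax of a normal-kernel density over the Wald
#' ratios — unweighted ("simple mode") or inverse-variance weighted
#' ("weighted mode") — with bandwidth `bandwidth_factor` times the modified
#' Silverman rule 0.9 min(sd, mad) n^(-1/5). Consistent when the largest
#' group of instruments sharing a ratio is valid (ZEMPA). SE from a seeded
#' parametric bootstrap.
#'
#' @param set An `mr_instruments` data frame (>= 3 instruments).
#' @param weighted Inverse-variance weights? FALSE = simple mode.
#' @param bandwidth_factor Multiplier on the modified-Silverman bandwidth
#'   (default 1).
#' @param n_boot,seed Bootstrap replicates and seed.
#' @return An `mr_result`.
#' @export
mr_mode <- function(set, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 1000L, seed = 1L) {
  check_instruments(set, 3L)
  if (bandwidth_factor <= 0) validation_error("'bandwidth_factor' must be > 0")
  if (n_boot < 100) warning("n_boot < 100 gives unstable bootstrap SEs")
  wr <- wald_ratios(set)
  w_point <- if (weighted) 1 / wr$se^2 else rep(1, nrow(wr))
  b <- mode_point(wr$theta, w_point, bandwidth_factor)
  boots <- boot_resample(set, n_boot, seed, function(theta, w) {
    mode_point(theta, if (weighted) w else rep(1, length(theta)), bandwidth_factor)
  })
  se <- sd(boots)
  p <- if (se == 0) as.numeric(b == 0) else 2 * pnorm(-abs(b / se))
  new_mr_result(if (weighted) "Weighted mode" else "Simple mode",
                b, se, p, nrow(wr), wr)
}

#' Run all five MR estimators
#'
#' @param set An `mr_instruments` data frame.
#' @param n_boot,seed Bootstrap settings shared by the median and mode
#'   estimators.
#' @param exposure,outcome Trait labels carried into the results table.
#' @return A list of class `mr_result_set`: `results` (the five
#'   `mr_result`s) and `table`, a data frame mirroring the conventional
#'   reporting layout (exposure, outcome, method, b, se, pval, n_snp).
#' @export
mr_all <- function(set, n_boot = 1000L, seed = 1L,
                   exposure = "exposure", outcome = "outcome") {
  results <- list(
    mr_egger(set),
    mr_weighted_median(set, n_boot = n_boot, seed = stage_seed(seed, 1L)),
    mr_ivw(set),
    mr_mode(set, weighted = FALSE, n_boot = n_boot, seed = stage_seed(seed, 2L)),
    mr_mode(set, weighted = TRUE, n_boot = n_boot, seed = stage_seed(seed, 3L)))
  table <- data.frame(
    exposure = exposure, outcome = outcome,
    method = vapply(results, `[[`, character(1), "method"),
    b = vapply(results, `[[`, numeric(1), "b"),
    se = vapply(results, `[[`, numeric(1), "se"),
    pval = vapply(results, `[[`, numeric(1), "p"),
    n_snp = vapply(results, `[[`, integer(1), "n_snp"),
    stringsAsFactors = FALSE)
  structure(list(results = results, table = table), class = "mr_result_set")
}

#' Forest- and scatter-plot data
#'
#' Forest rows: one per instrument (Wald ratio ± 1.96 SE) plus one combined
#' row per method. Scatter rows: the instrument effect pairs with SE bars,
#' plus per-method fitted lines (slope = the method's b; intercept 0 except
#' Egger, whose fitted intercept is carried).
#'
#' @param set An `mr_instruments` data frame.
#' @param results A list of `mr_result` objects (or an `mr_result_set`).
#' @return A list with data frames `forest` (label, kind, b, se, lo, hi) and
#'   `scatter_points` / `scatter_lines`.
#' @export
mr_plot_data <- function(set, results) {
  if (inherits(results, "mr_result_set")) results <- results$results
  if (length(results) == 0L) validation_error("'results' must be non-empty")
  wr <- wald_ratios(set)
  forest_snp <- data.frame(label = wr$snp, kind = "instrument",
                           b = wr$theta, se = wr$se, stringsAsFactors = FALSE)
  forest_meth <- data.frame(
    label = vapply(results, `[[`, character(1), "method"), kind = "method",
    b = vapply(results, `[[`, numeric(1), "b"),
    se = vapply(results, `[[`, numeric(1), "se"), stringsAsFactors = FALSE)
  forest <- rbind(forest_snp, forest_meth)
  forest$lo <- forest$b - qnorm(0.975) * forest$se
  forest$hi <- forest$b + qnorm(0.975) * forest$se
  lines <- data.frame(
    method = forest_meth$label,
    slope = forest_meth$b,
    intercept = vapply(results, function(r)
      if (is.null(r$intercept)) 0 else r$intercept, numeric(1)))
  points <- data.frame(snp = set$snp, beta_exp = set$beta_exp,
                       se_exp = set$se_exp, beta_out = set$beta_out,
                       se_out = set$se_out, stringsAsFactors = FALSE)
  list(forest = forest, scatter_points = points, scatter_lines = lines)
}

#' Write the MR results table
#'
#' @param res An `mr_result_set`.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(res, path) {
  if (!inherits(res, "mr_result_set")) validation_error("'res' must be an mr_result_set")
  write.table(res$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
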