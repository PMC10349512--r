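test_that("harmonization flips swapped alleles and drops palindromes", {
  exposure <- data.frame(snp = c("rs1", "rs2", "rs3"),
                         beta = c(0.1, 0.2, 0.3), se = 0.05,
                         effect_allele = c("A", "A", "C"),
                         other_allele = c("G", "T", "T"))
  outcome <- data.frame(snp = c("rs1", "rs2", "rs3"),
                        beta = c(0.05, 0.02, 0.03), se = 0.04,
                        effect_allele = c("G", "A", "C"),
                        other_allele = c("A", "T", "T"))
  h <- harmonize_instruments(exposure, outcome)
  expect_equal(h$snp, c("rs1", "rs3"))              # rs2 is A/T palindromic
  expect_equal(attr(h, "n_palindromic_dropped"), 1)
  expect_equal(h$beta_out, c(-0.05, 0.03))          # rs1 swapped -> negated
})

test_that("already-aligned simulated instruments round-trip unchanged", {
  set <- simulate_mr_instruments(mr_sim_spec(seed = 5))
  h <- harmonize_instruments(
    data.frame(snp = set$snp, beta = set$beta_exp, se = set$se_exp,
               effect_allele = set$ea_exp, other_allele = set$oa_exp),
    data.frame(snp = set$snp, beta = set$beta_out, se = set$se_out,
               effect_allele = set$ea_out, other_allele = set$oa_out))
  expect_equal(h$beta_out, set$beta_out)
  expect_equal(attr(h, "n_palindromic_dropped"), 0)
})

test_that("Wald ratios are direct arithmetic with first-order SEs", {
  set <- mk_set(0.2, 0.1, se_out = 0.02)
  wr <- wald_ratios(set)
  expect_equal(wr$theta, 0.5)
  expect_equal(wr$se, 0.1)
  expect_equal(wald_ratios(mk_set(0.2, 0))$theta, 0)
  expect_error(wald_ratios(mk_set(c(0.2, 0), c(0.1, 0.1))), "rs2",
               class = "conjfdr_validation_error")
})

test_that("IVW reduces to the equal-weight mean; Q = 0 when degenerate", {
  set <- mk_set(rep(1, 3), c(0.1, 0.2, 0.3), se_out = 0.1)
  r <- mr_ivw(set)
  expect_equal(r$b, 0.2)
  expect_equal(mr_ivw(set, random_effects = FALSE)$se, 0.1 / sqrt(3))
  same <- mk_set(rep(1, 4), rep(0.7, 4), se_out = 0.1)
  r2 <- mr_ivw(same)
  expect_equal(r2$b, 0.7)
  expect_equal(r2$Q, 0)
  expect_equal(r2$se, 0.1 / 2)   # RE scale floors at 1
})

test_that("IVW recovers the simulated causal effect", {
  set <- simulate_mr_instruments(
    mr_sim_spec(n_instruments = 50, true_effect = 0.3, seed = 11))
  r <- mr_ivw(set)
  expect_lt(abs(r$b - 0.3), 3 * r$se)
})

test_that("Egger fits exact and affine lines exactly", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  # suppressWarnings: summary.lm flags the (intentionally) perfect fit
  r <- suppressWarnings(mr_egger(mk_set(x, 0.5 * x)))
  expect_equal(r$b, 0.5, tolerance = 1e-10)
  expect_equal(r$intercept, 0, tolerance = 1e-10)
  r2 <- suppressWarnings(mr_egger(mk_set(x, 0.5 * x + 0.1)))
  expect_equal(r2$b, 0.5, tolerance = 1e-10)
  expect_equal(r2$intercept, 0.1, tolerance = 1e-10)
})

test_that("Egger equals the closed-form weighted normal equations", {
  set <- mk_set(c(0.12, 0.2, 0.31, 0.4, 0.55),
                c(0.05, 0.12, 0.18, 0.16, 0.3),
                se_out = c(0.03, 0.05, 0.04, 0.06, 0.05))
  r <- mr_egger(set)
  ref <- unname(wls_oracle(set$beta_exp, set$beta_out, 1 / set$se_out^2))
  expect_equal(r$intercept, ref[1], tolerance = 1e-10)
  expect_equal(r$b, ref[2], tolerance = 1e-10)
})

test_that("Egger recovers injected directional pleiotropy", {
  set <- simulate_mr_instruments(
    mr_sim_spec(n_instruments = 50, true_effect = 0.3, pleiotropy_mean = 0.1,
                pleiotropy_sd = 0.02, seed = 23))
  r <- mr_egger(set)
  expect_lt(abs(r$intercept - 0.1), 3 * r$intercept_se)
  expect_error(mr_egger(mk_set(c(0.2, 0.2, 0.2), c(0.1, 0.1, 0.2))),
               "variation", class = "conjfdr_validation_error")
})

test_that("weighted median matches hand-computable cases", {
  r <- mr_weighted_median(mk_set(rep(1, 3), c(0.1, 0.2, 0.9), se_out = 0.1),
                          n_boot = 200, seed = 1)
  expect_equal(r$b, 0.2)
  # the middle instrument holds > 50% of the weight -> its ratio
  dom <- mk_set(rep(1, 3), c(0.1, 0.5, 0.9), se_out = c(0.2, 0.05, 0.2))
  expect_equal(mr_weighted_median(dom, n_boot = 200, seed = 1)$b, 0.5)
  expect_warning(mr_weighted_median(dom, n_boot = 50, seed = 1), "n_boot")
})

test_that("weighted median resists 30% invalid instruments where IVW fails", {
  for (s in 1:5) {
    set <- simulate_mr_instruments(
      mr_sim_spec(n_instruments = 60, true_effect = 0.3, se_out = 0.01, seed = s))
    bad <- seq_len(18)   # 30% with large directional pleiotropy
    set$beta_out[bad] <- set$beta_out[bad] + 0.25
    med <- mr_weighted_median(set, n_boot = 500, seed = 2)
    ivw <- mr_ivw(set)
    expect_lt(abs(med$b - 0.3), 3 * med$se)
    expect_gt(abs(ivw$b - 0.3), abs(med$b - 0.3))
  }
})

test_that("mode estimators find the dominant cluster", {
  theta <- c(rep(0.3, 7), rep(1.5, 3))
  set <- mk_set(rep(1, 10), theta, se_out = 0.05)
  r <- mr_mode(set, n_boot = 200, seed = 3)
  expect_lt(abs(r$b - 0.3), 0.2)
  # grid-search oracle over the same kernel density
  wr <- wald_ratios(set)
  s <- 0.9 * sd(wr$theta) * 10^(-1 / 5)
  grid <- seq(min(theta) - 3 * s, max(theta) + 3 * s, length.out = 4000)
  dens <- vapply(grid, function(g) sum(dnorm((g - wr$theta) / s)), numeric(1))
  expect_lt(abs(r$b - grid[which.max(dens)]), 0.05)
  # all ratios equal -> that value, and weighting is then irrelevant
  cset <- mk_set(rep(1, 5), rep(0.4, 5))
  expect_equal(mr_mode(cset, n_boot = 100, seed = 1)$b, 0.4)
  expect_equal(mr_mode(cset, weighted = TRUE, n_boot = 100, seed = 1)$b, 0.4)
})

test_that("weighted and simple mode agree under equal weights", {
  set <- mk_set(rep(1, 9), seq(0.1, 0.5, length.out = 9), se_out = 0.07)
  r1 <- mr_mode(set, weighted = FALSE, n_boot = 100, seed = 4)
  r2 <- mr_mode(set, weighted = TRUE, n_boot = 100, seed = 4)
  expect_equal(r1$b, r2$b)
})

test_that("estimators are sign- and scale-equivariant", {
  set <- simulate_mr_instruments(mr_sim_spec(n_instruments = 30, seed = 41))
  flip <- set; flip$beta_out <- -flip$beta_out
  scale <- set; scale$beta_exp <- 2 * scale$beta_exp; scale$se_exp <- 2 * scale$se_exp
  for (f in list(mr_ivw, function(s) mr_egger(s),
                 function(s) mr_weighted_median(s, n_boot = 200, seed = 5),
                 function(s) mr_mode(s, n_boot = 200, seed = 5))) {
    expect_equal(f(flip)$b, -f(set)$b, tolerance = 1e-8)
    expect_equal(f(scale)$b, f(set)$b / 2, tolerance = 1e-8)
  }
})

test_that("no-pleiotropy estimates agree across methods at many instruments", {
  set <- simulate_mr_instruments(
    mr_sim_spec(n_instruments = 200, true_effect = 0.3, seed = 47))
  res <- mr_all(set, n_boot = 300, seed = 6)
  # every estimate within its own 3-SE band, and pairwise agreement within
  # joint Monte-Carlo error
  expect_true(all(abs(res$table$b - 0.3) < 3 * res$table$se))
  for (i in 1:4) for (j in (i + 1):5)
    expect_lt(abs(res$table$b[i] - res$table$b[j]),
              3 * sqrt(res$table$se[i]^2 + res$table$se[j]^2))
})

test_that("seeded bootstraps reproduce bit-for-bit", {
  set <- simulate_mr_instruments(mr_sim_spec(n_instruments = 20, seed = 51))
  expect_identical(mr_weighted_median(set, n_boot = 300, seed = 9),
                   mr_weighted_median(set, n_boot = 300, seed = 9))
  expect_identical(mr_mode(set, n_boot = 300, seed = 9),
                   mr_mode(set, n_boot = 300, seed = 9))
})

test_that("plot data covers every instrument and method", {
  set <- simulate_mr_instruments(mr_sim_spec(n_instruments = 3, seed = 53))
  res <- list(mr_ivw(set), mr_egger(set))
  pd <- mr_plot_data(set, res)
  expect_equal(nrow(pd$forest), 5)   # 3 instruments + 2 methods
  ivw_line <- pd$scatter_lines[pd$scatter_lines$method == "Inverse variance weighted", ]
  expect_equal(ivw_line$intercept, 0)
  egger_line <- pd$scatter_lines[pd$scatter_lines$method == "MR Egger", ]
  expect_equal(egger_line$intercept, res[[2]]$intercept)
})
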