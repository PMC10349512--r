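test_that("mixture_spec validates proportions and sigmas", {
  expect_error(mixture_spec(pi00 = 0.5, pi10 = 0.2, pi01 = 0.2, pi11 = 0.2),
               "sum to 1", class = "conjfdr_validation_error")
  expect_error(mixture_spec(pi00 = 1.04, pi10 = -0.04, pi01 = 0, pi11 = 0),
               "pi10", class = "conjfdr_validation_error")
  expect_error(mixture_spec(sigma_a = 1), "sigma_a",
               class = "conjfdr_validation_error")
})

test_that("identical spec and seed give bit-identical output", {
  spec <- mixture_spec(n_snps = 2000, seed = 42)
  ld <- ld_block_spec(block_size = 5, rho = 0.5)
  s1 <- simulate_paired_stats(spec, ld)
  s2 <- simulate_paired_stats(spec, ld)
  expect_identical(s1$stats, s2$stats)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$genotypes, s2$genotypes)
})

test_that("pure-null mixture gives uniform p-values and null labels", {
  sim <- simulate_paired_stats(
    mixture_spec(pi00 = 1, pi10 = 0, pi01 = 0, pi11 = 0, n_snps = 1000, seed = 7))
  expect_true(all(sim$labels == "null"))
  expect_true(all(sim$stats$p_a > 0 & sim$stats$p_a <= 1))
  expect_gt(suppressWarnings(ks.test(sim$stats$p_a, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(sim$stats$p_b, "punif"))$p.value, 0.01)
})

test_that("all-shared mixture inflates both traits", {
  sim <- simulate_paired_stats(
    mixture_spec(pi00 = 0, pi10 = 0, pi01 = 0, pi11 = 1,
                 sigma_a = 3, sigma_b = 3, n_snps = 20000, seed = 7))
  expect_true(all(sim$labels == "shared"))
  expect_lt(median(sim$stats$p_a), 0.05)
  expect_lt(median(sim$stats$p_b), 0.05)
})

test_that("label counts match the mixture proportions within binomial bounds", {
  n <- 50000
  sim <- simulate_paired_stats(
    mixture_spec(pi00 = 0.90, pi10 = 0.04, pi01 = 0.04, pi11 = 0.02,
                 n_snps = n, seed = 1))
  counts <- table(sim$labels)
  expected <- c(null = 0.90, a_only = 0.04, b_only = 0.04, shared = 0.02)
  for (lab in names(expected)) {
    pi <- expected[[lab]]
    expect_lt(abs(counts[[lab]] - n * pi), 4 * sqrt(n * pi * (1 - pi)))
  }
})

test_that("shared signal induces positive dependence of significance", {
  sim <- simulate_paired_stats(
    mixture_spec(pi00 = 0.96, pi10 = 0, pi01 = 0, pi11 = 0.04,
                 n_snps = 50000, seed = 9))
  a <- sim$stats$p_a < 0.05
  b <- sim$stats$p_b < 0.05
  expect_gt(mean(a & b), mean(a) * mean(b))
})

test_that("LD blocks deliver MAFs in range and the target correlation", {
  ld <- ld_block_spec(block_size = 8, rho = 0.6, maf_range = c(0.1, 0.4),
                      n_samples = 8000)
  sim <- simulate_paired_stats(mixture_spec(n_snps = 64, seed = 5), ld)
  expect_true(all(sim$stats$maf >= 0.1 & sim$stats$maf <= 0.4))
  g <- sim$genotypes
  cors <- cor(g[, 1:8])
  off <- cors[upper.tri(cors)]
  expect_lt(max(abs(off - 0.6)), 0.05)
  # across blocks: independent
  expect_lt(abs(cor(g[, 1], g[, 9])), 0.05)
})

test_that("ld_block_spec rejects bad correlation and MAF ranges", {
  expect_error(ld_block_spec(rho = 1), class = "conjfdr_validation_error")
  expect_error(ld_block_spec(maf_range = c(0, 0.5)), class = "conjfdr_validation_error")
  expect_error(ld_block_spec(maf_range = c(0.1, 0.6)), class = "conjfdr_validation_error")
})

test_that("noiseless MR simulation yields exact Wald ratios", {
  spec <- mr_sim_spec(n_instruments = 20, true_effect = 0.3,
                      pleiotropy_sd = 0, se_out = 0, seed = 2)
  set <- simulate_mr_instruments(spec)
  wr <- wald_ratios(set)
  expect_equal(wr$theta, rep(0.3, 20), tolerance = 1e-12)
})

test_that("MR simulation rejects too few instruments, reproduces by seed", {
  expect_error(mr_sim_spec(n_instruments = 2), "Egger",
               class = "conjfdr_validation_error")
  s1 <- simulate_mr_instruments(mr_sim_spec(seed = 3))
  s2 <- simulate_mr_instruments(mr_sim_spec(seed = 3))
  expect_identical(s1, s2)
})

test_that("IVW is calibrated under the global null (Monte-Carlo)", {
  z <- vapply(1:200, function(s) {
    set <- simulate_mr_instruments(
      mr_sim_spec(n_instruments = 30, true_effect = 0, pleiotropy_mean = 0,
                  pleiotropy_sd = 0.0, se_exp = 0.01, se_out = 0.05, seed = s))
    r <- mr_ivw(set)
    abs(r$b / r$se)
  }, numeric(1))
  expect_gte(mean(z < 4), 0.99)
})
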