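# Independent oracles used across the suite.  These deliberately stay naive
# (double loops, full-block greedy, explicit normal equations) so they never
# share code with the implementation they check.

# Direct O(n^2) double loop of the cFDR counting formula.
brute_cfdr <- function(p_primary, p_conditional) {
  n <- length(p_primary)
  vapply(seq_len(n), function(i) {
    num <- sum(p_conditional <= p_conditional[i])
    den <- sum(p_primary <= p_primary[i] & p_conditional <= p_conditional[i])
    min(1, p_primary[i] * num / den)
  }, numeric(1))
}

# Greedy prune over one whole block (no windows): while any pair exceeds the
# threshold, drop the smaller-MAF member of the worst pair; MAF tie removes
# the later SNP.
brute_prune_block <- function(r2m, maf, threshold) {
  m <- nrow(r2m)
  alive <- rep(TRUE, m)
  diag(r2m) <- 0
  repeat {
    best <- c(0, 0); worst <- threshold
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (alive[i] && alive[j] && r2m[i, j] > worst) {
        worst <- r2m[i, j]; best <- c(i, j)
      }
    }
    if (best[1] == 0) break
    i <- best[1]; j <- best[2]
    drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else j
    alive[drop] <- FALSE
  }
  which(alive)
}

# Weighted least squares with intercept via the explicit normal equations.
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1]
}

# Hand-built MR instrument set.
mk_set <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.05) {
  out <- data.frame(snp = paste0("rs", seq_along(beta_exp)),
                    beta_exp = beta_exp, se_exp = rep_len(se_exp, length(beta_exp)),
                    beta_out = beta_out, se_out = rep_len(se_out, length(beta_exp)),
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_instruments", "data.frame")
  out
}

# Write a small sumstats file from literal lines.
write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Split a simulated paired table into one trait's sumstats records.
sim_trait <- function(sim, trait = c("a", "b")) {
  trait <- match.arg(trait)
  st <- sim$stats
  out <- data.frame(snp = st$snp, chr = st$chr, pos = st$pos,
                    p = if (trait == "a") st$p_a else st$p_b,
                    stringsAsFactors = FALSE)
  if (!is.null(st$maf)) out$maf <- st$maf
  class(out) <- c("sumstats", "data.frame")
  out
}
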