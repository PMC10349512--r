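# Stratified conditional Q-Q curves, the empirical conditional FDR and its
# conjunction.
#
# The cFDR estimator for SNP i with primary-trait p-value p_i and
# conditioning-trait p-value q_i is
#
#   cFDR_i = min(1,  p_i * #{j : q_j <= q_i} / #{j : p_j <= p_i & q_j <= q_i})
#
# i.e. the primary p-value divided by the empirical conditional CDF of the
# primary p-values within the subset of SNPs at least as significant on the
# conditioning trait.  Comparisons are inclusive and self-inclusive, so the
# denominator is never zero; ties count in full (no rank jittering); values
# above 1 are capped.  With a constant conditioning vector the estimator
# collapses exactly to p * N / rank, the familiar rank-based empirical FDR.

#' Stratified conditional Q-Q curves
#'
#' For each stratum threshold t, restricts to SNPs whose conditioning-trait
#' p-value is at most t and plots the empirical quantiles of the primary
#' trait's p-values: the k-th smallest p among the n_t stratum members gets
#' x = -log10(k / n_t) and y = -log10(p). Leftward deflection of tighter
#' strata (larger y at fixed x) is the classic pleiotropic-enrichment
#' signature. Both conditioning orientations are returned.
#'
#' @param paired A `paired_stats` data frame (snp, p_a, p_b, ...).
#' @param strata Stratum thresholds, sorted descending, each in (0, 1].
#'   Default is the conventional 1, 0.1, 0.01, 1e-3, 1e-4 ladder.
#' @return A list of class `qq_curve_set`: `curves`, a long data frame
#'   (orientation, stratum, x, y), and `counts`, per-orientation stratum SNP
#'   counts with an `empty` flag (empty strata produce no curve points).
#' @export
conditional_qq <- function(paired, strata = c(1, 0.1, 0.01, 0.001, 0.0001)) {
  if (!all(c("p_a", "p_b") %in% names(paired)) || nrow(paired) == 0L)
    validation_error("'paired' must be a non-empty paired_stats table")
  if (length(strata) < 1 || any(strata <= 0) || any(strata > 1) ||
      is.unsorted(rev(strata), strictly = TRUE))
    validation_error("'strata' must be strictly decreasing thresholds in (0, 1]")
  one_orientation <- function(p_main, p_cond, label) {
    curves <- list(); counts <- list()
    for (t in strata) {
      sel <- p_cond <= t
      n_t <- sum(sel)
      counts[[length(counts) + 1L]] <-
        data.frame(orientation = label, stratum = t, n = n_t, empty = n_t == 0L)
      if (n_t == 0L) next
      ps <- sort(p_main[sel])
      curves[[length(curves) + 1L]] <- data.frame(
        orientation = label, stratum = t,
        x = -log10(seq_len(n_t) / n_t), y = -log10(ps))
    }
    list(curves = do.call(rbind, curves), counts = do.call(rbind, counts))
  }
  ab <- one_orientation(paired$p_a, paired$p_b, "A|B")
  ba <- one_orientation(paired$p_b, paired$p_a, "B|A")
  structure(list(curves = rbind(ab$curves, ba$curves),
                 counts = rbind(ab$counts, ba$counts),
                 strata = strata),
            class = "qq_curve_set")
}

#' Per-SNP empirical conditional FDR
#'
#' @param p_primary P-values of the trait being tested, in (0, 1].
#' @param p_conditional P-values of the conditioning trait, same length.
#' @return Numeric vector of cFDR values in (0, 1], in input order.
#' @export
compute_cfdr <- function(p_primary, p_conditional) {
  if (length(p_primary) != length(p_conditional))
    validation_error("'p_primary' and 'p_conditional' must have equal length")
  check_prob_vector(p_primary, "p_primary")
  check_prob_vector(p_conditional, "p_conditional")
  num <- rank(p_conditional, ties.method = "max")         # #{q_j <= q_i}
  den <- dominance_count(p_primary, p_conditional)        # #{p_j <= p_i & q_j <= q_i}
  pmin(1, p_primary * num / den)
}

#' Conjunctional FDR: the larger of the two conditional FDRs
#'
#' @param cfdr_ab,cfdr_ba Equal-length cFDR vectors in \[0, 1\] (each trait
#'   conditioned on the other).
#' @return Element-wise maximum.
#' @export
conjunction_ccfdr <- function(cfdr_ab, cfdr_ba) {
  if (length(cfdr_ab) != length(cfdr_ba))
    validation_error("cFDR vectors must have equal length")
  if (any(!is.finite(cfdr_ab)) || any(!is.finite(cfdr_ba)) ||
      any(cfdr_ab < 0) || any(cfdr_ab > 1) || any(cfdr_ba < 0) || any(cfdr_ba > 1))
    validation_error("cFDR values must lie in [0, 1]")
  pmax(cfdr_ab, cfdr_ba)
}

#' Full per-SNP cFDR/ccFDR table
#'
#' Computes the conditional FDR in both directions (`cfdr_a_given_b`: trait A
#' primary, conditioned on trait B; `cfdr_b_given_a`: the reverse) and their
#' conjunction for every SNP of a paired table.
#'
#' @param paired A `paired_stats` data frame.
#' @return A `cfdr_table` data frame: snp, chr, pos, p_a, p_b,
#'   cfdr_a_given_b, cfdr_b_given_a, ccfdr.
#' @export
cfdr_table <- function(paired) {
  if (!all(c("snp", "chr", "pos", "p_a", "p_b") %in% names(paired)) ||
      nrow(paired) == 0L)
    validation_error("'paired' must be a non-empty paired_stats table")
  out <- data.frame(snp = paired$snp, chr = paired$chr, pos = paired$pos,
                    p_a = paired$p_a, p_b = paired$p_b,
                    stringsAsFactors = FALSE)
  out$cfdr_a_given_b <- compute_cfdr(paired$p_a, paired$p_b)
  out$cfdr_b_given_a <- compute_cfdr(paired$p_b, paired$p_a)
  out$ccfdr <- conjunction_ccfdr(out$cfdr_a_given_b, out$cfdr_b_given_a)
  class(out) <- c("cfdr_table", "data.frame")
  out
}

#' Export Q-Q curves as a long-format table
#'
#' @param qq A `qq_curve_set` from [conditional_qq()].
#' @param path Output path (tab-delimited: orientation, stratum, x, y).
#' @return `path`, invisibly.
#' @export
write_qq_curves <- function(qq, path) {
  if (!inherits(qq, "qq_curve_set")) validation_error("'qq' must be a qq_curve_set")
  write.table(qq$curves, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
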