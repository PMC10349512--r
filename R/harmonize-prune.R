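# Merge two traits' summary statistics on rsID and remove linked SNPs.
#
# Pruning follows the classic windowed greedy rule: slide a fixed-size SNP
# window along each chromosome; while any pair of surviving SNPs in the
# window has r^2 above the threshold, drop the smaller-MAF member of the
# currently worst (highest-r^2) pair.  Pairs at or below the threshold are
# retained (the "r2 <= 0.2 survives" semantics).  Ties in MAF remove the SNP
# later in (chr, pos) order; ties in r^2 resolve to the first pair in
# within-window index order.  Both rules exist only to make removal
# deterministic.

#' Intersect two traits' SNP sets into a paired table
#'
#' @param records_a,records_b `sumstats` data frames (see [read_sumstats()]).
#'   Coordinates are taken from trait A; a warning is raised if trait B
#'   disagrees on any shared rsID. MAF is carried from trait A when present,
#'   otherwise from trait B.
#' @return A `paired_stats` data frame (snp, chr, pos, p_a, p_b, optionally
#'   maf), sorted by (chr, pos), one row per common rsID.
#' @export
merge_traits <- function(records_a, records_b) {
  for (x in list(records_a, records_b))
    if (!all(c("snp", "chr", "pos", "p") %in% names(x)))
      validation_error("inputs must have snp/chr/pos/p columns")
  common <- intersect(records_a$snp, records_b$snp)
  if (length(common) == 0L)
    empty_input_error("the two traits share no rsIDs")
  ia <- match(common, records_a$snp)
  ib <- match(common, records_b$snp)
  if (any(records_a$pos[ia] != records_b$pos[ib] |
            records_a$chr[ia] != records_b$chr[ib]))
    warning(sprintf("%d shared rsID(s) disagree on coordinates; trait A's are used",
                    sum(records_a$pos[ia] != records_b$pos[ib] |
                          records_a$chr[ia] != records_b$chr[ib])))
  out <- data.frame(snp = common,
                    chr = records_a$chr[ia],
                    pos = records_a$pos[ia],
                    p_a = records_a$p[ia],
                    p_b = records_b$p[ib],
                    stringsAsFactors = FALSE)
  if (!is.null(records_a$maf)) out$maf <- records_a$maf[ia]
  else if (!is.null(records_b$maf)) out$maf <- records_b$maf[ib]
  out <- out[genomic_order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paired_stats", "data.frame")
  out
}

#' LD-pruning configuration
#'
#' @param r2_threshold Squared-correlation cutoff; a pair is linked when
#'   `r2 > r2_threshold` (default 0.2, i.e. pairs at or below 0.2 survive).
#' @param window_size SNP-count window (default 50).
#' @param window_step SNP-count step between windows (default 5).
#' @return A validated `prune_config` object.
#' @export
prune_config <- function(r2_threshold = 0.2, window_size = 50L, window_step = 5L) {
  stopifnot_scalar_number(r2_threshold, "r2_threshold")
  if (r2_threshold <= 0 || r2_threshold >= 1)
    validation_error("'r2_threshold' must be in (0, 1)")
  stopifnot_scalar_number(window_size, "window_size")
  if (window_size < 2) validation_error("'window_size' must be >= 2")
  stopifnot_scalar_number(window_step, "window_step")
  if (window_step < 1 || window_step > window_size)
    validation_error("'window_step' must be in [1, window_size]")
  structure(list(r2_threshold = r2_threshold,
                 window_size = as.integer(window_size),
                 window_step = as.integer(window_step)),
            class = "prune_config")
}

# Build a pairwise r^2 lookup from either a latent genotype-score matrix
# (samples x SNPs, columns named by rsID) or a precomputed pair list
# (snp1, snp2, r2).  Returns f(snps) -> symmetric r^2 matrix.
r2_lookup <- function(r2_source) {
  if (is.matrix(r2_source)) {
    if (is.null(colnames(r2_source)))
      config_error("genotype matrix must have rsID column names")
    function(snps) {
      miss <- setdiff(snps, colnames(r2_source))
      if (length(miss))
        config_error(sprintf("no genotype column for SNP(s): %s",
                             paste(head(miss, 5), collapse = ", ")))
      cor(r2_source[, snps, drop = FALSE])^2
    }
  } else if (is.data.frame(r2_source)) {
    if (!all(c("snp1", "snp2", "r2") %in% names(r2_source)))
      config_error("LD pair list must have columns snp1, snp2, r2")
    key <- c(paste(r2_source$snp1, r2_source$snp2),
             paste(r2_source$snp2, r2_source$snp1))
    val <- rep(r2_source$r2, 2L)
    function(snps) {
      m <- length(snps)
      out <- matrix(0, m, m, dimnames = list(snps, snps))
      diag(out) <- 1
      if (m > 1) {
        idx <- which(upper.tri(out), arr.ind = TRUE)
        k <- paste(snps[idx[, 1]], snps[idx[, 2]])
        hit <- match(k, key)
        r2 <- ifelse(is.na(hit), 0, val[hit])
        out[idx] <- r2
        out[idx[, c(2, 1), drop = FALSE]] <- r2
      }
      out
    }
  } else {
    config_error("'r2_source' must be a genotype matrix or an LD pair list")
  }
}

# Greedy removal inside one window. alive: logical over window indices.
# Returns indices (within the window) to remove.
prune_window <- function(r2m, maf, ord_rank, threshold) {
  m <- nrow(r2m)
  removed <- integer(0)
  alive <- rep(TRUE, m)
  diag(r2m) <- 0
  repeat {
    sub <- r2m
    sub[!alive, ] <- 0
    sub[, !alive] <- 0
    worst <- max(sub)
    if (worst <= threshold) break
    hit <- which(sub == worst, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]  # deterministic tie-break
    i <- hit[1, 1]; j <- hit[1, 2]
    if (any(is.na(maf[c(i, j)])))
      config_error("MAF missing for a SNP implicated in a linked pair")
    drop_idx <- if (maf[i] < maf[j]) i
      else if (maf[j] < maf[i]) j
      else if (ord_rank[i] > ord_rank[j]) i else j  # MAF tie: later (chr,pos) goes
    alive[drop_idx] <- FALSE
    removed <- c(removed, drop_idx)
  }
  removed
}

#' Windowed greedy LD pruning
#'
#' Within each sliding window (per chromosome), repeatedly finds the
#' surviving pair with the highest r-squared above the threshold and removes
#' its smaller-MAF member, until no surviving within-window pair exceeds the
#' threshold. The result is invariant to input row order (sorting is
#' internal) and deterministic under the documented tie rules.
#'
#' @param paired A `paired_stats` data frame with a `maf` column (MAF is
#'   required for any SNP implicated in a linked pair).
#' @param r2_source Either a latent genotype-score matrix (samples x SNPs,
#'   columns named by rsID) from which r-squared is computed as squared
#'   Pearson correlation, or a data frame pair list with columns
#'   `snp1`, `snp2`, `r2` (absent pairs count as r2 = 0).
#' @param cfg A [prune_config()].
#' @return A list of class `prune_result`: `kept` and `removed`
#'   (`paired_stats` row subsets partitioning the input), plus `cfg`.
#' @export
ld_prune <- function(paired, r2_source, cfg = prune_config()) {
  if (!all(c("snp", "chr", "pos") %in% names(paired)))
    validation_error("'paired' must have snp/chr/pos columns")
  if (!inherits(cfg, "prune_config")) validation_error("'cfg' must be a prune_config")
  lookup <- r2_lookup(r2_source)
  paired <- paired[genomic_order(paired$chr, paired$pos), , drop = FALSE]
  rownames(paired) <- NULL
  maf <- if ("maf" %in% names(paired)) paired$maf else rep(NA_real_, nrow(paired))

  removed_global <- logical(nrow(paired))
  for (chrom in unique(paired$chr)) {
    idx <- which(paired$chr == chrom)
    m <- length(idx)
    if (m < 2) next
    starts <- seq(1L, m, by = cfg$window_step)
    for (s in starts) {
      win <- idx[s:min(s + cfg$window_size - 1L, m)]
      win <- win[!removed_global[win]]
      if (length(win) < 2) next
      r2m <- lookup(paired$snp[win])
      rem <- prune_window(r2m, maf[win], seq_along(win), cfg$r2_threshold)
      removed_global[win[rem]] <- TRUE
      if (s + cfg$window_size - 1L >= m) break
    }
  }
  kept <- paired[!removed_global, , drop = FALSE]
  removed <- paired[removed_global, , drop = FALSE]
  rownames(kept) <- NULL
  rownames(removed) <- NULL
  class(kept) <- class(removed) <- c("paired_stats", "data.frame")
  structure(list(kept = kept, removed = removed, cfg = cfg),
            class = "prune_result")
}
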