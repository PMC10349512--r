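# Reading, validating and writing GWAS summary-statistics tables.
#
# The retained layout is the minimal de-facto sumstats convention: SNP (rsID),
# CHR, POS (1-based, build left to the user) and P, with optional BETA, SE,
# A1, A2 and MAF columns for the MR path.  Rows failing validation are
# dropped and counted, never silently altered; duplicated rsIDs keep the
# smallest p-value (conservative for the rank-based FDR estimators).

default_column_map <- function() {
  c(snp = "SNP", chr = "CHR", pos = "POS", p = "P",
    beta = "BETA", se = "SE", a1 = "A1", a2 = "A2", maf = "MAF")
}

#' Read a GWAS summary-statistics table
#'
#' Auto-detects tab / whitespace / comma delimiters (header required),
#' validates each row, drops and counts invalid rows, resolves duplicated
#' rsIDs by keeping the smallest p-value, and returns records sorted by
#' (chromosome, position).
#'
#' Validation rules: p in (0, 1] (p = 0 is rejected — it would zero the cFDR
#' numerator; pre-clamp if needed), pos >= 1, chromosome in 1–22 or X, se > 0
#' wherever beta is present, maf in (0, 0.5] when present.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping the canonical field names
#'   (`snp`, `chr`, `pos`, `p`, and optionally `beta`, `se`, `a1`, `a2`,
#'   `maf`) to column names in the file. Defaults to the canonical
#'   SNP/CHR/POS/P layout.
#' @return A `sumstats` data frame (columns snp, chr, pos, p and any optional
#'   fields present) with attributes `n_input`, `n_dropped` (invalid rows)
#'   and `n_duplicates` (extra rows removed during rsID deduplication).
#' @export
read_sumstats <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  cmap <- default_column_map()
  cmap[names(column_map)] <- column_map
  raw <- data.table::fread(file = path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  required <- c("snp", "chr", "pos", "p")
  missing <- required[!cmap[required] %in% names(raw)]
  if (length(missing))
    format_error(sprintf("required column(s) missing from %s: %s",
                         path, paste(cmap[missing], collapse = ", ")))
  optional <- c("beta", "se", "a1", "a2", "maf")
  present_opt <- optional[cmap[optional] %in% names(raw)]

  df <- data.frame(
    snp = as.character(raw[[cmap[["snp"]]]]),
    chr = normalize_chr(raw[[cmap[["chr"]]]]),
    pos = suppressWarnings(as.numeric(raw[[cmap[["pos"]]]])),
    p = suppressWarnings(as.numeric(raw[[cmap[["p"]]]])),
    stringsAsFactors = FALSE)
  for (f in present_opt) {
    df[[f]] <- if (f %in% c("a1", "a2")) toupper(as.character(raw[[cmap[[f]]]]))
               else suppressWarnings(as.numeric(raw[[cmap[[f]]]]))
  }
  n_input <- nrow(df)

  ok <- !is.na(df$snp) & nzchar(df$snp) &
    !is.na(chr_rank(df$chr)) &
    is.finite(df$pos) & df$pos >= 1 &
    is.finite(df$p) & df$p > 0 & df$p <= 1
  if ("beta" %in% present_opt)
    ok <- ok & (is.na(df$beta) | (is.finite(df$beta) &
                                    "se" %in% present_opt &
                                    is.finite(df$se) & df$se > 0))
  if ("maf" %in% present_opt)
    ok <- ok & (is.na(df$maf) | (df$maf > 0 & df$maf <= 0.5))
  df <- df[ok, , drop = FALSE]
  n_dropped <- n_input - nrow(df)
  if (nrow(df) == 0L)
    empty_input_error(sprintf("no valid records remain after filtering %s", path))

  # dedup: keep minimum p per rsID (stable: ties keep the first occurrence)
  o <- order(df$snp, df$p)
  df <- df[o, , drop = FALSE]
  dup <- duplicated(df$snp)
  n_duplicates <- sum(dup)
  df <- df[!dup, , drop = FALSE]

  df <- df[genomic_order(df$chr, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"),
            n_input = n_input, n_dropped = n_dropped,
            n_duplicates = n_duplicates)
}

#' Write a summary-statistics table
#'
#' Tab-delimited, canonical header (SNP, CHR, POS, P and any optional columns
#' present); `read_sumstats(write_sumstats(x))` is the identity on the
#' retained columns. An empty collection yields a header-only file.
#'
#' @param records A `sumstats` data frame (or any data frame with at least
#'   snp/chr/pos/p columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  cmap <- default_column_map()
  fields <- intersect(names(cmap), names(records))
  out <- records[, fields, drop = FALSE]
  names(out) <- cmap[fields]
  # %.17g preserves doubles exactly through the text round-trip
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) format_error(sprintf("cannot write to %s", path))
  invisible(path)
}
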