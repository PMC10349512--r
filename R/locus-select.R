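# Threshold-based SNP selection, Manhattan-plot data and annotation joins.

cfdr_columns <- function() c("cfdr_a_given_b", "cfdr_b_given_a", "ccfdr")

#' Select SNPs below a significance threshold
#'
#' Rows whose value in the chosen cFDR/ccFDR column is strictly below the
#' threshold (the "cFDR < 0.01" convention), sorted by (chr, pos).
#'
#' @param table A `cfdr_table` data frame.
#' @param column One of `"cfdr_a_given_b"`, `"cfdr_b_given_a"`, `"ccfdr"`.
#' @param threshold Cutoff in \[0, 1).
#' @return A list of class `selection_report`: `selection` (selected rows),
#'   `n_selected`, `counts_per_chr`, `column`, `threshold`.
#' @export
select_by_threshold <- function(table, column, threshold) {
  if (!column %in% cfdr_columns() || !column %in% names(table))
    validation_error(sprintf("unknown selection column '%s'", column))
  stopifnot_scalar_number(threshold, "threshold")
  if (threshold < 0 || threshold >= 1)
    validation_error("'threshold' must be in [0, 1)")
  sel <- table[table[[column]] < threshold, , drop = FALSE]
  sel <- sel[genomic_order(sel$chr, sel$pos, sel$snp), , drop = FALSE]
  rownames(sel) <- NULL
  counts <- table(factor(sel$chr, levels = chr_levels()))
  counts <- counts[counts > 0]
  structure(list(selection = sel, n_selected = nrow(sel),
                 counts_per_chr = counts, column = column,
                 threshold = threshold),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection_report: %d SNP(s) with %s < %g\n",
              x$n_selected, x$column, x$threshold))
  invisible(x)
}

#' Manhattan-plot coordinates
#'
#' Cumulative genomic x-coordinate (chromosomes 1..22 then X laid end to end
#' with a one-unit gap) and y = -log10 of the chosen column, plus the
#' threshold reference line at -log10(threshold). Input row order is
#' irrelevant; output is in genome order.
#'
#' @param table A `cfdr_table` data frame.
#' @param column Which cFDR/ccFDR column to plot.
#' @param threshold Significance threshold for the reference line
#'   (default 0.01).
#' @return A data frame (snp, chr, pos, coord, y) with attribute
#'   `threshold_line` = -log10(threshold).
#' @export
manhattan_data <- function(table, column, threshold = 0.01) {
  if (nrow(table) == 0L) validation_error("'table' must be non-empty")
  if (!column %in% cfdr_columns() || !column %in% names(table))
    validation_error(sprintf("unknown column '%s'", column))
  tab <- table[genomic_order(table$chr, table$pos, table$snp), , drop = FALSE]
  offsets <- c(0, cumsum(vapply(chr_levels(), function(ch) {
    p <- tab$pos[tab$chr == ch]
    if (length(p)) max(p) + 1 else 0   # one-unit gap between chromosomes
  }, numeric(1))))
  names(offsets) <- c(chr_levels(), "end")
  out <- data.frame(snp = tab$snp, chr = tab$chr, pos = tab$pos,
                    coord = unname(offsets[tab$chr]) + tab$pos,
                    y = -log10(tab[[column]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold_line") <- -log10(threshold)
  out
}

#' Join an annotation table onto a selection report
#'
#' Left join on rsID: every selected row is kept, unmatched SNPs get NA
#' annotation, row count and order never change.
#'
#' @param report A `selection_report`.
#' @param annotation A data frame whose first column (or a column named
#'   `snp`/`SNP`) holds unique rsIDs; remaining columns are joined.
#' @return The report with annotation columns appended to `$selection`.
#' @export
annotate_selection <- function(report, annotation) {
  if (!inherits(report, "selection_report"))
    validation_error("'report' must be a selection_report")
  key <- intersect(c("snp", "SNP"), names(annotation))
  key <- if (length(key)) key[1] else names(annotation)[1]
  if (anyDuplicated(annotation[[key]]))
    validation_error("annotation table has duplicated rsID keys")
  idx <- match(report$selection$snp, annotation[[key]])
  extra <- annotation[idx, setdiff(names(annotation), key), drop = FALSE]
  rownames(extra) <- NULL
  cls <- class(report$selection)
  report$selection <- cbind(as.data.frame(report$selection), extra)
  class(report$selection) <- cls
  report
}

#' Write a selection report as a tab-delimited table
#'
#' @param report A `selection_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  write.table(report$selection, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a selection as BED (0-based half-open)
#'
#' Score is -log10 of the selection column, scaled by 100 and capped at 1000
#' (the BED score range).
#'
#' @param report A `selection_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_bed <- function(report, path) {
  sel <- report$selection
  score <- pmin(1000L, as.integer(round(100 * -log10(sel[[report$column]]))))
  bed <- data.frame(chrom = paste0("chr", sel$chr),
                    chromStart = format(sel$pos - 1, scientific = FALSE, trim = TRUE),
                    chromEnd = format(sel$pos, scientific = FALSE, trim = TRUE),
                    name = sel$snp, score = score)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
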