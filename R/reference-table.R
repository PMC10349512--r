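# Published reference results shipped with the package.

#' Published neuroticism / birth-weight pleiotropic SNP table
#'
#' The 62-SNP table of pleiotropic loci (ccFDR < 0.05) reported by a
#' published cross-trait conditional-FDR analysis of neuroticism and birth
#' weight, transcribed from the printed article table. Columns: SNP, CHR,
#' POS (positions as printed, some rounded to three significant figures),
#' the two conditional FDRs (`cFDR.BW`: birth weight given neuroticism,
#' `cFDR.NE`: neuroticism given birth weight), their conjunction `ccfdr`,
#' and the printed annotation columns (gene symbol, eQTL/meQTL counts,
#' functional class).
#'
#' Used by the test-suite as an exact in-data check of the conjunction rule
#' (`ccfdr = max(cFDR.BW, cFDR.NE)` on every row) and of threshold
#' bookkeeping (all 62 rows pass ccFDR < 0.05).
#'
#' @return A data frame with 62 rows.
#' @export
published_pleiotropy_table <- function() {
  path <- system.file("extdata", "neuroticism_bw_ccfdr_62snps.tsv",
                      package = "conjfdr", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", quote = "",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reference table recast as a `cfdr_table`
#'
#' Maps the published columns onto the package's `cfdr_table` layout
#' (trait A = neuroticism, trait B = birth weight, so
#' `cfdr_a_given_b` = cFDR.NE and `cfdr_b_given_a` = cFDR.BW), recomputing
#' the conjunction with [conjunction_ccfdr()].
#'
#' @return A `cfdr_table` data frame with 62 rows.
#' @export
published_pleiotropy_cfdr_table <- function() {
  tab <- published_pleiotropy_table()
  out <- data.frame(snp = tab$SNP, chr = as.character(tab$CHR), pos = tab$POS,
                    p_a = NA_real_, p_b = NA_real_,
                    cfdr_a_given_b = tab$cFDR.NE,
                    cfdr_b_given_a = tab$cFDR.BW,
                    stringsAsFactors = FALSE)
  out$ccfdr <- conjunction_ccfdr(out$cfdr_a_given_b, out$cfdr_b_given_a)
  class(out) <- c("cfdr_table", "data.frame")
  out
}
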