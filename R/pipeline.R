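# End-to-end orchestration: merge -> prune -> Q-Q -> cFDR/ccFDR -> selection
# -> MR, with per-stage row bookkeeping and byte-reproducible outputs.

#' Build and validate a pipeline run configuration
#'
#' Exactly one of `sumstats_a`/`sumstats_b` (paths to summary-statistics
#' files) or `synthetic` (a [mixture_spec()], optionally with `ld`) must
#' describe the trait pair. All thresholds default to the conventional
#' values: cFDR 0.01 with a stricter 0.001 tier, ccFDR 0.05, Q-Q strata
#' 1, 0.1, 0.01, 1e-3, 1e-4.
#'
#' @param sumstats_a,sumstats_b Paths to the two traits' summary statistics
#'   (both or neither).
#' @param synthetic A [mixture_spec()] used instead of real inputs.
#' @param ld An [ld_block_spec()] for the synthetic generator; enables the
#'   pruning stage on simulated data.
#' @param prune A [prune_config()], or NULL to skip pruning when no
#'   r-squared source is available.
#' @param r2_source Genotype matrix or LD pair list for pruning real inputs.
#' @param strata Q-Q stratum thresholds (descending).
#' @param cfdr_threshold,cfdr_threshold_strict,ccfdr_threshold Selection
#'   cutoffs.
#' @param mr_instruments Path to a harmonized instrument table, an
#'   `mr_instruments` data frame, or an [mr_sim_spec()]; NULL skips MR.
#' @param out_dir Output directory for the run.
#' @param seed Global seed fanned out to per-stage seeds by fixed offsets.
#' @return A validated `run_config` list.
#' @export
run_config <- function(sumstats_a = NULL, sumstats_b = NULL, synthetic = NULL,
                       ld = NULL, prune = prune_config(), r2_source = NULL,
                       strata = c(1, 0.1, 0.01, 0.001, 0.0001),
                       cfdr_threshold = 0.01, cfdr_threshold_strict = 0.001,
                       ccfdr_threshold = 0.05,
                       mr_instruments = NULL, out_dir = "conjfdr_run",
                       seed = 1L) {
  real <- !is.null(sumstats_a) || !is.null(sumstats_b)
  if (real && (is.null(sumstats_a) || is.null(sumstats_b)))
    config_error("both 'sumstats_a' and 'sumstats_b' are required for real inputs")
  if (real && !is.null(synthetic))
    config_error("supply either real sumstats paths or a synthetic spec, not both")
  if (!real && is.null(synthetic))
    config_error("one of {real sumstats paths, synthetic spec} is required")
  if (!is.null(synthetic) && !inherits(synthetic, "mixture_spec"))
    config_error("'synthetic' must be a mixture_spec")
  for (th in c(cfdr_threshold, cfdr_threshold_strict, ccfdr_threshold))
    if (!is.numeric(th) || th <= 0 || th >= 1)
      config_error("thresholds must lie in (0, 1)")
  structure(list(sumstats_a = sumstats_a, sumstats_b = sumstats_b,
                 synthetic = synthetic, ld = ld, prune = prune,
                 r2_source = r2_source, strata = strata,
                 cfdr_threshold = cfdr_threshold,
                 cfdr_threshold_strict = cfdr_threshold_strict,
                 ccfdr_threshold = ccfdr_threshold,
                 mr_instruments = mr_instruments,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  for (j in seq_along(df)) if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    conjfdr_abort(sprintf("pipeline stage '%s' failed: %s", name,
                          conditionMessage(e)), "conjfdr_stage_error")
  })
}

#' Run the full cross-trait pleiotropy pipeline
#'
#' Stages: obtain the two traits' statistics (read or simulate), merge on
#' rsID, LD-prune (when an r-squared source exists), stratified conditional
#' Q-Q curves, per-SNP cFDR/ccFDR, threshold selections (per-trait cFDR at
#' the default and strict cutoffs, ccFDR for pleiotropy), optional MR, and a
#' machine-readable run summary with per-stage row bookkeeping
#' (kept + dropped = input at every stage). Re-running with the same config
#' and seed reproduces every output file byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage outputs (`paired`,
#'   `pruned`, `qq`, `cfdr`, `selections`, `mr`, `summary`); files are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config_error("'config' must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed,
                  parameters = list(
                    strata = config$strata,
                    cfdr_threshold = config$cfdr_threshold,
                    cfdr_threshold_strict = config$cfdr_threshold_strict,
                    ccfdr_threshold = config$ccfdr_threshold))
  stages <- list()

  r2_source <- config$r2_source
  labels <- NULL
  if (!is.null(config$synthetic)) {
    sim <- run_stage("simulate", {
      spec <- config$synthetic
      spec$seed <- stage_seed(config$seed, 11L)
      simulate_paired_stats(spec, ld = config$ld)
    })
    paired <- sim$stats
    labels <- sim$labels
    if (is.null(r2_source)) r2_source <- sim$genotypes
    stages$merge <- list(input_a = nrow(paired), input_b = nrow(paired),
                         kept = nrow(paired), dropped = 0L)
  } else {
    a <- run_stage("read_a", read_sumstats(config$sumstats_a))
    b <- run_stage("read_b", read_sumstats(config$sumstats_b))
    paired <- run_stage("merge", merge_traits(a, b))
    stages$merge <- list(input_a = nrow(a), input_b = nrow(b),
                         kept = nrow(paired),
                         dropped = nrow(a) + nrow(b) - 2L * nrow(paired))
  }
  run_stage("write_merged", write_tsv(paired, file.path(config$out_dir, "merged.tsv")))

  if (!is.null(r2_source) && !is.null(config$prune)) {
    pr <- run_stage("prune", ld_prune(paired, r2_source, config$prune))
    pruned <- pr$kept
    stages$prune <- list(input = nrow(paired), kept = nrow(pruned),
                         dropped = nrow(pr$removed))
  } else {
    pruned <- paired
    stages$prune <- list(input = nrow(paired), kept = nrow(paired), dropped = 0L,
                         skipped = TRUE)
  }
  run_stage("write_pruned", write_tsv(pruned, file.path(config$out_dir, "pruned.tsv")))

  qq <- run_stage("qq", conditional_qq(pruned, config$strata))
  run_stage("write_qq", write_qq_curves(qq, file.path(config$out_dir, "qq_curves.tsv")))

  cfdr <- run_stage("cfdr", cfdr_table(pruned))
  run_stage("write_cfdr", write_tsv(cfdr, file.path(config$out_dir, "cfdr_table.tsv")))

  selections <- run_stage("select", {
    specs <- list(
      cfdr_a = list("cfdr_a_given_b", config$cfdr_threshold),
      cfdr_a_strict = list("cfdr_a_given_b", config$cfdr_threshold_strict),
      cfdr_b = list("cfdr_b_given_a", config$cfdr_threshold),
      cfdr_b_strict = list("cfdr_b_given_a", config$cfdr_threshold_strict),
      pleiotropic = list("ccfdr", config$ccfdr_threshold))
    out <- lapply(specs, function(s) select_by_threshold(cfdr, s[[1]], s[[2]]))
    for (nm in names(out))
      write_selection_report(out[[nm]],
                             file.path(config$out_dir, paste0("selection_", nm, ".tsv")))
    out
  })
  stages$selection <- lapply(selections, function(s)
    list(column = s$column, threshold = s$threshold, n_selected = s$n_selected))

  mr_res <- NULL
  if (!is.null(config$mr_instruments)) {
    mr_res <- run_stage("mr", {
      mi <- config$mr_instruments
      if (inherits(mi, "mr_sim_spec")) {
        mi$seed <- stage_seed(config$seed, 23L)
        mi <- simulate_mr_instruments(mi)
      } else if (is.character(mi)) {
        mi <- read_mr_instruments(mi)
      }
      mr_all(mi, seed = stage_seed(config$seed, 31L))
    })
    run_stage("write_mr",
              write_mr_results(mr_res, file.path(config$out_dir, "mr_results.tsv")))
    stages$mr <- list(n_instruments = mr_res$results[[1]]$n_snp)
  }

  summary$stages <- stages
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paired = paired, pruned = pruned, qq = qq, cfdr = cfdr,
                 selections = selections, labels = labels, mr = mr_res,
                 summary = summary))
}

#' Read a tab-delimited MR instrument table
#'
#' Expected columns: SNP, beta_exp, se_exp, beta_out, se_out (alleles
#' optional; the table is assumed pre-harmonized when alleles are absent).
#'
#' @param path Input path.
#' @return An `mr_instruments` data frame.
#' @export
read_mr_instruments <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- data.table::fread(file = path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  names(df)[names(df) %in% c("SNP", "snp")] <- "snp"
  req <- c("beta_exp", "se_exp", "beta_out", "se_out")
  missing <- setdiff(req, names(df))
  if (length(missing))
    format_error(sprintf("instrument table lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  class(df) <- c("mr_instruments", "data.frame")
  df
}
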