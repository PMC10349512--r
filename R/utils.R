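# Shared validation helpers and condition constructors.

conjfdr_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "conjfdr_error")))
}

#' @noRd
validation_error <- function(message) conjfdr_abort(message, "conjfdr_validation_error")
format_error <- function(message) conjfdr_abort(message, "conjfdr_format_error")
empty_input_error <- function(message) conjfdr_abort(message, "conjfdr_empty_error")
config_error <- function(message) conjfdr_abort(message, "conjfdr_config_error")

# Chromosome labels in genome plotting order: autosomes then X.
chr_levels <- function() c(as.character(1:22), "X")

# Integer sort key for chromosome labels; NA for anything unrecognized.
chr_rank <- function(chr) {
  chr <- sub("^chr", "", as.character(chr), ignore.case = TRUE)
  chr[toupper(chr) == "X"] <- "X"
  match(chr, chr_levels())
}

normalize_chr <- function(chr) {
  chr <- sub("^chr", "", as.character(chr), ignore.case = TRUE)
  ifelse(toupper(chr) == "X", "X", chr)
}

# (chr, pos) ordering used everywhere downstream; the optional tie key keeps
# the ordering deterministic when positions collide (e.g. display-rounded
# coordinates).
genomic_order <- function(chr, pos, tie = NULL) {
  if (is.null(tie)) order(chr_rank(chr), pos)
  else order(chr_rank(chr), pos, tie)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(sprintf("'%s' must be a single finite number", name))
}

check_prob_vector <- function(p, name) {
  if (!is.numeric(p)) validation_error(sprintf("'%s' must be numeric", name))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    validation_error(sprintf("'%s' must lie in (0, 1]", name))
  invisible(p)
}

# Deterministic per-stage seeds fanned out from one global seed.
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
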