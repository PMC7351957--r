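# Internal helpers shared across modules.

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "phylostage_format_error")
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "phylostage_config_error")
}

stop_undefined_cor <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "phylostage_undefined_cor")
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_config("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_seed <- function(seed) {
  seed <- check_count(seed, "seed", min = 0L)
  if (seed > .Machine$integer.max - 10L) stop_config("`seed` too large")
  seed
}

# Stage order convention: within each species, the order of first appearance
# in the table (which read_expression_table() ties to file column order and
# the simulator ties to developmental order).
stage_order <- function(tbl) {
  sp <- unique(tbl$species)
  setNames(lapply(sp, function(s) unique(tbl$stage[tbl$species == s])), sp)
}

check_expr_tbl <- function(tbl, arg = "data") {
  need <- c("species", "group_id", "stage", "tpm")
  if (!is.data.frame(tbl) || !all(need %in% names(tbl))) {
    stop_format(
      "`%s` must be a data frame with columns %s",
      arg, paste(sprintf("'%s'", need), collapse = ", ")
    )
  }
  if (any(!is.finite(tbl$tpm)) || any(tbl$tpm < 0)) {
    stop_format("expression values must be finite and >= 0")
  }
  invisible(tbl)
}

# Average ranks, centred and scaled so that crossprod() of two such matrices
# is the Spearman correlation matrix of the original columns. Columns with
# zero rank variance (constant profiles) come back as all-NaN.
scale_ranks <- function(x) {
  col_ranks_scaled(x)
}
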