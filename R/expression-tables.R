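#' Read a per-species developmental expression table
#'
#' Parses a tab-separated expression table whose first column is `group_id`
#' (ortholog-group identifiers) and whose remaining columns are named
#' `stage:replicate` (for example `gastrula:r1`). Values are TPM-scale
#' relative expression levels of ortholog groups. The column order of the
#' file defines the developmental stage order and is preserved.
#'
#' @param path Path to a TSV file.
#' @param species Species label attached to every row.
#' @return A tibble in long format with columns `species`, `group_id`,
#'   `stage`, `replicate`, `tpm`. Stages appear in file column order.
#' @details A missing group in a species is represented by the group being
#'   absent from the file, never by blank cells; ragged rows, duplicated
#'   group ids and negative values are format errors.
#' @seealso [write_expression_table()], [restrict_to_shared_groups()]
#' @export
read_expression_table <- function(path, species) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  tbl <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    group_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0L) {
    stop_format(
      "malformed expression table %s (first problem: row %d, %s)",
      path, probs$row[1], probs$expected[1]
    )
  }
  if (names(tbl)[1] != "group_id") {
    stop_format("first column of %s must be 'group_id'", path)
  }
  if (anyDuplicated(tbl$group_id)) {
    stop_format(
      "duplicate group id(s) in %s: %s", path,
      paste(unique(tbl$group_id[duplicated(tbl$group_id)]), collapse = ", ")
    )
  }
  cols <- names(tbl)[-1]
  if (!all(grepl(":", cols, fixed = TRUE))) {
    stop_format("column names of %s must be 'stage:replicate'", path)
  }
  long <- tidyr::pivot_longer(tbl, -"group_id",
    names_to = c("stage", "replicate"), names_sep = ":", values_to = "tpm"
  )
  if (anyNA(long$tpm)) stop_format("missing cells in %s", path)
  if (any(long$tpm < 0)) stop_format("negative expression value in %s", path)
  out <- tibble(
    species = species, group_id = long$group_id,
    stage = long$stage, replicate = long$replicate, tpm = long$tpm
  )
  # stable order: group as in file, stage/replicate in column order
  out[order(match(out$group_id, tbl$group_id)), , drop = FALSE]
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_table()] for a single species: writes a wide
#' table with `group_id` first and one `stage:replicate` column per
#' measurement, stages in their stored order.
#'
#' @param tbl Long-format expression tibble for one species.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(tbl, path) {
  check_expr_tbl(tbl)
  if (length(unique(tbl$species)) != 1L) {
    stop_config("write_expression_table() expects a single species")
  }
  stages <- stage_order(tbl)[[1]]
  tbl <- mutate(tbl, column = paste(.data$stage, .data$replicate, sep = ":"))
  col_order <- unique(tbl$column[order(match(tbl$stage, stages))])
  wide <- tidyr::pivot_wider(
    select(tbl, "group_id", "column", "tpm"),
    names_from = "column", values_from = "tpm"
  )
  wide <- wide[, c("group_id", col_order)]
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Restrict expression tables to ortholog groups shared by all species
#'
#' A group enters the cross-species comparison only if it is present in
#' every species of the taxon set under analysis (set intersection, the
#' strictest reproducible membership rule). Groups are re-ordered into a
#' canonical lexicographic shared order so that profiles of different
#' species align element-wise.
#'
#' @param data Long-format expression tibble holding at least two species.
#' @return The filtered tibble; every species retains exactly the shared
#'   groups, rows ordered by species, then group id, then stage order.
#' @export
restrict_to_shared_groups <- function(data) {
  check_expr_tbl(data)
  sets <- split(data$group_id, data$species)
  sets <- lapply(sets, unique)
  if (length(sets) < 2L) {
    stop_config("restrict_to_shared_groups() needs at least two species")
  }
  shared <- sort(Reduce(intersect, sets))
  if (length(shared) == 0L) {
    counts <- paste(sprintf("%s (%d groups)", names(sets), lengths(sets)),
      collapse = ", "
    )
    stop_config("no ortholog group shared by all species: %s", counts)
  }
  stages <- stage_order(data)
  out <- filter(data, .data$group_id %in% shared)
  ord <- order(
    out$species,
    match(out$group_id, shared),
    unlist(Map(function(sp, st) match(st, stages[[sp]]), out$species, out$stage),
      use.names = FALSE
    ),
    out$replicate
  )
  out[ord, , drop = FALSE]
}

#' Resample biological-replicate-included (BRI) expression tables
#'
#' Builds `B` resampled table layouts by randomly picking one biological
#' replicate for each developmental stage in each species, independently
#' across stages, species and tables (sampling with replacement across
#' tables). The full set of `B` layouts quantifies replicate-level
#' uncertainty of downstream stage-conservation scores.
#'
#' @param data Long-format expression tibble (any number of species).
#' @param B Number of resampled tables (the field default is 100).
#' @param seed Integer seed; the same seed reproduces the same choices.
#' @return A provenance tibble with columns `table` (1..B), `species`,
#'   `stage`, `replicate`: exactly one chosen replicate per
#'   (table, species, stage).
#' @seealso [bri_table()] materialises one layout as an expression tibble.
#' @export
bri_resample <- function(data, B = 100, seed = 1) {
  check_expr_tbl(data)
  B <- check_count(B, "B")
  seed <- check_seed(seed)
  stages <- stage_order(data)
  slots <- distinct(data, .data$species, .data$stage, .data$replicate)
  slots <- slots[order(
    slots$species,
    unlist(Map(function(sp, st) match(st, stages[[sp]]), slots$species, slots$stage),
      use.names = FALSE
    ),
    slots$replicate
  ), , drop = FALSE]
  keys <- split(
    slots$replicate,
    factor(
      paste(slots$species, slots$stage, sep = "\r"),
      levels = unique(paste(slots$species, slots$stage, sep = "\r"))
    )
  )
  if (any(lengths(keys) == 0L)) stop_config("a stage has zero replicates")
  picks <- withr::with_seed(seed, lapply(keys, function(r) {
    if (length(r) == 1L) rep(r, B) else sample(r, B, replace = TRUE)
  }))
  meta <- unique(slots[, c("species", "stage")])
  tibble(
    table = rep(seq_len(B), times = nrow(meta)),
    species = rep(meta$species, each = B),
    stage = rep(meta$stage, each = B),
    replicate = unlist(picks, use.names = FALSE)
  )
}

#' Materialise one BRI table
#'
#' Joins a single layout of a [bri_resample()] provenance tibble back onto
#' the parent expression data, yielding a table with exactly one replicate
#' per (species, stage).
#'
#' @param data The parent long-format expression tibble.
#' @param provenance Tibble returned by [bri_resample()].
#' @param index Which table (1..B) to materialise.
#' @return Long-format expression tibble with one value per
#'   (species, group, stage); the `replicate` column records the choice.
#' @export
bri_table <- function(data, provenance, index = 1) {
  index <- check_count(index, "index")
  choice <- filter(provenance, .data$table == index)
  if (nrow(choice) == 0L) stop_config("no table with index %d", index)
  out <- inner_join(data, select(choice, -"table"),
    by = c("species", "stage", "replicate")
  )
  out[order(match(
    paste(out$species, out$group_id, out$stage, out$replicate),
    paste(data$species, data$group_id, data$stage, data$replicate)
  )), , drop = FALSE]
}

#' Average replicates into per-stage expression profiles
#'
#' @param data Long-format expression tibble.
#' @return Tibble with one `tpm` value per (species, group, stage): the
#'   arithmetic mean over replicates. Stage order is preserved.
#' @export
aggregate_replicates <- function(data) {
  check_expr_tbl(data)
  stages <- stage_order(data)
  out <- summarise(
    group_by(data, .data$species, .data$group_id, .data$stage),
    tpm = mean(.data$tpm), .groups = "drop"
  )
  ord <- order(
    out$species, out$group_id,
    unlist(Map(function(sp, st) match(st, stages[[sp]]), out$species, out$stage),
      use.names = FALSE
    )
  )
  out[ord, , drop = FALSE]
}
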