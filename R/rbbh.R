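# Reciprocal-best-hit one-to-one orthology from tabular similarity hits,
# and supergene concatenation of pre-aligned ortholog sets.

HIT_COLUMNS <- c(
  "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' Read a 12-column tabular similarity hit table
#'
#' Parses the standard 12-column tab-separated hit layout (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) as produced by sequence similarity searches in tabular output
#' mode. Malformed rows are rejected with their line numbers.
#'
#' @param path Path to a headerless TSV.
#' @return Tibble with the 12 standard columns.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    stop_format(
      "malformed hit table %s: expected 12 tab-separated columns (bad line(s): %s)",
      path, paste(head(bad, 5L), collapse = ", ")
    )
  }
  tbl <- utils::read.delim(path,
    header = FALSE, sep = "\t", quote = "", comment.char = "",
    col.names = HIT_COLUMNS, stringsAsFactors = FALSE,
    colClasses = c(
      "character", "character", "numeric", "integer", "integer", "integer",
      "integer", "integer", "integer", "integer", "numeric", "numeric"
    )
  )
  tbl <- as_tibble(tbl)
  if (anyNA(tbl)) {
    stop_format(
      "malformed hit table %s: unparseable field(s) on line(s) %s", path,
      paste(head(which(rowSums(is.na(tbl)) > 0), 5L), collapse = ", ")
    )
  }
  validate_hits(tbl, path)
  tbl
}

validate_hits <- function(hits, what = "hit table") {
  if (any(hits$pident < 0 | hits$pident > 100)) {
    stop_format("%s: pident outside [0, 100]", what)
  }
  if (any(hits$length < 1)) stop_format("%s: alignment length < 1", what)
  if (any(hits$evalue < 0)) stop_format("%s: negative e-value", what)
  invisible(hits)
}

#' Write a hit table to a headerless 12-column TSV
#'
#' @param hits Tibble with the 12 standard columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  if (!all(HIT_COLUMNS %in% names(hits))) {
    stop_format("`hits` must carry the 12 standard columns")
  }
  readr::write_tsv(hits[, HIT_COLUMNS], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Best hit per query
#'
#' Filters hits by e-value and keeps, for every query, the single best
#' subject: maximum bitscore, ties broken by minimum e-value, then by the
#' lexicographically smallest subject id. Multiple HSPs of the same
#' query-subject pair are collapsed to their best-scoring row first.
#' Self-hits (query equal to subject) are not expected and are dropped
#' with a warning. Queries with no passing hit are absent from the result.
#'
#' @param hits Hit tibble (from [read_hit_table()] or equivalent).
#' @param evalue_max E-value cutoff (default 1e-5).
#' @return Tibble with columns `qseqid`, `sseqid`, one row per query,
#'   sorted by query id.
#' @export
best_hits <- function(hits, evalue_max = 1e-5) {
  if (!all(c("qseqid", "sseqid", "evalue", "bitscore") %in% names(hits))) {
    stop_format("`hits` must carry qseqid, sseqid, evalue, bitscore")
  }
  self <- hits$qseqid == hits$sseqid
  if (any(self)) {
    warn(sprintf("%d self-hit(s) ignored", sum(self)))
    hits <- hits[!self, , drop = FALSE]
  }
  hits <- filter(hits, .data$evalue <= evalue_max)
  if (nrow(hits) == 0L) {
    return(tibble(qseqid = character(), sseqid = character()))
  }
  # best HSP per query-subject pair, then best subject per query
  hits <- hits[order(
    hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid
  ), , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("qseqid", "sseqid")]), , drop = FALSE]
  hits <- hits[order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid), ,
    drop = FALSE
  ]
  best <- hits[!duplicated(hits$qseqid), c("qseqid", "sseqid")]
  as_tibble(best[order(best$qseqid), , drop = FALSE])
}

#' Reciprocal best hits between two species
#'
#' A pair `(a, b)` is reciprocal-best iff `a`'s best hit in the other
#' species is `b` and `b`'s best hit back is `a`. Such pairs are the
#' standard one-to-one orthology proxy.
#'
#' @param ab Best-hit map (tibble qseqid, sseqid) from species A to B.
#' @param ba Best-hit map from species B to A.
#' @return Tibble with columns `gene_a`, `gene_b`, sorted by `gene_a`.
#'   Swapping the two input maps transposes every pair.
#' @export
reciprocal_best_pairs <- function(ab, ba) {
  m <- inner_join(
    rename(ab, gene_a = "qseqid", gene_b = "sseqid"),
    rename(ba, gene_b = "qseqid", back = "sseqid"),
    by = "gene_b"
  )
  out <- select(filter(m, .data$gene_a == .data$back), "gene_a", "gene_b")
  out[order(out$gene_a), , drop = FALSE]
}

#' Reference-anchored one-to-one ortholog sets
#'
#' Joins per-species reciprocal-best-hit pair lists, all anchored on one
#' reference species: a set is emitted iff the reference gene has an RBBH
#' partner in every other species.
#'
#' @param pair_maps Named list (one entry per non-reference species) of
#'   pair tibbles with columns `gene_a` (reference gene) and `gene_b`.
#' @param reference Label of the reference species (used to name the
#'   output column).
#' @param species Optional character vector of the non-reference species
#'   that must be covered; a species without a pair map is an error.
#' @return Tibble with one column per species — the reference first,
#'   named `reference` — and one row per complete ortholog set, sorted by
#'   reference gene id.
#' @export
anchored_one_to_one <- function(pair_maps, reference = "reference",
                                species = NULL) {
  if (is.null(names(pair_maps)) || any(names(pair_maps) == "")) {
    stop_config("`pair_maps` must be a named list (species -> pair tibble)")
  }
  if (!is.null(species)) {
    missing <- setdiff(species, names(pair_maps))
    if (length(missing) > 0L) {
      stop_config(
        "species missing a pair map: %s", paste(missing, collapse = ", ")
      )
    }
  }
  for (sp in names(pair_maps)) {
    pm <- pair_maps[[sp]]
    if (!all(c("gene_a", "gene_b") %in% names(pm))) {
      stop_config("pair map for '%s' lacks gene_a/gene_b columns", sp)
    }
  }
  out <- NULL
  for (sp in names(pair_maps)) {
    pm <- rename(pair_maps[[sp]][, c("gene_a", "gene_b")], !!sp := "gene_b")
    out <- if (is.null(out)) pm else inner_join(out, pm, by = "gene_a")
  }
  out <- rename(out, !!reference := "gene_a")
  out[order(out[[reference]]), , drop = FALSE]
}

#' Concatenate aligned ortholog sets into a supergene matrix
#'
#' Per-species concatenation of pre-aligned ortholog-set sequences in a
#' fixed set order ("in the same gene order"), with a partition table of
#' half-open column intervals per set. Within a set all species sequences
#' must have the same aligned length and every species must be present
#' (one-to-one sets are complete by construction; no gap-filling is
#' performed).
#'
#' @param aligned Tibble with columns `set_id`, `species`, `seq` (aligned
#'   sequences, one row per set x species).
#' @param order Character vector of set ids fixing the concatenation
#'   order; defaults to the sets' order of first appearance.
#' @return List with `supermatrix` (tibble species, seq; total length =
#'   sum of set lengths) and `partitions` (tibble set_id, start, end with
#'   0-based half-open intervals).
#' @export
concatenate_supergene <- function(aligned, order = NULL) {
  need <- c("set_id", "species", "seq")
  if (!is.data.frame(aligned) || !all(need %in% names(aligned))) {
    stop_format("`aligned` needs columns set_id, species, seq")
  }
  order <- order %||% unique(aligned$set_id)
  if (!setequal(order, unique(aligned$set_id))) {
    stop_config("`order` must list exactly the set ids present")
  }
  species <- unique(aligned$species)
  widths <- integer(length(order))
  chunks <- vector("list", length(order))
  for (i in seq_along(order)) {
    d <- aligned[aligned$set_id == order[i], , drop = FALSE]
    missing <- setdiff(species, d$species)
    if (length(missing) > 0L) {
      stop_config(
        "set '%s' is missing species: %s", order[i],
        paste(missing, collapse = ", ")
      )
    }
    w <- unique(nchar(d$seq))
    if (length(w) != 1L) {
      stop_config("set '%s' has unequal aligned lengths", order[i])
    }
    widths[i] <- w
    chunks[[i]] <- setNames(d$seq, d$species)[species]
  }
  ends <- cumsum(widths)
  starts <- ends - widths
  supermatrix <- tibble(
    species = species,
    seq = unname(vapply(
      species,
      function(sp) paste(vapply(chunks, `[[`, "", sp), collapse = ""),
      ""
    ))
  )
  list(
    supermatrix = supermatrix,
    partitions = tibble(set_id = order, start = starts, end = ends)
  )
}

#' Write a supergene matrix as FASTA and its partitions as text
#'
#' @param supergene Result of [concatenate_supergene()].
#' @param fasta_path Output FASTA path.
#' @param partition_path Optional partition file path; lines use the
#'   conventional `"name = start-end"` style with 1-based inclusive
#'   coordinates.
#' @return `fasta_path`, invisibly.
#' @export
write_supergene <- function(supergene, fasta_path, partition_path = NULL) {
  aa <- Biostrings::AAStringSet(
    setNames(supergene$supermatrix$seq, supergene$supermatrix$species)
  )
  Biostrings::writeXStringSet(aa, fasta_path)
  if (!is.null(partition_path)) {
    p <- supergene$partitions
    writeLines(
      sprintf("%s = %d-%d", p$set_id, p$start + 1L, p$end),
      partition_path
    )
  }
  invisible(fasta_path)
}
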