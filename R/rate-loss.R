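# Tajima's relative rate test on aligned triplets, and the lineage
# gene-loss presence screen.

split_sites <- function(x, name) {
  if (is.character(x) && length(x) == 1L) {
    return(strsplit(toupper(x), "")[[1]])
  }
  if (is.character(x)) {
    return(toupper(x))
  }
  stop_config("`%s` must be a sequence string or a character vector of residues", name)
}

#' Tajima's relative rate test
#'
#' Count-based test of equal evolutionary rates in two lineages A and B
#' relative to an outgroup O, on an aligned sequence triplet. Sites with a
#' gap or ambiguity symbol in any of the three sequences are skipped.
#' `m_a` counts sites where A alone differs from the outgroup state
#' (A != O and B == O), `m_b` the converse; sites where all three differ,
#' or where A and B share a state different from O, contribute to
#' neither. Under rate equality `chi2 = (m_a - m_b)^2 / (m_a + m_b)` is
#' asymptotically chi-square with 1 degree of freedom (no continuity
#' correction, no multiple-hit correction — the simple count-based form).
#'
#' @param seq_a,seq_b,seq_o Aligned sequences (single strings or character
#'   vectors of residues) of equal length: the two test lineages and the
#'   outgroup.
#' @param ambiguous Symbols treated as gap/ambiguity (default suits
#'   protein alignments; add `"N"` for nucleotides).
#' @return A `tajima_rrt` object with `m_a`, `m_b`, `chi2`, `df`,
#'   `p_value`, `n_sites_used` and `undefined` (TRUE when
#'   `m_a + m_b == 0`, in which case the test is flagged undefined and no
#'   p-value is reported). `tidy()` method available.
#' @examples
#' tajima_rrt("AAAAAAAA", "AAAAAACC", "AAAAAAAA") # m_b = 2
#' @export
tajima_rrt <- function(seq_a, seq_b, seq_o,
                       ambiguous = c("-", ".", "?", "*", "X")) {
  a <- split_sites(seq_a, "seq_a")
  b <- split_sites(seq_b, "seq_b")
  o <- split_sites(seq_o, "seq_o")
  if (length(a) != length(b) || length(a) != length(o)) {
    stop_config(
      "aligned sequences must have equal length (%d, %d, %d)",
      length(a), length(b), length(o)
    )
  }
  ambiguous <- toupper(ambiguous)
  use <- !(a %in% ambiguous | b %in% ambiguous | o %in% ambiguous)
  a <- a[use]
  b <- b[use]
  o <- o[use]
  m_a <- sum(a != o & b == o)
  m_b <- sum(b != o & a == o)
  if (m_a + m_b == 0L) {
    res <- list(
      m_a = m_a, m_b = m_b, chi2 = NA_real_, df = 1L,
      p_value = NA_real_, n_sites_used = length(a), undefined = TRUE
    )
  } else {
    chi2 <- (m_a - m_b)^2 / (m_a + m_b)
    res <- list(
      m_a = m_a, m_b = m_b, chi2 = chi2, df = 1L,
      p_value = pchisq(chi2, 1L, lower.tail = FALSE),
      n_sites_used = length(a), undefined = FALSE
    )
  }
  structure(res, class = "tajima_rrt")
}

#' @export
print.tajima_rrt <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf(
      "Tajima relative rate test: undefined (no lineage-unique sites among %d used)\n",
      x$n_sites_used
    ))
  } else {
    cat(sprintf(
      "Tajima relative rate test: m_a = %d, m_b = %d, chi2 = %.4g, df = 1, p = %.4g (%d sites)\n",
      x$m_a, x$m_b, x$chi2, x$p_value, x$n_sites_used
    ))
  }
  invisible(x)
}

#' @rdname tajima_rrt
#' @param x A `tajima_rrt` object.
#' @param ... Unused.
#' @export
tidy.tajima_rrt <- function(x, ...) {
  tibble(
    m_a = x$m_a, m_b = x$m_b, chi2 = x$chi2, df = x$df,
    p_value = x$p_value, n_sites_used = x$n_sites_used,
    undefined = x$undefined
  )
}

#' Presence call from similarity hits
#'
#' A query gene is called present in a target gene set iff it has at
#' least one hit with identity strictly above `id_min` percent and an
#' alignment ratio (100 * aligned length / query length) strictly above
#' `ratio_min` percent. Genes of `query_lengths` without any qualifying
#' hit are called absent.
#'
#' @param hits Hit tibble (columns qseqid, pident, length at least).
#' @param query_lengths Named numeric vector or tibble
#'   (`gene_id`, `length`) giving each query's sequence length; must
#'   cover every query appearing in `hits`.
#' @param id_min,ratio_min Percent thresholds (strict `>`), defaults 50
#'   and 30.
#' @return Tibble with columns `gene_id`, `present` for every gene of
#'   `query_lengths`.
#' @export
presence_call <- function(hits, query_lengths, id_min = 50, ratio_min = 30) {
  if (is.data.frame(query_lengths)) {
    query_lengths <- setNames(query_lengths$length, query_lengths$gene_id)
  }
  missing <- setdiff(unique(hits$qseqid), names(query_lengths))
  if (length(missing) > 0L) {
    stop_config(
      "query_lengths missing for: %s",
      paste(head(missing, 5L), collapse = ", ")
    )
  }
  qlen <- query_lengths[hits$qseqid]
  ok <- hits$pident > id_min & 100 * hits$length / qlen > ratio_min
  present_genes <- unique(hits$qseqid[ok])
  tibble(
    gene_id = names(query_lengths),
    present = names(query_lengths) %in% present_genes
  )
}

#' Lineage gene-loss screen
#'
#' An anchor gene is reported lost in the ingroup lineage iff it is
#' present in at least one comparison-set species and absent from every
#' ingroup species. Genes absent everywhere are not reported (they fail
#' the comparison-set condition).
#'
#' @param presence Long tibble with columns `gene_id`, `species`,
#'   `present` (logical) — rectangular over genes x species.
#' @param ingroup Species whose joint absence defines loss (e.g. the
#'   echinoderm-like set).
#' @param compare Species in which presence is required (e.g. the
#'   chordate-like set).
#' @return Tibble with column `gene_id`: the lost genes, sorted.
#' @export
lineage_loss_screen <- function(presence, ingroup, compare) {
  need <- c("gene_id", "species", "present")
  if (!is.data.frame(presence) || !all(need %in% names(presence))) {
    stop_format("`presence` needs columns gene_id, species, present")
  }
  if (length(ingroup) == 0L || length(compare) == 0L) {
    stop_config("both species sets must be non-empty")
  }
  missing <- setdiff(c(ingroup, compare), unique(presence$species))
  if (length(missing) > 0L) {
    stop_config("species not in presence matrix: %s", paste(missing, collapse = ", "))
  }
  per_gene <- summarise(
    group_by(filter(presence, .data$species %in% c(ingroup, compare)), .data$gene_id),
    in_compare = any(.data$present[.data$species %in% compare]),
    in_ingroup = any(.data$present[.data$species %in% ingroup]),
    .groups = "drop"
  )
  lost <- filter(per_gene, .data$in_compare & !.data$in_ingroup)
  tibble(gene_id = sort(lost$gene_id))
}
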