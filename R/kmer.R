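# K-mer-histogram genome-size estimation: canonical k-mer counting from
# FASTQ, error-valley / coverage-peak detection, and the size formula
# genome size (bp) = k-mer number / k-mer depth at the coverage peak.

# Minimal validating FASTQ reader: returns the sequence lines. Kept
# in-package because the error contract reports the offending record
# index, which a generic parser does not surface.
read_fastq_seqs <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop_format(
      "malformed FASTQ %s: %d lines is not a multiple of 4 (record %d truncated)",
      path, length(lines), length(lines) %/% 4L + 1L
    )
  }
  n <- length(lines) %/% 4L
  heads <- lines[seq(1L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+") |
    nchar(seqs) != nchar(quals))
  if (length(bad) > 0L) {
    stop_format("malformed FASTQ %s: record %d invalid", path, bad[1])
  }
  toupper(seqs)
}

#' Count canonical k-mers from reads
#'
#' Tallies canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement, making counting strand-neutral) across all reads
#' and returns the depth histogram: for each depth `d`, the number of
#' distinct canonical k-mers observed exactly `d` times. K-mers
#' containing non-ACGT characters are skipped; reads shorter than `k` are
#' skipped and counted.
#'
#' @param reads A FASTQ file path, the result of [simulate_reads()], or a
#'   character vector of read sequences.
#' @param k Odd k-mer size >= 3 (default 17, the standard survey size; an
#'   odd k makes no k-mer its own reverse complement).
#' @return A `kmer_histogram` object: a list with `histogram` (tibble
#'   `depth`, `n_kmers`), `k`, `total_kmers` (sum of depth * count,
#'   verified against the token count on ingest), `n_distinct` and
#'   `n_reads_skipped`.
#' @export
count_kmers <- function(reads, k = 17) {
  k <- check_count(k, "k", min = 3L)
  if (k %% 2L == 0L) stop_config("`k` must be odd")
  if (is.list(reads) && !is.null(reads$reads)) reads <- reads$reads$seq
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq_seqs(reads)
  }
  if (!is.character(reads)) stop_config("`reads` must be sequences or a FASTQ path")
  reads <- toupper(reads)
  len <- nchar(reads)
  skipped <- sum(len < k)
  reads <- reads[len >= k]
  len <- len[len >= k]
  if (length(reads) == 0L) stop_config("no read is >= k long")
  max_off <- max(len) - k + 1L
  tokens <- vector("list", max_off)
  for (i in seq_len(max_off)) {
    keep <- len >= i + k - 1L
    tokens[[i]] <- substring(reads[keep], i, i + k - 1L)
  }
  tokens <- unlist(tokens, use.names = FALSE)
  tokens <- tokens[!grepl("[^ACGT]", tokens)]
  if (length(tokens) == 0L) stop_config("no valid ACGT k-mers found")
  rc <- revcomp(tokens)
  canon <- ifelse(tokens <= rc, tokens, rc)
  depth_per_kmer <- rle(sort(canon, method = "radix"))$lengths
  depth_tab <- tabulate(depth_per_kmer)
  hist <- tibble(depth = which(depth_tab > 0L), n_kmers = depth_tab[depth_tab > 0L])
  total <- sum(as.numeric(hist$depth) * hist$n_kmers)
  stopifnot(total == length(tokens)) # ingest invariant
  structure(
    list(
      histogram = hist, k = k, total_kmers = total,
      n_distinct = sum(hist$n_kmers), n_reads_skipped = skipped
    ),
    class = "kmer_histogram"
  )
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf(
    "k-mer histogram (k = %d): %g tokens, %g distinct canonical k-mers, depth 1..%d\n",
    x$k, x$total_kmers, x$n_distinct, max(x$histogram$depth)
  ))
  invisible(x)
}

as_kmer_histogram <- function(x) {
  if (inherits(x, "kmer_histogram")) {
    return(x)
  }
  if (is.data.frame(x) && all(c("depth", "n_kmers") %in% names(x))) {
    x <- x[order(x$depth), , drop = FALSE]
    return(structure(
      list(
        histogram = as_tibble(x), k = NA_integer_,
        total_kmers = sum(as.numeric(x$depth) * x$n_kmers),
        n_distinct = sum(x$n_kmers), n_reads_skipped = NA_integer_
      ),
      class = "kmer_histogram"
    ))
  }
  stop_config("`hist` must be a kmer_histogram or a depth/n_kmers data frame")
}

# dense counts over depth 1..max (absent depths are zero)
dense_counts <- function(hist) {
  h <- hist$histogram
  counts <- numeric(max(h$depth))
  counts[h$depth] <- h$n_kmers
  counts
}

#' Locate the error valley and the coverage peak of a k-mer histogram
#'
#' Sequencing errors produce a mass of low-depth k-mers whose count
#' decreases with depth, while true genomic k-mers pile up around the
#' sequencing depth. The valley is the first depth `d >= 1` with
#' `count(d) < count(d + 1)` (the boundary of the error peak); the
#' coverage peak is the depth with the highest count above the valley
#' (ties resolved to the smaller depth). A histogram that never rises
#' again has no coverage peak and is an error.
#'
#' @param hist A `kmer_histogram` or a tibble with `depth`, `n_kmers`.
#' @return A list with `valley_depth` and `peak_depth`.
#' @examples
#' h <- tibble::tibble(depth = 1:6, n_kmers = c(1000, 100, 50, 80, 200, 120))
#' find_error_valley_and_peak(h) # valley 3, peak 5
#' @export
find_error_valley_and_peak <- function(hist) {
  hist <- as_kmer_histogram(hist)
  if (nrow(hist$histogram) < 2L) {
    stop_config("no diploid/haploid peak found (single-depth histogram)")
  }
  counts <- dense_counts(hist)
  rising <- which(counts[-length(counts)] < counts[-1L])
  if (length(rising) == 0L) {
    stop_config("no diploid/haploid peak found (histogram never rises)")
  }
  valley <- rising[1L]
  above <- counts[(valley + 1L):length(counts)]
  peak <- valley + which.max(above) # which.max takes the first (smaller depth)
  list(valley_depth = valley, peak_depth = peak)
}

#' Estimate genome size from a k-mer histogram
#'
#' Applies the k-mer size formula: genome size (bp) = k-mer number /
#' k-mer depth, where the k-mer number excludes the error mass at depths
#' up to the valley (`kmer_number = sum over d > valley of d * count(d)`)
#' and the depth is the coverage peak of [find_error_valley_and_peak()].
#'
#' @param hist A `kmer_histogram` or a tibble with `depth`, `n_kmers`.
#' @return A `genome_size_estimate` object with `genome_size_bp`,
#'   `kmer_number`, `peak_depth`, `valley_depth`, `k`; `glance()` method
#'   available.
#' @export
estimate_genome_size <- function(hist) {
  hist <- as_kmer_histogram(hist)
  vp <- find_error_valley_and_peak(hist)
  h <- hist$histogram
  use <- h$depth > vp$valley_depth
  kmer_number <- sum(as.numeric(h$depth[use]) * h$n_kmers[use])
  structure(
    list(
      genome_size_bp = kmer_number / vp$peak_depth,
      kmer_number = kmer_number,
      peak_depth = vp$peak_depth, valley_depth = vp$valley_depth,
      k = hist$k, total_kmers = hist$total_kmers
    ),
    class = "genome_size_estimate"
  )
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(
    "Genome size estimate: %.0f bp (k-mer number %.0f / peak depth %d; error valley at depth %d)\n",
    x$genome_size_bp, x$kmer_number, x$peak_depth, x$valley_depth
  ))
  invisible(x)
}

#' @rdname estimate_genome_size
#' @param x A `genome_size_estimate`.
#' @param ... Unused.
#' @export
glance.genome_size_estimate <- function(x, ...) {
  tibble(
    genome_size_bp = x$genome_size_bp, kmer_number = x$kmer_number,
    peak_depth = x$peak_depth, valley_depth = x$valley_depth, k = x$k
  )
}
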