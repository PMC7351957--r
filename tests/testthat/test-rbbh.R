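toy_hits <- function(rows) {
  pick <- function(i) vapply(rows, `[`, "", i)
  tibble::tibble(
    qseqid = pick(1), sseqid = pick(2),
    pident = as.numeric(pick(3)), length = as.integer(pick(4)),
    mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = as.integer(pick(4)),
    sstart = 1L, send = as.integer(pick(4)),
    evalue = as.numeric(pick(5)), bitscore = as.numeric(pick(6))
  )
}

test_that("hit tables round-trip through the 12-column layout", {
  hits <- toy_hits(list(
    c("a1", "b1", "97.25", "180", "1e-50", "350.5"),
    c("a2", "b2", "88.4", "150", "1e-30", "200"),
    c("a3", "b9", "45.123", "60", "1e-6", "55.25")
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, path)
  back <- read_hit_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$pident, hits$pident, tolerance = 0)
  expect_equal(back$evalue, hits$evalue, tolerance = 0)
  expect_equal(back$bitscore, hits$bitscore, tolerance = 0)
})

test_that("rows with the wrong column count are format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("a1", "b1", "90", "100", "0", "0", "1", "100", "1", "100", "1e-20", "300"), collapse = "\t"),
    paste(c("a2", "b2", "90", "100", "0", "0", "1", "100", "1", "100", "1e-20"), collapse = "\t")
  ), path)
  expect_error(read_hit_table(path), class = "phylostage_format_error")
})

test_that("best_hits applies the e-value filter and the tie rules", {
  hits <- toy_hits(list(
    c("q1", "s1", "90", "100", "1e-20", "100"),
    c("q1", "s2", "90", "100", "1e-20", "90"),
    c("q2", "s3", "90", "100", "1e-3", "500"), # fails e-value filter
    c("q3", "gB", "90", "100", "1e-20", "80"),
    c("q3", "gA", "90", "100", "1e-20", "80") # equal bitscore & evalue
  ))
  bh <- best_hits(hits)
  expect_equal(bh$sseqid[bh$qseqid == "q1"], "s1")
  expect_false("q2" %in% bh$qseqid)
  expect_equal(bh$sseqid[bh$qseqid == "q3"], "gA")
})

test_that("best_hits collapses multiple HSPs and prefers lower e-value on bitscore ties", {
  hits <- toy_hits(list(
    c("q1", "s1", "90", "100", "1e-10", "120"),
    c("q1", "s1", "90", "100", "1e-40", "80"), # second HSP, same pair
    c("q1", "s2", "90", "100", "1e-30", "120") # same bitscore, better evalue
  ))
  bh <- best_hits(hits)
  expect_equal(bh$sseqid, "s2")
})

test_that("self-hits are dropped with a warning", {
  hits <- toy_hits(list(
    c("q1", "q1", "100", "100", "1e-60", "400"),
    c("q1", "s1", "90", "100", "1e-20", "100")
  ))
  expect_warning(bh <- best_hits(hits), "self-hit")
  expect_equal(bh$sseqid, "s1")
})

test_that("reciprocal pairs require mutual bests and are symmetric", {
  ab <- tibble::tibble(qseqid = c("a1", "a2", "a3"), sseqid = c("b1", "b2", "b9"))
  ba <- tibble::tibble(qseqid = c("b1", "b2", "b9"), sseqid = c("a1", "a2", "a7"))
  p <- reciprocal_best_pairs(ab, ba)
  expect_equal(p$gene_a, c("a1", "a2"))
  expect_equal(p$gene_b, c("b1", "b2"))
  swapped <- reciprocal_best_pairs(ba, ab)
  expect_equal(swapped$gene_a, c("b1", "b2"))
  expect_equal(swapped$gene_b, c("a1", "a2"))
})

test_that("reciprocal pairs from raw tables match the brute-force oracle", {
  withr::with_seed(17, {
    for (i in 1:5) {
      genes_a <- paste0("a", 1:8)
      genes_b <- paste0("b", 1:8)
      mk <- function(qs, ss) {
        n <- 30
        toy_hits(lapply(1:n, function(j) {
          c(
            sample(qs, 1), sample(ss, 1), "80", "100",
            format(10^-sample(4:30, 1), scientific = TRUE),
            as.character(sample(50:500, 1))
          )
        }))
      }
      ab_hits <- mk(genes_a, genes_b)
      ba_hits <- mk(genes_b, genes_a)
      mine <- reciprocal_best_pairs(best_hits(ab_hits), best_hits(ba_hits))
      oracle <- oracle_rbbh(ab_hits, ba_hits)
      expect_equal(mine$gene_a, oracle$gene_a)
      expect_equal(mine$gene_b, oracle$gene_b)
    }
  })
})

test_that("anchored one-to-one sets require coverage in every species", {
  pm <- list(
    B = tibble::tibble(gene_a = c("r1", "r2", "r3"), gene_b = c("b1", "b2", "b3")),
    C = tibble::tibble(gene_a = c("r1", "r3"), gene_b = c("c1", "c3"))
  )
  sets <- anchored_one_to_one(pm, reference = "A")
  expect_equal(nrow(sets), 2)
  expect_identical(names(sets), c("A", "B", "C"))
  expect_equal(sets$A, c("r1", "r3"))
  expect_equal(sets$C, c("c1", "c3"))

  pm$C <- pm$C[0, ]
  expect_equal(nrow(anchored_one_to_one(pm, reference = "A")), 0)
  expect_error(
    anchored_one_to_one(pm, reference = "A", species = c("B", "C", "D")),
    "species missing a pair map: D"
  )

  bij <- list(
    B = tibble::tibble(gene_a = paste0("r", 1:4), gene_b = paste0("b", 1:4)),
    C = tibble::tibble(gene_a = paste0("r", 1:4), gene_b = paste0("c", 1:4))
  )
  expect_equal(nrow(anchored_one_to_one(bij)), 4)
})

test_that("RBBH recovers the simulated truth with zero mutation, with and without decoys", {
  for (n_dec in c(0, 5)) {
    cfg <- sim_config(
      seed = 23, n_groups = 20,
      protein_params = list(
        length = 80, mutation_rate = 0, n_decoys = n_dec,
        decoy_extra_rate = 0.2, background_hit_rate = 0.3
      )
    )
    ps <- simulate_proteome_set(cfg)
    ref <- "Anj"
    others <- setdiff(unique(ps$ortholog_map$species), ref)
    pair_maps <- lapply(others, function(sp) {
      reciprocal_best_pairs(
        best_hits(ps$hits[[paste0(ref, "->", sp)]]),
        best_hits(ps$hits[[paste0(sp, "->", ref)]])
      )
    })
    names(pair_maps) <- others
    sets <- anchored_one_to_one(pair_maps, reference = ref)
    truth <- tidyr::pivot_wider(ps$ortholog_map,
      names_from = "species", values_from = "gene_id"
    )
    truth <- truth[order(truth[[ref]]), c(ref, others)]
    expect_equal(nrow(sets), 20)
    for (cn in c(ref, others)) {
      expect_identical(sets[[cn]], truth[[cn]])
    }
    # also equal to the brute-force double loop on the same tables
    for (sp in others) {
      oracle <- oracle_rbbh(
        ps$hits[[paste0(ref, "->", sp)]],
        ps$hits[[paste0(sp, "->", ref)]]
      )
      expect_equal(pair_maps[[sp]]$gene_a, oracle$gene_a)
      expect_equal(pair_maps[[sp]]$gene_b, oracle$gene_b)
    }
  }
})

test_that("supergene concatenation preserves order, lengths and partitions", {
  aligned <- tibble::tibble(
    set_id = rep(c("og1", "og2"), each = 2),
    species = rep(c("X", "Y"), times = 2),
    seq = c("MKLVA", "MKIVA", "WWTESQR", "WWTDSQR")
  )
  sg <- concatenate_supergene(aligned)
  expect_equal(nchar(sg$supermatrix$seq), c(12, 12))
  expect_equal(sg$partitions$start, c(0, 5))
  expect_equal(sg$partitions$end, c(5, 12))
  expect_equal(sg$supermatrix$seq[sg$supermatrix$species == "X"], "MKLVAWWTESQR")

  # single set is the identity
  one <- concatenate_supergene(aligned[aligned$set_id == "og1", ])
  expect_equal(one$supermatrix$seq, c("MKLVA", "MKIVA"))

  # shuffling the order permutes partitions but not the column multiset
  shuf <- concatenate_supergene(aligned, order = c("og2", "og1"))
  for (sp in c("X", "Y")) {
    a <- sort(strsplit(sg$supermatrix$seq[sg$supermatrix$species == sp], "")[[1]])
    b <- sort(strsplit(shuf$supermatrix$seq[shuf$supermatrix$species == sp], "")[[1]])
    expect_identical(a, b)
  }
  expect_equal(sum(sg$partitions$end - sg$partitions$start), 12)
})

test_that("supergene concatenation rejects ragged sets and missing species", {
  bad_len <- tibble::tibble(
    set_id = c("og1", "og1"), species = c("X", "Y"), seq = c("MKL", "MKLV")
  )
  expect_error(concatenate_supergene(bad_len), "unequal")
  missing_sp <- tibble::tibble(
    set_id = c("og1", "og1", "og2"), species = c("X", "Y", "X"),
    seq = c("MKL", "MKI", "AAA")
  )
  expect_error(concatenate_supergene(missing_sp), "missing species")
})

test_that("write_supergene emits FASTA plus 1-based partition lines", {
  aligned <- tibble::tibble(
    set_id = rep(c("og1", "og2"), each = 2),
    species = rep(c("X", "Y"), times = 2),
    seq = c("MKLVA", "MKIVA", "WWT", "WWT")
  )
  sg <- concatenate_supergene(aligned)
  fa <- withr::local_tempfile(fileext = ".faa")
  pt <- withr::local_tempfile(fileext = ".txt")
  write_supergene(sg, fa, pt)
  seqs <- Biostrings::readAAStringSet(fa)
  expect_equal(as.character(seqs[["X"]]), "MKLVAWWT")
  expect_identical(readLines(pt), c("og1 = 1-5", "og2 = 6-8"))
})
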