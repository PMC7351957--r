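# Independent oracles and toy-data builders shared by the tests. The
# oracles deliberately use different code paths from the package:
# stats::cor(method = "spearman") for rank correlations, plain loops for
# enumeration, and brute-force double checks for best-hit logic.

toy_expression <- function(n_groups = 6, species = c("A", "B"),
                           stages = c("s1", "s2", "s3"),
                           reps = c("r1", "r2"), seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(species, function(sp) {
      n <- n_groups * length(stages) * length(reps)
      tibble::tibble(
        species = sp,
        group_id = rep(sprintf("g%02d", seq_len(n_groups)),
          each = length(stages) * length(reps)
        ),
        stage = rep(rep(stages, each = length(reps)), times = n_groups),
        replicate = rep(reps, times = length(stages) * n_groups),
        tpm = round(runif(n, 1, 1000), 3)
      )
    }))
  })
}

oracle_expdist <- function(x, y) {
  1 - stats::cor(x, y, method = "spearman")
}

# post-order traversal with profile averaging, written independently
oracle_combo_dist <- function(profiles, newick) {
  phy <- ape::read.tree(text = newick)
  ntip <- length(phy$tip.label)
  rec <- function(node) {
    if (node <= ntip) {
      return(list(p = profiles[[phy$tip.label[node]]], d = 0))
    }
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    L <- rec(kids[1])
    R <- rec(kids[2])
    list(
      p = (L$p + R$p) / 2,
      d = L$d + R$d + (1 - stats::cor(L$p, R$p, method = "spearman"))
    )
  }
  rec(ntip + 1L)$d
}

# exhaustive double-loop scorer over the cartesian product of stage lists
# (stage_lists must be in tree leaf order; first species varies slowest)
oracle_score_all <- function(mats, stage_lists, newick) {
  grid <- do.call(expand.grid, c(rev(stage_lists), stringsAsFactors = FALSE))
  grid <- grid[, rev(seq_along(stage_lists)), drop = FALSE]
  names(grid) <- names(stage_lists)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    profiles <- lapply(names(stage_lists), function(sp) {
      mats[[sp]][, grid[i, sp]]
    })
    names(profiles) <- names(stage_lists)
    oracle_combo_dist(profiles, newick)
  }, numeric(1))
  cbind(grid, expdist_total = scores)
}

oracle_ptop <- function(scores_df, q) {
  sp_cols <- setdiff(names(scores_df), "expdist_total")
  N <- nrow(scores_df)
  n_top <- max(1L, as.integer(round(q * N)))
  top <- scores_df[order(scores_df$expdist_total, seq_len(N)), ][seq_len(n_top), ]
  out <- list()
  for (sp in sp_cols) {
    stages <- unique(scores_df[[sp]])
    for (st in stages) {
      out[[length(out) + 1L]] <- data.frame(
        species = sp, stage = st,
        ptop = 100 * sum(top[[sp]] == st) / n_top
      )
    }
  }
  do.call(rbind, out)
}

# brute-force reciprocal best hit over two raw hit tables
oracle_rbbh <- function(ab_hits, ba_hits, evalue_max = 1e-5) {
  best_of <- function(hits) {
    hits <- hits[hits$evalue <= evalue_max & hits$qseqid != hits$sseqid, ]
    res <- list()
    for (q in unique(hits$qseqid)) {
      h <- hits[hits$qseqid == q, ]
      h <- h[order(-h$bitscore, h$evalue, h$sseqid), ]
      res[[q]] <- h$sseqid[1]
    }
    res
  }
  ab <- best_of(ab_hits)
  ba <- best_of(ba_hits)
  pairs <- list()
  for (a in names(ab)) {
    b <- ab[[a]]
    if (!is.null(ba[[b]]) && ba[[b]] == a) {
      pairs[[length(pairs) + 1L]] <- data.frame(gene_a = a, gene_b = b)
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character()))
  }
  out <- do.call(rbind, pairs)
  out[order(out$gene_a), , drop = FALSE]
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
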