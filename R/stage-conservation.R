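# Core statistic: tree-aware scoring of cross-species stage combinations,
# Ptop over the top-q most conserved combinations, BRI aggregation, and a
# tie-corrected Friedman test of stage effects.

# ---- internal profile machinery ---------------------------------------------

# One groups x stages matrix per species from a single-replicate table.
leaf_profile_matrices <- function(data, leaves) {
  missing <- setdiff(leaves, unique(data$species))
  if (length(missing) > 0L) {
    stop_config("species in tree but not in data: %s", paste(missing, collapse = ", "))
  }
  data <- filter(data, .data$species %in% leaves)
  if (length(leaves) > 1L) data <- restrict_to_shared_groups(data)
  groups <- sort(unique(data$group_id))
  if (length(groups) < 3L) stop_config("need >= 3 shared ortholog groups")
  stages <- stage_order(data)
  mats <- lapply(leaves, function(sp) {
    d <- data[data$species == sp, , drop = FALSE]
    st <- stages[[sp]]
    if (nrow(d) != length(groups) * length(st)) {
      stop_config(
        "species '%s' has %d values for %d groups x %d stages; collapse replicates first (aggregate_replicates() or bri_table())",
        sp, nrow(d), length(groups), length(st)
      )
    }
    m <- matrix(NA_real_, length(groups), length(st),
      dimnames = list(groups, st)
    )
    m[cbind(match(d$group_id, groups), match(d$stage, st))] <- d$tpm
    if (anyNA(m)) stop_config("incomplete stage grid for species '%s'", sp)
    m
  })
  setNames(mats, leaves)
}

# Post-order scorer. At each internal node the left and right candidate
# profiles are compared by 1 - Spearman and the node profile is the
# element-wise arithmetic mean of the two children (TPM scale). Candidate
# combinations are crossed with the left child varying slowest, so the
# full enumeration is lexicographic in stage index over the leaf order.
score_tree_node <- function(node, mats, want_profiles = TRUE, want_combos = TRUE) {
  if (node$leaf) {
    m <- mats[[node$species]]
    out <- list(
      profiles = m, score = rep(0, ncol(m)),
      species = node$species, stages = list(colnames(m))
    )
    if (want_combos) out$combos <- matrix(seq_len(ncol(m)), ncol = 1L)
    return(out)
  }
  L <- score_tree_node(node$left, mats, TRUE, want_combos)
  R <- score_tree_node(node$right, mats, TRUE, want_combos)
  rho <- crossprod(scale_ranks(L$profiles), scale_ranks(R$profiles))
  nL <- length(L$score)
  nR <- length(R$score)
  iL <- rep(seq_len(nL), each = nR)
  iR <- rep.int(seq_len(nR), nL)
  out <- list(
    score = L$score[iL] + R$score[iR] + as.vector(t(1 - rho)),
    species = c(L$species, R$species),
    stages = c(L$stages, R$stages)
  )
  if (want_combos) {
    out$combos <- cbind(L$combos[iL, , drop = FALSE], R$combos[iR, , drop = FALSE])
  }
  if (want_profiles) {
    out$profiles <- cross_mean(L$profiles, R$profiles, iL, iR)
  }
  out
}

# ---- exported operations ----------------------------------------------------

#' Tree-aware expression distance of one stage combination
#'
#' Scores a single cross-species stage combination (one stage per species)
#' on a rooted binary species tree. The tree is traversed post-order: at
#' every internal node the expression distance ([expdist()]) between the
#' two child profiles is accumulated, and the node then carries the
#' element-wise arithmetic mean of the child profiles (TPM scale) upward.
#' Taking the topology into account avoids the double-counting bias of
#' simple all-pairs comparisons; for two species the score reduces exactly
#' to the pairwise [expdist()]. Branch lengths are ignored.
#'
#' @param data Long-format expression tibble with exactly one value per
#'   (species, group, stage) — a BRI table or replicate-averaged table.
#' @param tree A `phylo` object or Newick string whose tips are species of
#'   `data`.
#' @param combo Named character vector mapping each species to one of its
#'   stage labels.
#' @return The total expression distance (sum over internal nodes), a
#'   number in `[0, 2 * n_internal_nodes]`.
#' @examples
#' toy <- tibble::tibble(
#'   species = rep(c("A", "B", "C"), each = 4),
#'   group_id = rep(paste0("g", 1:4), times = 3),
#'   stage = "s1", replicate = "r1",
#'   tpm = c(4, 3, 2, 1, 1, 2, 3, 4, 1, 3, 2, 4)
#' )
#' combination_distance(toy, "(A,(B,C));", c(A = "s1", B = "s1", C = "s1"))
#' @export
combination_distance <- function(data, tree, combo) {
  check_expr_tbl(data)
  phy <- species_tree(tree)
  leaves <- tree_leaf_order(phy)
  if (!all(leaves %in% names(combo))) {
    stop_config("`combo` must name one stage for every species in the tree")
  }
  mats <- leaf_profile_matrices(data, leaves)
  mats <- lapply(leaves, function(sp) {
    st <- combo[[sp]]
    if (!st %in% colnames(mats[[sp]])) {
      stop_config("species '%s' has no stage '%s'", sp, st)
    }
    mats[[sp]][, st, drop = FALSE]
  })
  names(mats) <- leaves
  res <- score_tree_node(tree_structure(phy), mats,
    want_profiles = FALSE, want_combos = FALSE
  )
  if (!is.finite(res$score)) {
    stop_undefined_cor("constant profile at an internal comparison: expdist undefined for this combination")
  }
  res$score
}

#' Score every cross-species stage combination
#'
#' Exhaustively scores the Cartesian product of the species' stage lists
#' with [combination_distance()] semantics, sharing intermediate node
#' profiles so the full enumeration stays fast. Combinations are returned
#' in lexicographic stage-index order over the tree's left-to-right leaf
#' order (first species varies slowest).
#'
#' @inheritParams combination_distance
#' @param cap Maximum number of combinations (guard against accidental
#'   combinatorial blow-up). Raise it explicitly for larger products.
#' @return A tibble with one stage-label column per species (columns in
#'   leaf order) and `expdist_total`. Combinations whose scoring hits an
#'   undefined correlation (a constant profile at some node) carry `NA`
#'   and are excluded downstream; a warning reports their count.
#' @export
score_all_combinations <- function(data, tree, cap = 1e7) {
  check_expr_tbl(data)
  phy <- species_tree(tree)
  leaves <- tree_leaf_order(phy)
  mats <- leaf_profile_matrices(data, leaves)
  n_comb <- prod(vapply(mats, ncol, 1L))
  if (n_comb > cap) {
    stop_config(
      "%.3g stage combinations exceed cap = %.3g; raise `cap` to proceed",
      n_comb, cap
    )
  }
  res <- score_tree_node(tree_structure(phy), mats,
    want_profiles = FALSE, want_combos = TRUE
  )
  n_bad <- sum(!is.finite(res$score))
  if (n_bad > 0L) {
    warn(sprintf("%d combination(s) excluded (undefined correlation)", n_bad))
  }
  out <- lapply(seq_along(res$species), function(k) {
    res$stages[[k]][res$combos[, k]]
  })
  names(out) <- res$species
  out$expdist_total <- ifelse(is.finite(res$score), res$score, NA_real_)
  as_tibble(out)
}

#' Per-stage Ptop from combination scores
#'
#' `Ptop(species, stage)` is the percentage of the top fraction `q` most
#' conserved stage combinations (smallest total expression distance) that
#' include the given stage. The top-set size is `max(1, round(q * N))`;
#' distance ties at the cutoff are broken by the combinations' enumeration
#' order, so results are reproducible. Within each species the Ptop values
#' sum to exactly 100 because every top combination contributes one stage
#' per species.
#'
#' @param scores Tibble from [score_all_combinations()].
#' @param q Top fraction of combinations regarded as conserved
#'   (default 0.01, the top 1%).
#' @return Tibble with columns `species`, `stage`, `ptop` covering every
#'   stage of every species (zero where a stage never enters the top set).
#' @export
ptop_from_scores <- function(scores, q = 0.01) {
  if (!is.data.frame(scores) || !"expdist_total" %in% names(scores)) {
    stop_config("`scores` must come from score_all_combinations()")
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1) {
    stop_config("`q` must be a fraction in (0, 1]")
  }
  sp_cols <- setdiff(names(scores), "expdist_total")
  N <- nrow(scores)
  if (N == 0L) stop_config("`scores` is empty")
  n_top <- max(1L, as.integer(round(q * N)))
  ok <- is.finite(scores$expdist_total)
  if (sum(ok) < n_top) {
    stop_config("only %d scored combinations but top set needs %d", sum(ok), n_top)
  }
  ord <- order(scores$expdist_total, seq_len(N), na.last = TRUE)
  top <- ord[seq_len(n_top)]
  res <- lapply(sp_cols, function(sp) {
    stages <- unique(scores[[sp]])
    cnt <- table(factor(scores[[sp]][top], levels = stages))
    tibble(species = sp, stage = stages, ptop = 100 * as.vector(cnt) / n_top)
  })
  bind_rows(res)
}

#' Ptop with biological-replicate resampling (BRI)
#'
#' The full stage-conservation analysis: `B` BRI tables are drawn
#' ([bri_resample()]), every stage combination is scored within each table
#' ([score_all_combinations()]), the per-stage Ptop is computed per table
#' ([ptop_from_scores()]), and the mean and standard deviation over the
#' `B` tables are reported per (species, stage). Stage effects are tested
#' per species with a tie-corrected Friedman test, with the BRI tables as
#' blocks and the species' stages as treatments.
#'
#' @param data Long-format expression tibble with replicates.
#' @param tree A `phylo` object or Newick string; its tips define the
#'   taxon set analysed (prune with [species_tree()] for other levels).
#' @param B Number of BRI tables (default 100).
#' @param q Top fraction of combinations (default 0.01).
#' @param seed Integer seed driving the replicate resampling.
#' @param cap Combination-count guard, as in [score_all_combinations()].
#' @return A `ptop_result` object: a list with `summary` (tibble species,
#'   stage, mean_ptop, sd_ptop), `ptop` (tibble table, species, stage,
#'   ptop with all B tables), `friedman` (per-species test tibble), and
#'   the run parameters. `tidy()`, `glance()` and `autoplot()` methods are
#'   provided.
#' @export
ptop_with_bri <- function(data, tree, B = 100, q = 0.01, seed = 1, cap = 1e7) {
  check_expr_tbl(data)
  B <- check_count(B, "B")
  phy <- species_tree(tree)
  leaves <- tree_leaf_order(phy)
  data <- filter(data, .data$species %in% leaves)
  data <- restrict_to_shared_groups(data)
  stages <- stage_order(data)
  provenance <- bri_resample(data, B = B, seed = seed)

  # one groups x (stage:replicate) matrix per species; BRI tables are then
  # column selections, so the expensive pivot happens once
  groups <- sort(unique(data$group_id))
  stacks <- lapply(leaves, function(sp) {
    d <- data[data$species == sp, , drop = FALSE]
    key <- paste(d$stage, d$replicate, sep = "\r")
    cols <- unique(key)
    m <- matrix(NA_real_, length(groups), length(cols),
      dimnames = list(groups, NULL)
    )
    m[cbind(match(d$group_id, groups), match(key, cols))] <- d$tpm
    if (anyNA(m)) stop_config("incomplete stage/replicate grid for '%s'", sp)
    list(values = m, colkey = cols)
  })
  names(stacks) <- leaves

  struct <- tree_structure(phy)
  prov_split <- split(provenance, provenance$table)
  combos <- NULL
  n_comb <- prod(lengths(stages[leaves]))
  if (n_comb > cap) {
    stop_config("%.3g stage combinations exceed cap = %.3g", n_comb, cap)
  }
  n_top <- max(1L, as.integer(round(q * n_comb)))
  ptop_b <- vector("list", B)
  n_excluded <- 0L
  for (b in seq_len(B)) {
    pb <- prov_split[[b]]
    mats <- lapply(leaves, function(sp) {
      st <- stages[[sp]]
      pk <- pb[pb$species == sp, , drop = FALSE]
      sel <- paste(st, pk$replicate[match(st, pk$stage)], sep = "\r")
      m <- stacks[[sp]]$values[, match(sel, stacks[[sp]]$colkey), drop = FALSE]
      colnames(m) <- st
      m
    })
    names(mats) <- leaves
    res <- score_tree_node(struct, mats,
      want_profiles = FALSE, want_combos = is.null(combos)
    )
    if (is.null(combos)) combos <- res$combos
    score <- res$score
    bad <- !is.finite(score)
    n_excluded <- n_excluded + sum(bad)
    if (sum(!bad) < n_top) {
      stop_config("table %d: fewer valid combinations than the top set", b)
    }
    top <- order(score, seq_along(score), na.last = TRUE)[seq_len(n_top)]
    ptop_b[[b]] <- lapply(seq_along(leaves), function(k) {
      100 * tabulate(combos[top, k], nbins = length(stages[[leaves[k]]])) / n_top
    })
  }
  if (n_excluded > 0L) {
    warn(sprintf("%d combination(s) excluded across BRI tables (undefined correlation)", n_excluded))
  }

  long <- bind_rows(lapply(seq_len(B), function(b) {
    bind_rows(lapply(seq_along(leaves), function(k) {
      tibble(
        table = b, species = leaves[k],
        stage = stages[[leaves[k]]], ptop = ptop_b[[b]][[k]]
      )
    }))
  }))
  summary <- summarise(
    group_by(long, .data$species, .data$stage),
    mean_ptop = mean(.data$ptop),
    sd_ptop = if (dplyr::n() > 1L) sd(.data$ptop) else 0,
    .groups = "drop"
  )
  ord <- order(
    match(summary$species, leaves),
    unlist(Map(function(sp, st) match(st, stages[[sp]]), summary$species, summary$stage),
      use.names = FALSE
    )
  )
  summary <- summary[ord, , drop = FALSE]

  fr <- bind_rows(lapply(seq_along(leaves), function(k) {
    mat <- do.call(rbind, lapply(ptop_b, function(p) p[[k]]))
    ft <- friedman_rank_test(mat)
    tibble(
      species = leaves[k], statistic = ft$statistic, df = ft$df,
      p_value = ft$p_value
    )
  }))

  structure(
    list(
      summary = summary, ptop = long, friedman = fr,
      B = B, q = q, seed = seed, n_combinations = n_comb, n_top = n_top,
      n_excluded = n_excluded, tree = phy, provenance = provenance
    ),
    class = "ptop_result"
  )
}

#' @export
print.ptop_result <- function(x, ...) {
  cat(sprintf(
    "Stage-conservation result: %d species, %d combinations, top %d (q = %g), B = %d BRI tables\n",
    length(unique(x$summary$species)), x$n_combinations, x$n_top, x$q, x$B
  ))
  print(x$summary, n = nrow(x$summary))
  cat("\nFriedman test of stage effects (blocks = BRI tables):\n")
  print(x$friedman)
  invisible(x)
}

#' @rdname ptop_with_bri
#' @param x,object A `ptop_result`.
#' @param ... Unused.
#' @export
tidy.ptop_result <- function(x, ...) x$summary

#' @rdname ptop_with_bri
#' @export
glance.ptop_result <- function(x, ...) {
  tibble(
    n_species = length(unique(x$summary$species)),
    n_combinations = x$n_combinations, n_top = x$n_top,
    B = x$B, q = x$q, n_excluded = x$n_excluded,
    min_p_friedman = min(x$friedman$p_value)
  )
}

#' Friedman rank test for blocked stage effects
#'
#' Nonparametric test that `k` treatments (here: developmental stages)
#' differ, with values ranked within each of `B` blocks (here: BRI
#' tables). The statistic is the tie-corrected Friedman chi-square
#' `(k - 1) * sum((R_j - B(k+1)/2)^2) / (A - B k (k+1)^2 / 4)` with `R_j`
#' the rank sums and `A` the sum of squared ranks; without ties it reduces
#' to `12/(B k (k+1)) * sum(R_j^2) - 3 B (k+1)`. The p-value uses the
#' chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param x Numeric matrix or data frame, blocks in rows, treatments in
#'   columns (`B >= 2`, `k >= 2`).
#' @return A `phylostage_friedman` object with `statistic`, `df`,
#'   `p_value`, `n_blocks`, `k` and `tie_corrected`; `tidy()`/`glance()`
#'   methods are provided. If every block is completely tied the
#'   denominator vanishes and the statistic is reported as 0 with a
#'   warning.
#' @examples
#' friedman_rank_test(rbind(c(10, 20, 30), c(1, 2, 3))) # chi2 = 4, df = 2
#' @export
friedman_rank_test <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stop_config("`x` must be a complete numeric matrix")
  Bn <- nrow(x)
  k <- ncol(x)
  if (Bn < 2L || k < 2L) stop_config("need >= 2 blocks and >= 2 treatments")
  r <- t(apply(x, 1L, rank, ties.method = "average"))
  Rj <- colSums(r)
  A <- sum(r^2)
  Cc <- Bn * k * (k + 1)^2 / 4
  num <- (k - 1) * sum((Rj - Bn * (k + 1) / 2)^2)
  den <- A - Cc
  if (den <= .Machine$double.eps * A) {
    warn("all blocks completely tied; Friedman statistic reported as 0")
    stat <- 0
  } else {
    stat <- num / den
  }
  structure(
    list(
      statistic = stat, df = k - 1L,
      p_value = pchisq(stat, k - 1L, lower.tail = FALSE),
      n_blocks = Bn, k = k,
      tie_corrected = any(apply(r, 1L, anyDuplicated) > 0L)
    ),
    class = "phylostage_friedman"
  )
}

#' @export
print.phylostage_friedman <- function(x, ...) {
  cat(sprintf(
    "Friedman rank test: chi2 = %.4g, df = %d, p = %.4g (%d blocks, %d treatments%s)\n",
    x$statistic, x$df, x$p_value, x$n_blocks, x$k,
    if (x$tie_corrected) ", tie-corrected" else ""
  ))
  invisible(x)
}

#' @rdname friedman_rank_test
#' @param x,object A `phylostage_friedman` object.
#' @param ... Unused.
#' @export
tidy.phylostage_friedman <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @rdname friedman_rank_test
#' @export
glance.phylostage_friedman <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    n_blocks = x$n_blocks, k = x$k, tie_corrected = x$tie_corrected
  )
}

#' Pairwise stage-by-stage expression-distance matrix
#'
#' All pairwise [expdist()] values between the replicate-averaged stage
#' profiles of two species, the classic two-species view that complements
#' the tree-aware combination scoring.
#'
#' @param data Long-format expression tibble containing both species.
#' @param species Character vector of exactly two species; defaults to the
#'   two species present in `data`.
#' @return Tibble with columns `stage_a`, `stage_b`, `expdist` (species A
#'   stages cycling slowest, both in developmental order). Swapping the
#'   two species transposes the matrix.
#' @export
pairwise_stage_matrix <- function(data, species = NULL) {
  check_expr_tbl(data)
  if (is.null(species)) species <- unique(data$species)
  if (length(species) != 2L) stop_config("exactly two species are required")
  data <- filter(data, .data$species %in% !!species)
  data <- aggregate_replicates(data)
  data$replicate <- "mean"
  mats <- leaf_profile_matrices(data, species)
  ra <- scale_ranks(mats[[1]])
  rb <- scale_ranks(mats[[2]])
  if (any(!is.finite(ra)) || any(!is.finite(rb))) {
    stop_undefined_cor("constant stage profile: expdist undefined")
  }
  d <- 1 - crossprod(ra, rb)
  tibble(
    stage_a = rep(colnames(mats[[1]]), each = ncol(mats[[2]])),
    stage_b = rep(colnames(mats[[2]]), times = ncol(mats[[1]])),
    expdist = as.vector(t(d))
  )
}
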