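# Seeded generators for every input the pipeline consumes: developmental
# expression tables with a controllable cross-species divergence profile,
# synthetic proteomes with all-vs-all hit tables, and sequencing reads for
# k-mer genome sizing. All draws derive from one root seed with fixed
# per-component offsets (+1 expression, +2 proteomes, +3 reads).

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Hourglass divergence profile
#'
#' Stage-dependent divergence scale with a Gaussian-shaped dip: divergence
#' is lowest at `center` (the designated phylotypic period) and rises
#' towards early and late development.
#'
#' @param sigma_min,sigma_max Divergence scale (per unit branch length, on
#'   the log-expression scale) at the dip and at the extremes.
#' @param center Pseudo-time fraction (0..1) of maximal conservation.
#' @param width Gaussian width of the dip.
#' @return A function mapping pseudo-time fractions to divergence scales.
#' @export
hourglass_profile <- function(sigma_min = 0.1, sigma_max = 0.8,
                              center = 0.5, width = 0.15) {
  force(sigma_min); force(sigma_max); force(center); force(width)
  if (sigma_min < 0 || sigma_max < sigma_min) {
    stop_config("need 0 <= sigma_min <= sigma_max")
  }
  function(t) sigma_max - (sigma_max - sigma_min) * exp(-(t - center)^2 / (2 * width^2))
}

#' Flat divergence profile
#'
#' Constant divergence scale: no stage is more conserved than any other,
#' the null condition for calibration checks.
#'
#' @param sigma Divergence scale per unit branch length.
#' @return A function mapping pseudo-time fractions to `sigma`.
#' @export
flat_profile <- function(sigma = 0.45) {
  force(sigma)
  if (sigma < 0) stop_config("`sigma` must be >= 0")
  function(t) rep_len(sigma, length(t))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate
#' the study design the package targets: four echinoderm-like species
#' related as `(Anj,(Apj,(Sp,Lv)))`, ten developmental stages per species,
#' two biological replicates per stage, a thousand ortholog groups with
#' TPM-scale lognormal replicate noise, and an hourglass-shaped
#' cross-species divergence profile.
#'
#' @param seed Root seed; component streams use fixed offsets from it.
#' @param tree_newick Rooted binary species tree (Newick).
#' @param stages_per_species Named list: species -> ordered stage labels.
#' @param n_groups Number of ortholog groups.
#' @param n_replicates Biological replicates per stage.
#' @param divergence_profile Function pseudo-time fraction -> divergence
#'   scale (sigma >= 0), e.g. [hourglass_profile()] or [flat_profile()].
#' @param noise_sd Lognormal sigma of multiplicative replicate noise.
#' @param dropout_rate Probability that a group is absent in a species.
#' @param read_params List with `genome_size` (bp), `coverage` (x),
#'   `read_length` (bp), `error_rate` (substitutions per base).
#' @param protein_params List with `length` (aa), `mutation_rate` (per
#'   site per unit branch length), `n_decoys` (decoy paralogs),
#'   `decoy_extra_rate` (extra mutation of decoys), `background_hit_rate`
#'   (cross-group hit-table noise).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       tree_newick = "(Anj,(Apj,(Sp,Lv)));",
                       stages_per_species = NULL,
                       n_groups = 1000,
                       n_replicates = 2,
                       divergence_profile = hourglass_profile(),
                       noise_sd = 0.3,
                       dropout_rate = 0,
                       read_params = list(
                         genome_size = 1e5, coverage = 40,
                         read_length = 100, error_rate = 0.005
                       ),
                       protein_params = list(
                         length = 200, mutation_rate = 0.05,
                         n_decoys = 0, decoy_extra_rate = 0.1,
                         background_hit_rate = 0.01
                       )) {
  seed <- check_seed(seed)
  phy <- species_tree(tree_newick)
  sp <- tree_leaf_order(phy)
  if (is.null(stages_per_species)) {
    stages_per_species <- setNames(
      rep(list(sprintf("s%02d", 1:10)), length(sp)), sp
    )
  }
  if (!setequal(names(stages_per_species), sp)) {
    stop_config(
      "stages_per_species must name exactly the tree species (%s)",
      paste(sp, collapse = ", ")
    )
  }
  n_groups <- check_count(n_groups, "n_groups")
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (!is.function(divergence_profile)) {
    stop_config("`divergence_profile` must be a function of pseudo-time")
  }
  probe <- divergence_profile(seq(0, 1, length.out = 21))
  if (any(!is.finite(probe)) || any(probe < 0)) {
    stop_config("divergence_profile must return finite values >= 0")
  }
  if (noise_sd < 0) stop_config("`noise_sd` must be >= 0")
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop_config("`dropout_rate` must be in [0, 1]")
  }
  rp <- read_params
  if (rp$coverage <= 0 || rp$read_length < 1 || rp$genome_size < 1 ||
    rp$error_rate < 0 || rp$error_rate > 1) {
    stop_config("invalid read_params")
  }
  structure(
    list(
      seed = seed, tree_newick = tree_newick, tree = phy,
      stages_per_species = stages_per_species[sp],
      n_groups = n_groups, n_replicates = n_replicates,
      divergence_profile = divergence_profile, noise_sd = noise_sd,
      dropout_rate = dropout_rate, read_params = rp,
      protein_params = protein_params
    ),
    class = "sim_config"
  )
}

# smooth random curves: standard-normal knot values interpolated by a
# natural cubic spline onto an m-point pseudo-time grid. The interpolation
# is linear in the knot values, so one basis matrix serves all groups.
spline_basis <- function(m = 100L, n_knots = 10L) {
  knots <- seq(0, 1, length.out = n_knots)
  grid <- seq(0, 1, length.out = m)
  vapply(seq_len(n_knots), function(j) {
    e <- numeric(n_knots)
    e[j] <- 1
    spline(knots, e, xout = grid, method = "natural")$y
  }, numeric(m))
}

# stage fractions: stage i of S sits at pseudo-time (i-1)/(S-1)
stage_fractions <- function(S) {
  if (S == 1L) 0.5 else (seq_len(S) - 1) / (S - 1)
}

# linear interpolation of grid curves (m x G) at arbitrary fractions;
# returns G x length(frac)
eval_curves <- function(curves, frac) {
  m <- nrow(curves)
  u <- frac * (m - 1) + 1
  i0 <- pmin(floor(u), m - 1L)
  w <- u - i0
  # S x G slices; a length-S vector recycles down the S rows column-wise
  val <- curves[i0, , drop = FALSE] * (1 - w) + curves[i0 + 1L, , drop = FALSE] * w
  t(val)
}

#' Simulate a multi-species developmental expression dataset
#'
#' For each ortholog group an ancestral log-expression trajectory over a
#' common pseudo-time is drawn as a smooth random curve; along every tree
#' branch the trajectory is perturbed by an independent smooth Gaussian
#' curve whose pointwise scale is `divergence_profile(t) * branch length`;
#' leaf trajectories are sampled at each species' stage grid (stage `i` of
#' `S` at fraction `(i-1)/(S-1)`); replicates receive multiplicative
#' lognormal noise; and each stage-replicate column is rescaled to a total
#' of 1e6, matching TPM semantics.
#'
#' @param config A [sim_config()] object.
#' @return A list with `expression` (long-format tibble: species,
#'   group_id, stage, replicate, tpm) and `truth`, a list carrying
#'   `conserved_stages` (per species, the stages whose divergence scale is
#'   within 25% of the profile's range above its minimum — the designated
#'   conserved window), `ortholog_map`, `stage_sigma` and the generator
#'   parameters. Identical configs (same seed) give identical output.
#' @export
simulate_expression_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("`config` must be a sim_config")
  phy <- config$tree
  leaves <- tree_leaf_order(phy)
  G <- config$n_groups
  m <- 100L
  basis <- spline_basis(m)
  grid_t <- seq(0, 1, length.out = m)
  sig_grid <- config$divergence_profile(grid_t)

  withr::with_seed(config$seed + 1L, {
    mu <- rnorm(G, log(50), 1.5)
    anc <- basis %*% matrix(rnorm(10L * G), 10L, G)
    log_root <- sweep(anc, 2L, mu, "+")

    ntip <- length(phy$tip.label)
    edge <- phy$edge
    blen <- phy$edge.length %||% rep(1, nrow(edge))
    leaf_curves <- vector("list", ntip)
    walk <- function(node, curve) {
      rows <- which(edge[, 1] == node)
      if (length(rows) == 0L) {
        leaf_curves[[node]] <<- curve
        return(invisible())
      }
      for (r in rows) {
        pert <- basis %*% matrix(rnorm(10L * G), 10L, G)
        child_curve <- curve + pert * (sig_grid * blen[r])
        walk(edge[r, 2], child_curve)
      }
    }
    walk(ntip + 1L, log_root)

    groups <- sprintf("g%04d", seq_len(G))
    R <- config$n_replicates
    reps <- paste0("r", seq_len(R))
    tables <- vector("list", length(leaves))
    stage_sigma <- vector("list", length(leaves))
    for (k in seq_along(leaves)) {
      sp <- leaves[k]
      tip <- match(sp, phy$tip.label)
      stages <- config$stages_per_species[[sp]]
      S <- length(stages)
      frac <- stage_fractions(S)
      stage_sigma[[k]] <- setNames(config$divergence_profile(frac), stages)
      logval <- eval_curves(leaf_curves[[tip]], frac) # G x S
      keep <- rep(TRUE, G)
      if (config$dropout_rate > 0) {
        keep <- runif(G) >= config$dropout_rate
        if (sum(keep) < 3L) keep[1:3] <- TRUE
      }
      vals <- matrix(NA_real_, sum(keep), S * R)
      for (s in seq_len(S)) {
        for (r in seq_len(R)) {
          x <- exp(logval[keep, s] + rnorm(sum(keep), 0, config$noise_sd))
          vals[, (s - 1L) * R + r] <- x / sum(x) * 1e6
        }
      }
      gk <- groups[keep]
      tables[[k]] <- tibble(
        species = sp,
        group_id = rep(gk, each = S * R),
        stage = rep(rep(stages, each = R), times = length(gk)),
        replicate = rep(reps, times = S * length(gk)),
        tpm = as.vector(t(vals))
      )
    }
  })
  names(stage_sigma) <- leaves
  expression <- bind_rows(tables)

  conserved <- lapply(stage_sigma, function(sig) {
    lo <- min(sig)
    hi <- max(sig)
    if (hi - lo < 1e-12) {
      names(sig) # flat profile: every stage equally conserved
    } else {
      names(sig)[sig <= lo + 0.25 * (hi - lo)]
    }
  })
  map <- distinct(expression, .data$species, .data$group_id)
  map <- mutate(map,
    gene_id = paste(.data$species, .data$group_id, sep = "_")
  )
  list(
    expression = expression,
    truth = list(
      conserved_stages = conserved,
      stage_sigma = stage_sigma,
      ortholog_map = select(map, "group_id", "species", "gene_id"),
      true_genome_size = config$read_params$genome_size
    ),
    config = config
  )
}

# mutate a character matrix of residues (L x n) in place
mutate_residues <- function(mat, p, alphabet = AA_ALPHABET) {
  hit <- which(runif(length(mat)) < p)
  if (length(hit) > 0L) {
    old <- match(mat[hit], alphabet)
    off <- sample.int(length(alphabet) - 1L, length(hit), replace = TRUE)
    mat[hit] <- alphabet[(old + off - 1L) %% length(alphabet) + 1L]
  }
  mat
}

#' Simulate proteomes and all-vs-all similarity hit tables
#'
#' Random protein sequences, one per ortholog group, are mutated along the
#' species tree; per ordered species pair a 12-column tabular hit table is
#' emitted in which within-group hits score higher (bitscore = 2 x
#' matching residues) than cross-group background hits and than hits to
#' optional decoy paralogs (extra-mutated copies of true genes). With zero
#' mutation and no decoys, reciprocal-best-hit orthology on these tables
#' recovers the true ortholog map exactly.
#'
#' @param config A [sim_config()] object (`protein_params` controls
#'   sequence length, mutation, decoys and background hits).
#' @return List with `proteins` (tibble: species, gene_id, group_id,
#'   is_decoy, seq), `ortholog_map` (the ground truth), and `hits`, a
#'   named list of hit-table tibbles keyed `"A->B"`.
#' @export
simulate_proteome_set <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("`config` must be a sim_config")
  pp <- config$protein_params
  phy <- config$tree
  leaves <- tree_leaf_order(phy)
  G <- config$n_groups
  L <- pp$length

  withr::with_seed(config$seed + 2L, {
    root <- matrix(sample(AA_ALPHABET, L * G, replace = TRUE), L, G)
    ntip <- length(phy$tip.label)
    edge <- phy$edge
    blen <- phy$edge.length %||% rep(1, nrow(edge))
    leaf_seq <- vector("list", ntip)
    walk <- function(node, mat) {
      rows <- which(edge[, 1] == node)
      if (length(rows) == 0L) {
        leaf_seq[[node]] <<- mat
        return(invisible())
      }
      for (r in rows) {
        walk(edge[r, 2], mutate_residues(mat, pp$mutation_rate * blen[r]))
      }
    }
    walk(ntip + 1L, root)

    groups <- sprintf("g%04d", seq_len(G))
    proteins <- bind_rows(lapply(leaves, function(sp) {
      mat <- leaf_seq[[match(sp, phy$tip.label)]]
      tibble(
        species = sp,
        gene_id = paste(sp, groups, sep = "_"),
        group_id = groups, is_decoy = FALSE,
        seq = apply(mat, 2L, paste, collapse = "")
      )
    }))
    if (pp$n_decoys > 0L) {
      dg <- sample.int(G, min(pp$n_decoys, G))
      dsp <- sample(leaves, length(dg), replace = TRUE)
      decoys <- bind_rows(lapply(seq_along(dg), function(i) {
        src <- leaf_seq[[match(dsp[i], phy$tip.label)]][, dg[i], drop = FALSE]
        src <- mutate_residues(src, pp$decoy_extra_rate)
        if (identical(
          paste(src, collapse = ""),
          proteins$seq[proteins$species == dsp[i] & proteins$group_id == groups[dg[i]]]
        )) {
          src[1L] <- AA_ALPHABET[match(src[1L], AA_ALPHABET) %% 20L + 1L]
        }
        tibble(
          species = dsp[i],
          gene_id = paste0(dsp[i], "_d", sprintf("%04d", dg[i])),
          group_id = groups[dg[i]], is_decoy = TRUE,
          seq = paste(src, collapse = "")
        )
      }))
      proteins <- bind_rows(proteins, decoys)
    }

    seq_mat <- function(gene) {
      matrix(strsplit(proteins$seq[match(gene, proteins$gene_id)], "")[[1]], ncol = 1)
    }
    hit_row <- function(q, s, qseq, sseq) {
      matches <- sum(qseq == sseq)
      bits <- 2 * matches
      tibble(
        qseqid = q, sseqid = s, pident = round(100 * matches / L, 2),
        length = L, mismatch = L - matches, gapopen = 0L,
        qstart = 1L, qend = L, sstart = 1L, send = L,
        evalue = 10^(-bits / 10), bitscore = bits
      )
    }
    hits <- list()
    for (a in leaves) {
      mat_a <- leaf_seq[[match(a, phy$tip.label)]]
      for (b in leaves) {
        if (a == b) next
        mat_b <- leaf_seq[[match(b, phy$tip.label)]]
        matches <- colSums(mat_a == mat_b)
        bits <- 2 * matches
        tab <- tibble(
          qseqid = paste(a, groups, sep = "_"),
          sseqid = paste(b, groups, sep = "_"),
          pident = round(100 * matches / L, 2), length = L,
          mismatch = L - matches, gapopen = 0L,
          qstart = 1L, qend = L, sstart = 1L, send = L,
          evalue = 10^(-bits / 10), bitscore = bits
        )
        # decoy hits: queries in a hit the decoy copies living in b
        dec_b <- proteins[proteins$is_decoy & proteins$species == b, , drop = FALSE]
        if (nrow(dec_b) > 0L) {
          drows <- bind_rows(lapply(seq_len(nrow(dec_b)), function(i) {
            g <- dec_b$group_id[i]
            hit_row(
              paste(a, g, sep = "_"), dec_b$gene_id[i],
              mat_a[, match(g, groups), drop = FALSE], seq_mat(dec_b$gene_id[i])
            )
          }))
          tab <- bind_rows(tab, drows)
        }
        # decoys of a as queries: their best target is the true gene in b
        dec_a <- proteins[proteins$is_decoy & proteins$species == a, , drop = FALSE]
        if (nrow(dec_a) > 0L) {
          drows <- bind_rows(lapply(seq_len(nrow(dec_a)), function(i) {
            g <- dec_a$group_id[i]
            hit_row(
              dec_a$gene_id[i], paste(b, g, sep = "_"),
              seq_mat(dec_a$gene_id[i]), mat_b[, match(g, groups), drop = FALSE]
            )
          }))
          tab <- bind_rows(tab, drows)
        }
        n_bg <- round(pp$background_hit_rate * G)
        if (n_bg > 0L && G > 1L) {
          qi <- sample.int(G, n_bg, replace = TRUE)
          si <- (qi + sample.int(G - 1L, n_bg, replace = TRUE) - 1L) %% G + 1L
          bg_bits <- round(runif(n_bg, 30, 70), 1)
          tab <- bind_rows(tab, tibble(
            qseqid = paste(a, groups[qi], sep = "_"),
            sseqid = paste(b, groups[si], sep = "_"),
            pident = round(runif(n_bg, 20, 30), 2),
            length = as.integer(round(L * runif(n_bg, 0.3, 0.8))),
            mismatch = 0L, gapopen = 0L, qstart = 1L, qend = L,
            sstart = 1L, send = L,
            evalue = 10^(-bg_bits / 10), bitscore = bg_bits
          ))
        }
        hits[[paste0(a, "->", b)]] <- tab
      }
    }
  })
  truth <- filter(proteins, !.data$is_decoy)
  list(
    proteins = proteins,
    ortholog_map = select(truth, "group_id", "species", "gene_id"),
    hits = hits,
    config = config
  )
}

#' Simulate shotgun sequencing reads from a random genome
#'
#' A uniform-random genome of the configured size is drawn; reads of fixed
#' length are sampled uniformly from both strands at the configured
#' coverage (`floor(coverage * genome / read_length)` reads) and receive
#' independent substitution errors at the configured rate. The Phred
#' quality line is constant ("I").
#'
#' @param config A [sim_config()] object (`read_params` is used).
#' @return List with `reads` (tibble: read_id, seq), `genome` (the true
#'   genome string) and `true_genome_size`.
#' @export
simulate_reads <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("`config` must be a sim_config")
  rp <- config$read_params
  G <- as.integer(rp$genome_size)
  L <- as.integer(rp$read_length)
  if (L > G) stop_config("read length (%d) exceeds genome length (%d)", L, G)
  withr::with_seed(config$seed + 3L, {
    genome <- paste(sample(c("A", "C", "G", "T"), G, replace = TRUE), collapse = "")
    n_reads <- floor(rp$coverage * G / L)
    starts <- sample.int(G - L + 1L, n_reads, replace = TRUE)
    reads <- substring(genome, starts, starts + L - 1L)
    rc <- runif(n_reads) < 0.5
    reads[rc] <- revcomp(reads[rc])
    if (rp$error_rate > 0) {
      mat <- matrix(unlist(strsplit(reads, ""), use.names = FALSE), nrow = L)
      mat <- mutate_residues(mat, rp$error_rate, alphabet = c("A", "C", "G", "T"))
      reads <- do.call(paste0, as.data.frame(t(mat), stringsAsFactors = FALSE))
    }
  })
  list(
    reads = tibble(read_id = sprintf("read_%06d", seq_len(length(reads))), seq = reads),
    genome = genome,
    true_genome_size = G
  )
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", stringi::stri_reverse(x))
}

#' Write simulated proteomes, hit tables and the ortholog map to disk
#'
#' @param sim Result of [simulate_proteome_set()].
#' @param dir Output directory (created if needed). FASTA files are
#'   written per species, hit tables as 12-column TSVs, and the true
#'   ortholog map as a TSV.
#' @return `dir`, invisibly.
#' @export
write_sim_proteomes <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in unique(sim$proteins$species)) {
    d <- sim$proteins[sim$proteins$species == sp, , drop = FALSE]
    aa <- Biostrings::AAStringSet(setNames(d$seq, d$gene_id))
    Biostrings::writeXStringSet(aa, file.path(dir, paste0(sp, ".faa")))
  }
  for (key in names(sim$hits)) {
    fname <- paste0(sub("->", "_vs_", key, fixed = TRUE), ".tsv")
    write_hit_table(sim$hits[[key]], file.path(dir, fname))
  }
  readr::write_tsv(sim$ortholog_map, file.path(dir, "ortholog_map.tsv"),
    progress = FALSE
  )
  invisible(dir)
}

#' Write a simulated expression dataset to disk
#'
#' One wide TSV per species (via [write_expression_table()]), the species
#' tree as Newick, the true ortholog map as TSV and the remaining ground
#' truth (conserved stages, per-stage divergence scales, genome size) as
#' JSON.
#'
#' @param sim Result of [simulate_expression_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_expression <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in unique(sim$expression$species)) {
    write_expression_table(
      sim$expression[sim$expression$species == sp, , drop = FALSE],
      file.path(dir, paste0(sp, "_expression.tsv"))
    )
  }
  ape::write.tree(sim$config$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(sim$truth$ortholog_map, file.path(dir, "ortholog_map.tsv"),
    progress = FALSE
  )
  jsonlite::write_json(
    list(
      conserved_stages = sim$truth$conserved_stages,
      stage_sigma = lapply(sim$truth$stage_sigma, as.list),
      true_genome_size = sim$truth$true_genome_size
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Write simulated reads as FASTQ
#'
#' @param sim Result of [simulate_reads()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_sim_reads <- function(sim, path) {
  dna <- Biostrings::DNAStringSet(setNames(sim$reads$seq, sim$reads$read_id))
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}
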