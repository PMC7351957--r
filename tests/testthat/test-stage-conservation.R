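one_rep <- function(tbl) {
  tbl <- tbl[tbl$replicate == "r1", ]
  tbl
}

test_that("combination_distance reduces to expdist for two species", {
  tbl <- one_rep(toy_expression(8, species = c("A", "B")))
  d <- combination_distance(tbl, "(A,B);", c(A = "s1", B = "s2"))
  xa <- tbl$tpm[tbl$species == "A" & tbl$stage == "s1"]
  xb <- tbl$tpm[tbl$species == "B" & tbl$stage == "s2"]
  expect_equal(d, expdist(xa, xb), tolerance = 1e-12)
})

test_that("identical profiles across species score zero", {
  tbl <- one_rep(toy_expression(6, species = c("A", "B", "C")))
  base <- tbl$tpm[tbl$species == "A"]
  tbl$tpm <- rep(base, times = 3)
  expect_equal(
    combination_distance(tbl, "(A,(B,C));", c(A = "s1", B = "s1", C = "s1")),
    0,
    tolerance = 1e-12
  )
})

test_that("the three-species hand traversal gives 0.2 + (1 + 0.9487)", {
  tbl <- tibble::tibble(
    species = rep(c("A", "B", "C"), each = 4),
    group_id = rep(paste0("g", 1:4), times = 3),
    stage = "s1", replicate = "r1",
    tpm = c(4, 3, 2, 1, 1, 2, 3, 4, 1, 3, 2, 4)
  )
  d <- combination_distance(tbl, "(A,(B,C));", c(A = "s1", B = "s1", C = "s1"))
  # oracle: node(B,C) = 1 - cor rank = 0.2; then A vs mean(B,C)
  bc <- (c(1, 2, 3, 4) + c(1, 3, 2, 4)) / 2
  expected <- oracle_expdist(c(1, 2, 3, 4), c(1, 3, 2, 4)) +
    oracle_expdist(c(4, 3, 2, 1), bc)
  expect_equal(d, expected, tolerance = 1e-12)
  expect_equal(d, 2.148683, tolerance = 1e-6)
})

test_that("constant profiles raise an undefined-correlation error", {
  tbl <- one_rep(toy_expression(5, species = c("A", "B")))
  tbl$tpm[tbl$species == "A" & tbl$stage == "s1"] <- 7
  expect_error(
    combination_distance(tbl, "(A,B);", c(A = "s1", B = "s1")),
    class = "phylostage_undefined_cor"
  )
})

test_that("score_all_combinations enumerates the full product in lexicographic order", {
  tbl <- one_rep(toy_expression(5,
    species = c("A", "B"),
    stages = paste0("s", 1:4)
  ))
  scores <- score_all_combinations(tbl, "(A,B);")
  expect_equal(nrow(scores), 16)
  expect_identical(names(scores), c("A", "B", "expdist_total"))
  # first species varies slowest
  expect_identical(scores$A, rep(paste0("s", 1:4), each = 4))
  expect_identical(scores$B, rep(paste0("s", 1:4), times = 4))
})

test_that("pipeline scores equal the naive re-implementation exactly", {
  tbl <- one_rep(toy_expression(7,
    species = c("A", "B", "C"),
    stages = paste0("s", 1:3)
  ))
  newick <- "(A,(B,C));"
  scores <- score_all_combinations(tbl, newick)
  tbl_shared <- restrict_to_shared_groups(tbl)
  groups <- sort(unique(tbl_shared$group_id))
  mats <- lapply(c("A", "B", "C"), function(sp) {
    d <- tbl_shared[tbl_shared$species == sp, ]
    m <- matrix(NA_real_, length(groups), 3,
      dimnames = list(groups, paste0("s", 1:3))
    )
    m[cbind(match(d$group_id, groups), match(d$stage, colnames(m)))] <- d$tpm
    m
  })
  names(mats) <- c("A", "B", "C")
  stage_lists <- list(A = paste0("s", 1:3), B = paste0("s", 1:3), C = paste0("s", 1:3))
  oracle <- oracle_score_all(mats, stage_lists, newick)
  expect_identical(scores$A, oracle$A)
  expect_identical(scores$B, oracle$B)
  expect_identical(scores$C, oracle$C)
  expect_equal(scores$expdist_total, oracle$expdist_total, tolerance = 1e-12)
})

test_that("ptop_from_scores counts top-set membership and sums to 100", {
  tbl <- one_rep(toy_expression(5,
    species = c("A", "B"),
    stages = paste0("s", 1:4)
  ))
  scores <- score_all_combinations(tbl, "(A,B);")
  # q = 0.01 of 16 -> top set of exactly one combination
  pt <- ptop_from_scores(scores, q = 0.01)
  best <- scores[which.min(scores$expdist_total), ]
  expect_equal(pt$ptop[pt$species == "A" & pt$stage == best$A], 100)
  expect_equal(pt$ptop[pt$species == "B" & pt$stage == best$B], 100)
  expect_equal(sum(pt$ptop[pt$species == "A"]), 100)
  expect_equal(sum(pt$ptop[pt$species == "B"]), 100)
  # larger q matches the independent oracle
  for (q in c(0.1, 0.25, 1)) {
    pt <- ptop_from_scores(scores, q = q)
    po <- oracle_ptop(as.data.frame(scores), q = q)
    m <- merge(as.data.frame(pt), po, by = c("species", "stage"))
    expect_equal(m$ptop.x, m$ptop.y, tolerance = 1e-12)
    sums <- tapply(pt$ptop, pt$species, sum)
    expect_true(all(abs(sums - 100) < 1e-9))
  }
})

test_that("ptop_with_bri is seed-deterministic and degenerate with one replicate", {
  tbl <- toy_expression(8, species = c("A", "B"), stages = paste0("s", 1:3))
  r1 <- ptop_with_bri(tbl, "(A,B);", B = 8, q = 0.1, seed = 4)
  r2 <- ptop_with_bri(tbl, "(A,B);", B = 8, q = 0.1, seed = 4)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$ptop, r2$ptop)

  single <- tbl[tbl$replicate == "r1", ]
  rs <- ptop_with_bri(single, "(A,B);", B = 6, q = 0.1, seed = 1)
  expect_true(all(rs$summary$sd_ptop == 0))
  sums <- tapply(rs$ptop$ptop, list(rs$ptop$table, rs$ptop$species), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("ptop_with_bri agrees with scoring each BRI table independently", {
  tbl <- toy_expression(6, species = c("A", "B", "C"), stages = paste0("s", 1:3))
  res <- ptop_with_bri(tbl, "(A,(B,C));", B = 3, q = 0.05, seed = 12)
  prov <- bri_resample(restrict_to_shared_groups(tbl), B = 3, seed = 12)
  for (b in 1:3) {
    bt <- bri_table(tbl, prov, b)
    pt <- ptop_from_scores(score_all_combinations(bt, "(A,(B,C));"), q = 0.05)
    got <- res$ptop[res$ptop$table == b, c("species", "stage", "ptop")]
    m <- merge(as.data.frame(got), as.data.frame(pt),
      by = c("species", "stage")
    )
    expect_equal(m$ptop.x, m$ptop.y, tolerance = 1e-12)
  }
})

test_that("friedman_rank_test reproduces the worked rank arithmetic", {
  ft <- friedman_rank_test(rbind(c(10, 20, 30), c(1, 2, 3)))
  expect_equal(ft$statistic, 4)
  expect_equal(ft$df, 2)
  expect_equal(ft$p_value, pchisq(4, 2, lower.tail = FALSE))
})

test_that("friedman statistic is zero for identical treatments and warns on full ties", {
  expect_warning(
    ft <- friedman_rank_test(matrix(5, nrow = 3, ncol = 4)),
    "tied"
  )
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)
})

test_that("friedman statistic is invariant under within-block monotone transforms", {
  withr::with_seed(8, {
    x <- matrix(runif(40), 8, 5)
  })
  f1 <- friedman_rank_test(x)
  f2 <- friedman_rank_test(exp(4 * x))
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-12)
})

test_that("friedman_rank_test matches stats::friedman.test with and without ties", {
  withr::with_seed(21, {
    for (i in 1:20) {
      B <- sample(3:12, 1)
      k <- sample(3:6, 1)
      x <- matrix(sample(1:5, B * k, replace = TRUE) + (i %% 2) * runif(B * k), B, k)
      if (any(apply(x, 1, function(r) length(unique(r))) == 1)) next
      mine <- friedman_rank_test(x)
      ref <- stats::friedman.test(x)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
    }
  })
})

test_that("pairwise stage matrices have zero diagonal and transpose symmetry", {
  tbl <- toy_expression(10, species = c("A", "B"), stages = paste0("s", 1:4))
  self <- dplyr::bind_rows(
    tbl[tbl$species == "A", ],
    dplyr::mutate(tbl[tbl$species == "A", ], species = "A2")
  )
  m_self <- pairwise_stage_matrix(self, c("A", "A2"))
  diag_vals <- m_self$expdist[m_self$stage_a == m_self$stage_b]
  expect_true(all(abs(diag_vals) < 1e-12))

  m_ab <- pairwise_stage_matrix(tbl, c("A", "B"))
  m_ba <- pairwise_stage_matrix(tbl, c("B", "A"))
  m <- merge(
    as.data.frame(m_ab),
    as.data.frame(m_ba),
    by.x = c("stage_a", "stage_b"), by.y = c("stage_b", "stage_a")
  )
  expect_equal(m$expdist.x, m$expdist.y, tolerance = 1e-12)

  # element-wise against scalar expdist on replicate-averaged profiles
  avg <- aggregate_replicates(restrict_to_shared_groups(tbl))
  xa <- avg$tpm[avg$species == "A" & avg$stage == "s2"]
  xb <- avg$tpm[avg$species == "B" & avg$stage == "s3"]
  got <- m_ab$expdist[m_ab$stage_a == "s2" & m_ab$stage_b == "s3"]
  expect_equal(got, expdist(xa, xb), tolerance = 1e-12)
})
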