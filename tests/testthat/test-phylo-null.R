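test_that("patristic distances: hand values, zero cherry, triangle", {
  pd <- patristic_matrix(four_tip_tree())
  expect_equal(pd["A", "B"], 2)
  expect_equal(pd["A", "C"], 4)
  expect_equal(pd["C", "D"], 2)
  cherry <- ape::read.tree(text = "((A:0,B:0):1,C:2);")
  expect_equal(patristic_matrix(cherry)["A", "B"], 0)
  set.seed(10)
  for (i in 1:5) {
    tr <- random_tree(sample(4:12, 1))
    pd <- patristic_matrix(tr)
    # against the independent root-path oracle
    tips <- sample(tr$tip.label, 2)
    expect_equal(pd[tips[1], tips[2]],
                 oracle_patristic(tr, tips[1], tips[2]), tolerance = 1e-10)
    # triangle inequality over all triples
    n <- nrow(pd)
    worst <- max(vapply(seq_len(n), function(c) {
      max(pd - outer(pd[, c], pd[c, ], "+"))
    }, numeric(1)))
    expect_lte(worst, 1e-12)
  }
})

test_that("betaMNTD reproduces the worked examples exactly", {
  tr <- four_tip_tree()
  m <- rbind(S1 = c(A = 0.5, B = 0.5, C = 0, D = 0),
             S2 = c(A = 0, B = 0, C = 0.5, D = 0.5))
  b <- as.matrix(beta_mntd(m, tr))
  expect_equal(b["S1", "S2"], 4)
  m2 <- rbind(S1 = c(A = 1, B = 0, C = 0, D = 0),
              S2 = c(A = 0.5, B = 0.5, C = 0, D = 0))
  expect_equal(as.matrix(beta_mntd(m2, tr))["S1", "S2"], 0.5)
  # identical membership: every taxon's nearest neighbour is itself
  m3 <- rbind(S1 = c(A = 0.2, B = 0.8, C = 0, D = 0),
              S2 = c(A = 0.7, B = 0.3, C = 0, D = 0))
  expect_equal(as.matrix(beta_mntd(m3, tr))["S1", "S2"], 0)
})

test_that("betaMNTD equals the naive triple-loop oracle on random cases", {
  set.seed(20)
  for (i in 1:10) {
    tr <- random_tree(sample(5:15, 1))
    m <- random_table(sample(3:8, 1), length(tr$tip.label))
    pd <- patristic_matrix(tr)
    for (w in c(TRUE, FALSE)) {
      expect_equal(as.matrix(beta_mntd(m, pd, weighted = w)),
                   oracle_beta_mntd(m, pd, weighted = w), tolerance = 1e-10)
    }
  }
})

test_that("betaMNTD agrees with picante's comdistnt cross-check", {
  skip_if_not_installed("picante")
  set.seed(21)
  tr <- random_tree(12)
  m <- random_table(5, 12)
  ours <- as.matrix(beta_mntd(m, tr, weighted = TRUE))
  theirs <- as.matrix(picante::comdistnt(m, patristic_matrix(tr),
                                         abundance.weighted = TRUE))
  expect_equal(ours[rownames(theirs), colnames(theirs)], theirs,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("tip shuffling preserves the patristic distance multiset", {
  tr <- random_tree(10)
  pd <- patristic_matrix(tr)
  set.seed(3)
  perm <- sample(10)
  expect_equal(sort(lower_vec(pd[perm, perm])), sort(lower_vec(pd)))
})

test_that("betaNTI is seeded, matches a brute-force null mean, and masks
           degenerate pairs", {
  set.seed(30)
  tr <- random_tree(15)
  m <- random_table(5, 15)
  cfg <- null_model_config(n_null = 999, seed = 77)
  a <- beta_nti(m, tr, cfg)
  b <- beta_nti(m, tr, cfg)
  expect_identical(as.matrix(a$bnti), as.matrix(b$bnti))
  # brute-force re-implementation of the null mean via the oracle betaMNTD
  pd <- patristic_matrix(tr)[colnames(m), colnames(m)]
  set.seed(123)
  nulls <- replicate(999, {
    p <- sample(15)
    pdp <- pd[p, p]
    dimnames(pdp) <- dimnames(pd)  # shuffle taxa across tips = relabel
    oracle_beta_mntd(m, pdp)["S01", "S02"]
  })
  se <- sd(nulls) / sqrt(999)
  expect_lt(abs(a$null_mean["S01", "S02"] - mean(nulls)), 3 * se)
  # identical communities: observed and all nulls are 0 -> degenerate mask
  m_id <- rbind(S1 = c(rep(1, 15)), S2 = c(rep(1, 15)))
  colnames(m_id) <- colnames(m)
  r <- beta_nti(m_id, tr, null_model_config(n_null = 99, seed = 1))
  expect_true(r$degenerate["S1", "S2"])
  expect_true(is.na(as.matrix(r$bnti)["S1", "S2"]))
  expect_error(null_model_config(n_null = 50), "99")
})

test_that("RC-BC hits the rank extremes and stays within [-1, 1]", {
  # two identical samples: observed BC = 0, below every null draw
  m <- rbind(S1 = c(8, 6, 4, 2, 2, 2), S2 = c(8, 6, 4, 2, 2, 2),
             S3 = c(1, 2, 8, 5, 3, 1), S4 = c(2, 1, 2, 9, 4, 6))
  colnames(m) <- paste0("u", 1:6)
  rc <- as.matrix(raup_crick_bc(m, null_model_config(199, seed = 2)))
  expect_equal(rc["S1", "S2"], -1)
  # disjoint supports; a 16-species pool with 8+8 richness makes a disjoint
  # null pair (the only way to tie the observed BC of 1) vanishingly rare
  m2 <- rbind(S1 = c(rep(4, 8), rep(0, 8)), S2 = c(rep(0, 8), rep(4, 8)),
              S3 = rep(3, 16), S4 = rep(c(2, 4), 8))
  colnames(m2) <- paste0("u", 1:16)
  rc2 <- as.matrix(raup_crick_bc(m2, null_model_config(199, seed = 3)))
  expect_equal(rc2["S1", "S2"], 1)
  expect_true(all(abs(rc2[lower.tri(rc2)]) <= 1))
  expect_error(raup_crick_bc(m / 2), "non-integer")
})

test_that("the five-process decision table follows the thresholds strictly", {
  bnti_grid <- c(-3, -2.01, -2, -1, 0, 1.99, 2, 2.01, 3.1)
  rc_grid <- c(-1, -0.96, -0.95, -0.5, 0, 0.5, 0.95, 0.96, 0.99)
  grid <- expand.grid(bnti = bnti_grid, rc = rc_grid)
  got <- betanull:::classify_pair(grid$bnti, grid$rc)
  want <- ifelse(grid$bnti > 2, "heterogeneous_selection",
          ifelse(grid$bnti < -2, "homogeneous_selection",
          ifelse(grid$rc > 0.95, "dispersal_limitation",
          ifelse(grid$rc < -0.95, "homogenizing_dispersal", "drift"))))
  expect_identical(got, want)
  # the +/-2 boundary itself is stochastic; +/-0.95 itself is drift
  expect_identical(unique(got[grid$bnti == 2 & abs(grid$rc) == 0.95]),
                   "drift")
  expect_identical(unique(got[grid$bnti == -2 & abs(grid$rc) == 0.95]),
                   "drift")
})

test_that("classification fractions partition the classified pairs", {
  labs <- paste0("S", 1:5)
  bnti <- matrix(0, 5, 5, dimnames = list(labs, labs))
  rc <- matrix(0, 5, 5, dimnames = list(labs, labs))
  bnti[2, 1] <- bnti[1, 2] <- 3.1    # heterogeneous regardless of RC
  bnti[3, 1] <- bnti[1, 3] <- -2.5   # homogeneous
  rc[4, 1] <- rc[1, 4] <- 0.99       # dispersal limitation (bnti 0.4)
  bnti[4, 1] <- bnti[1, 4] <- 0.4
  rc[5, 1] <- rc[1, 5] <- -0.99      # homogenizing dispersal
  res <- classify_processes(pairwise_matrix(bnti, "bnti"),
                            pairwise_matrix(rc, "rc"))
  expect_equal(sum(res$fractions$fraction), 1)
  expect_equal(res$n_classified, 10)
  got <- res$pairs$process[res$pairs$sample_b == "S1" |
                             res$pairs$sample_a == "S1"]
  expect_setequal(
    res$pairs$process[res$pairs$sample_a == "S1" |
                        res$pairs$sample_b == "S1"],
    c("heterogeneous_selection", "homogeneous_selection",
      "dispersal_limitation", "homogenizing_dispersal"))
  expect_true(all(res$fractions$fraction >= 0))
  # selection labels occur only where |betaNTI| > 2
  sel <- res$pairs$process %in% c("heterogeneous_selection",
                                  "homogeneous_selection")
  expect_true(all(abs(res$pairs$bnti[sel]) > 2))
})

test_that("RC-BC under its own generative null is centred", {
  set.seed(55)
  base <- random_table(10, 60, max_count = 50)
  nulltab <- draw_rc_null(base, seed = 5)
  m <- as_count_matrix(nulltab)
  expect_equal(rowSums(m), rowSums(base))
  expect_equal(rowSums(m > 0), rowSums(base > 0))
  rc <- raup_crick_bc(nulltab, null_model_config(199, seed = 6))
  v <- tidy(rc)$value
  expect_lt(abs(mean(v)), 0.25)
})
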