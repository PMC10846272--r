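test_that("NMDS embeds planar configurations nearly perfectly", {
  set.seed(40)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("S", 1:10), paste0("S", 1:10))
  fit <- nmds(d, n_dim = 2, n_restarts = 5, seed = 1)
  expect_lt(fit$stress, 1e-3)
  expect_lte(fit$stress, fit$stress_metric_start + 1e-12)
  expect_error(nmds(d[1:3, 1:3], n_dim = 2), "n_dim")
})

test_that("NMDS separates the selection scenario's groups", {
  d <- simulate_dataset(sim_scenario("heterogeneous_selection", n_otus = 80,
                                     n_samples = 12,
                                     reads_per_sample = 2000), seed = 41)
  fit <- nmds(bray_curtis(d$table), seed = 2)
  sc <- as.matrix(fit$scores[-1])
  grp <- d$metadata$group
  within <- c(dist(sc[grp == "G1", ]), dist(sc[grp == "G2", ]))
  between <- as.matrix(dist(sc))[grp == "G1", grp == "G2"]
  expect_gt(mean(between), mean(within))
})

test_that("ANOSIM matches its formula oracle and vegan on random cases", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    m <- random_table(n, 10)
    d <- as.matrix(bray_curtis(m))
    grp <- sample(rep(c("a", "b"), length.out = n))
    fit <- anosim(d, grp, n_perm = 99, seed = i)
    expect_equal(fit$statistic, oracle_anosim_r(d, grp), tolerance = 1e-10)
    veg <- vegan::anosim(stats::as.dist(d), grouping = grp,
                         permutations = 0)
    expect_equal(fit$statistic, unname(veg$statistic), tolerance = 1e-10)
  }
})

test_that("ANOSIM: perfect separation gives R = 1; label swap is symmetric", {
  # construct distances where all between-pairs exceed all within-pairs
  d <- matrix(0, 6, 6, dimnames = list(paste0("S", 1:6), paste0("S", 1:6)))
  grp <- rep(c("x", "y"), each = 3)
  for (i in 1:5) for (j in (i + 1):6) {
    d[i, j] <- d[j, i] <- if (grp[i] == grp[j]) runif(1, 0, 0.2) else
      runif(1, 0.5, 1)
  }
  fit <- anosim(d, grp, n_perm = 99, seed = 1)
  expect_equal(fit$statistic, 1)
  swapped <- anosim(d, rev(grp), n_perm = 99, seed = 1)
  expect_equal(abs(swapped$statistic), abs(fit$statistic))
  expect_gt(fit$p_value, 0)
})

test_that("pairwise ANOSIM skips singleton groups with a warning", {
  set.seed(43)
  m <- random_table(7, 8)
  d <- as.matrix(bray_curtis(m))
  grp <- c("a", "a", "a", "b", "b", "b", "c")
  w <- capture_warnings(fit <- anosim(d, grp, n_perm = 49, seed = 2,
                                      pairwise = TRUE))
  expect_match(w, "single member", all = TRUE)
  expect_length(w, 2)  # the two pairs involving group "c"
  pw <- fit$pairwise
  expect_true(is.na(pw$statistic[pw$group_a == "a" & pw$group_b == "c"]))
  expect_false(is.na(pw$statistic[pw$group_a == "a" & pw$group_b == "b"]))
})

test_that("SIMPER decomposition: hand case, identity, oracle", {
  m <- rbind(S1 = c(5, 5, 0), S2 = c(0, 5, 5))
  colnames(m) <- paste0("u", 1:3)
  out <- simper(m, c("g1", "g2"))
  expect_equal(out$average[match(paste0("u", 1:3), out$otu_id)],
               c(0.25, 0, 0.25))
  # per-pair contributions sum to the pair's Bray-Curtis
  expect_equal(sum(out$average), as.matrix(bray_curtis(m))["S1", "S2"],
               tolerance = 1e-12)
  # identical groups -> all contributions zero
  m2 <- rbind(S1 = c(3, 2, 1), S2 = c(3, 2, 1))
  colnames(m2) <- paste0("u", 1:3)
  expect_equal(simper(m2, c("g1", "g2"))$average, rep(0, 3))
  set.seed(44)
  for (i in 1:5) {
    r <- random_table(6, 9)
    grp <- rep(c("a", "b"), each = 3)
    got <- simper(r, grp)
    want <- oracle_simper(r, grp, "a", "b")
    expect_equal(got$average, unname(want[got$otu_id]), tolerance = 1e-10)
  }
})

test_that("SIMPER agrees with vegan's average contributions", {
  set.seed(45)
  m <- random_table(8, 10)
  grp <- rep(c("a", "b"), each = 4)
  ours <- simper(m, grp)
  veg <- summary(vegan::simper(m, grp, permutations = 0))$a_b
  expect_equal(ours$average[match(rownames(veg), ours$otu_id)],
               veg$average, tolerance = 1e-10)
})

test_that("VIF pruning drops collinear and constant variables", {
  set.seed(46)
  x <- rnorm(30)
  env <- data.frame(a = x, b = 2 * x + 1e-9 * rnorm(30), c = rnorm(30))
  out <- vif_prune(env, threshold = 10)
  expect_length(out$dropped, 1)
  expect_true(all(out$vif$vif <= 10))
  # orthogonal variables all kept with VIF near 1
  q <- qr.Q(qr(matrix(rnorm(60), 20, 3)))
  env2 <- as.data.frame(q); names(env2) <- c("p", "q", "r")
  out2 <- vif_prune(env2)
  expect_length(out2$dropped, 0)
  expect_equal(out2$vif$vif, rep(1, 3), tolerance = 1e-2)
  env3 <- data.frame(a = rnorm(10), k = rep(1, 10))
  expect_warning(out3 <- vif_prune(env3), "constant")
  expect_identical(out3$dropped, "k")
})

test_that("VIF values match the least-squares 1/(1-R2) oracle", {
  set.seed(47)
  a <- rnorm(40); b <- 0.6 * a + rnorm(40); c <- rnorm(40)
  env <- data.frame(a = a, b = b, c = c)
  out <- vif_prune(env, threshold = 100)
  r2_a <- summary(lm(a ~ b + c))$r.squared
  expect_equal(out$vif$vif[out$vif$variable == "a"], 1 / (1 - r2_a),
               tolerance = 1e-10)
})

test_that("CCA inertia identities hold", {
  set.seed(48)
  m <- random_table(10, 12)
  # total inertia equals the chi-square statistic over the grand total
  fit <- constrained_ordination(m, data.frame(z = rnorm(10)), n_perm = 99,
                                seed = 1)
  exp_chi <- suppressWarnings(chisq.test(m)$statistic)
  expect_equal(fit$total_inertia, unname(exp_chi) / sum(m),
               tolerance = 1e-10)
  expect_lte(fit$constrained_inertia, fit$total_inertia)
  # saturated dummy predictors absorb all inertia
  dummy <- as.data.frame(model.matrix(~ 0 + factor(seq_len(10)))[, 1:9])
  names(dummy) <- paste0("d", 1:9)
  sat <- constrained_ordination(m, dummy, n_perm = 99, seed = 2)
  expect_equal(sat$constrained_inertia, sat$total_inertia,
               tolerance = 1e-8)
  expect_error(constrained_ordination(m, cbind(dummy, extra = rnorm(10))),
               "samples - 1")
})

test_that("CCA recovers a strong synthetic gradient", {
  d <- simulate_dataset(sim_scenario("heterogeneous_selection", n_otus = 100,
                                     n_samples = 14,
                                     reads_per_sample = 3000), seed = 49)
  env <- data.frame(temperature = d$metadata$temperature)
  fit <- constrained_ordination(d$table, env, n_perm = 199, seed = 3)
  expect_gt(abs(cor(fit$scores$CCA1, d$metadata$temperature)), 0.9)
  expect_lt(fit$terms$p_value[1], 0.05)
})

test_that("water-mass clustering finds the planted k by silhouette", {
  set.seed(50)
  md2 <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:12),
    temperature = c(rnorm(6, 22, 0.2), rnorm(6, 29, 0.2)),
    salinity = c(rnorm(6, 34.4, 0.05), rnorm(6, 33.4, 0.05)))
  fit2 <- cluster_water_masses(md2, k_range = 2:5)
  expect_equal(fit2$k, 2)
  expect_gt(fit2$silhouette, 0.7)
  # three water masses with distinct temperature/salinity centroids
  md3 <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:15),
    temperature = c(rnorm(5, 22, 0.3), rnorm(5, 29.5, 0.3),
                    rnorm(5, 25, 0.3)),
    salinity = c(rnorm(5, 33.6, 0.05), rnorm(5, 33.9, 0.05),
                 rnorm(5, 34.5, 0.05)))
  fit3 <- cluster_water_masses(md3, k_range = 2:6)
  expect_equal(fit3$k, 3)
  # deterministic labels on repeated runs
  expect_identical(tidy(fit3), tidy(cluster_water_masses(md3,
                                                         k_range = 2:6)))
  expect_error(cluster_water_masses(md3, k_range = 2:20), "k_range")
  expect_error(cluster_water_masses(md3[-2], ), "lacks variable")
})
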