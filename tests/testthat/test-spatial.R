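test_that("geographic distances: models, hand value, symmetry", {
  md <- tibble::tibble(sample_id = c("A", "B", "C"),
                       lat = c(0, 0, 10), lon = c(0, 1, 10))
  g <- geo_distances(md, model = "sphere")
  expect_equal(as.matrix(g)["A", "A"], 0)
  # one degree of longitude at the equator, R = 6371 km
  expect_equal(as.matrix(g)["A", "B"], 6371 * pi / 180, tolerance = 1e-4)
  gs <- geo_distances(md, model = "spheroid")
  expect_equal(as.matrix(gs)["A", "B"], 111.32, tolerance = 1e-2)
  set.seed(60)
  md2 <- tibble::tibble(sample_id = paste0("S", 1:6),
                        lat = runif(6, -60, 60), lon = runif(6, -170, 170))
  for (model in c("sphere", "spheroid")) {
    m <- as.matrix(geo_distances(md2, model = model))
    expect_equal(m, t(m), tolerance = 1e-9)
  }
  md3 <- tibble::tibble(sample_id = c("A", "B"), x = c(0, 3), y = c(0, 4))
  expect_equal(as.matrix(geo_distances(md3, model = "planar"))["A", "B"], 5)
  expect_error(geo_distances(tibble::tibble(sample_id = "A", lat = 1,
                                            lon = NA), "sphere"), "missing")
})

test_that("Mantel r equals the naive vectorized-correlation oracle", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    a <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    b <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    for (meth in c("pearson", "spearman")) {
      fit <- mantel(a, b, method = meth, n_perm = 49, seed = i)
      expect_equal(fit$r, oracle_mantel_r(a, b, meth), tolerance = 1e-12)
    }
  }
  a <- as.matrix(dist(matrix(rnorm(12), 6)))
  fit <- mantel(a, a, n_perm = 99, seed = 1)
  expect_equal(fit$r, 1)
  expect_error(mantel(a, matrix(0, 6, 6)), "constant")
})

test_that("Mantel agrees with vegan's statistic", {
  set.seed(62)
  a <- as.matrix(dist(matrix(rnorm(16), 8)))
  b <- as.matrix(dist(matrix(rnorm(16), 8)))
  ours <- mantel(a, b, n_perm = 49, seed = 1)
  veg <- vegan::mantel(stats::as.dist(a), stats::as.dist(b),
                       permutations = 0)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
})

test_that("partial Mantel equals the residual-correlation route", {
  set.seed(63)
  n <- 8
  a <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  b <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  cc <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  fit <- partial_mantel(a, b, cc, n_perm = 49, seed = 1)
  lv <- function(m) m[lower.tri(m)]
  ra <- residuals(lm(lv(a) ~ lv(cc)))
  rb <- residuals(lm(lv(b) ~ lv(cc)))
  expect_equal(fit$r, cor(ra, rb), tolerance = 1e-10)
  # controlling for the second matrix itself is degenerate
  expect_error(partial_mantel(a, b, b, n_perm = 49, seed = 2),
               "collinear")
})

test_that("distance decay responds to the dispersal chain and log1p is
           rank-neutral", {
  d <- simulate_dataset(sim_scenario("dispersal_limitation", n_otus = 100,
                                     n_samples = 12,
                                     reads_per_sample = 2000, n_eff = 200),
                        seed = 64)
  g <- geo_distances(d$metadata, model = "sphere")
  dd <- distance_decay(d$table, g, n_perm = 199, seed = 1)
  expect_lt(dd$mantel$r, 0)
  expect_lt(dd$mantel$p_value, 0.05)
  dd_log <- distance_decay(d$table, g, n_perm = 199, seed = 1,
                           log_transform = TRUE)
  expect_equal(dd$mantel$r, dd_log$mantel$r, tolerance = 1e-12)
  expect_equal(nrow(dd$scatter), 12 * 11 / 2)
  # a well-mixed community shows no decay
  d2 <- simulate_dataset(sim_scenario("homogenizing_dispersal", n_otus = 100,
                                      n_samples = 12,
                                      reads_per_sample = 2000,
                                      n_eff = 2000), seed = 65)
  dd2 <- distance_decay(d2$table, geo_distances(d2$metadata, "sphere"),
                        n_perm = 199, seed = 2)
  expect_lt(abs(dd2$mantel$r), 0.35)
})

test_that("PCNM eigenvectors are centred, orthonormal and transect-ordered", {
  md <- tibble::tibble(sample_id = sprintf("S%02d", 1:10),
                       x = seq(0, 90, by = 10), y = 0)
  g <- geo_distances(md, model = "planar")
  v <- pcnm_vectors(g)
  vm <- as.matrix(v[-1])
  expect_lte(ncol(vm), 9)
  expect_equal(unname(colMeans(vm)), rep(0, ncol(vm)), tolerance = 1e-10)
  expect_equal(unname(crossprod(vm)), diag(ncol(vm)), tolerance = 1e-8)
  # the leading vectors trace sinusoids of increasing frequency along the
  # transect; with the default (minimum-spanning-tree) truncation the first
  # axis orders positions strongly, and with an untruncated matrix exactly
  expect_gt(abs(cor(vm[, 1], seq_len(10), method = "spearman")), 0.8)
  v_wide <- pcnm_vectors(g, truncation = 100)
  vw <- as.matrix(v_wide[-1])
  expect_equal(abs(cor(vw[, 1], seq_len(10), method = "spearman")), 1)
  expect_error(pcnm_vectors(matrix(0, 3, 3)), "degenerate")
})

test_that("second-community predictors are orthogonal PCoA axes", {
  set.seed(66)
  m <- rbind(random_table(4, 10) + 30, random_table(4, 10))
  rownames(m) <- paste0("S", 1:8)
  ax <- community_as_predictors(m, k = 2)
  am <- as.matrix(ax[-1])
  expect_equal(abs(crossprod(am[, 1], am[, 2])[1]), 0, tolerance = 1e-8)
  # k = 1 separates two compositional clusters
  clus <- rep(c(1, 2), each = 4)
  ax1 <- community_as_predictors(m, k = 1)$Axis1
  expect_true(max(ax1[clus == 1]) < min(ax1[clus == 2]) ||
                min(ax1[clus == 1]) > max(ax1[clus == 2]))
  expect_error(community_as_predictors(m, k = 8), "below")
})

test_that("variation partitioning closes to 1 and calibrates on noise", {
  set.seed(67)
  for (i in 1:5) {
    m <- random_table(12, 20)
    e <- data.frame(e1 = rnorm(12), e2 = rnorm(12))
    b <- data.frame(b1 = rnorm(12))
    s <- data.frame(s1 = rnorm(12), s2 = rnorm(12))
    vp <- varpart3(m, e, b, s, n_perm = 99, seed = i)
    expect_equal(sum(vp$fractions$adj_r_squared), 1, tolerance = 1e-12)
  }
  # a response driven by E alone (species-specific slopes so that
  # composition, not just totals, tracks the gradient): pure E dominates
  e_drive <- rnorm(12)
  slopes <- seq(-1.2, 1.2, length.out = 20)
  resp <- sapply(1:20, function(k) rpois(12, exp(2 + slopes[k] * e_drive)))
  rownames(resp) <- paste0("S", 1:12)
  colnames(resp) <- paste0("u", 1:20)
  vp2 <- varpart3(resp, data.frame(e = e_drive), data.frame(b = rnorm(12)),
                  data.frame(s = rnorm(12)), n_perm = 199, seed = 9)
  f <- setNames(vp2$fractions$adj_r_squared, vp2$fractions$fraction)
  expect_gt(f["E_pure"], 0.2)
  expect_lt(abs(f["B_pure"]), 0.1)
  expect_lt(abs(f["S_pure"]), 0.1)
  expect_lt(vp2$tests$p_value[vp2$tests$fraction == "E_pure"], 0.05)
  expect_error(varpart3(random_table(6, 8), data.frame(a = rnorm(6),
                                                       b = rnorm(6)),
                        data.frame(c = rnorm(6)), data.frame(d = rnorm(6),
                                                             e = rnorm(6))),
               "saturated")
})

test_that("a block built from the response itself dominates the partition", {
  set.seed(68)
  m <- random_table(12, 25)
  b_axes <- community_as_predictors(m, k = 3)
  vp <- varpart3(m, data.frame(e = rnorm(12)), b_axes,
                 data.frame(s = rnorm(12)), n_perm = 99, seed = 1)
  f <- setNames(vp$fractions$adj_r_squared, vp$fractions$fraction)
  expect_gt(f["B_pure"], f["E_pure"])
  expect_gt(f["B_pure"], f["S_pure"])
})
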