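# Ordination and group statistics: NMDS, ANOSIM, SIMPER, VIF pruning, CCA
# with permutation significance, and medoid water-mass clustering.

#' Nonmetric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 by iterative monotone regression
#' ([vegan::monoMDS()]) from a metric-MDS (principal coordinates) start plus
#' `n_restarts` random starts; the best configuration is returned. Ties in
#' the monotone regression receive primary treatment (tied dissimilarities
#' averaged).
#'
#' @param d Dissimilarity as a [pairwise_matrix()], `dist` or square matrix.
#' @param n_dim Number of ordination dimensions.
#' @param n_restarts Number of random restarts in addition to the metric
#'   start.
#' @param max_iter Maximum iterations per start.
#' @param seed Optional RNG seed.
#' @return Object of class `nmds_ord`: `scores` tibble, `stress` (in
#'   `[0, 1]`), `stress_metric_start`, `n_dim`.
#' @export
nmds <- function(d, n_dim = 2, n_restarts = 20, max_iter = 200, seed = NULL) {
  m <- as_square(d)
  n <- nrow(m)
  if (n <= n_dim + 1) {
    stop("need more than n_dim + 1 samples for NMDS", call. = FALSE)
  }
  dd <- stats::as.dist(m)
  run <- function() {
    y0 <- cmdscale(dd, k = n_dim, add = TRUE)$points
    fit_from <- function(y) {
      vegan::monoMDS(dd, y = y, k = n_dim, model = "global",
                     maxit = max_iter)
    }
    best <- fit_from(y0)
    metric_stress <- best$stress
    for (r in seq_len(n_restarts)) {
      cand <- fit_from(matrix(rnorm(n * n_dim), n, n_dim))
      if (cand$stress < best$stress) best <- cand
    }
    list(best = best, metric_stress = metric_stress)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  pts <- res$best$points
  colnames(pts) <- paste0("NMDS", seq_len(n_dim))
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                              tibble::as_tibble(pts)),
    stress = res$best$stress,
    stress_metric_start = res$metric_stress,
    n_dim = n_dim
  ), class = "nmds_ord")
}

#' @export
print.nmds_ord <- function(x, ...) {
  cat(sprintf("NMDS (%d dims, %d samples), stress-1 = %.4f\n",
              x$n_dim, nrow(x$scores), x$stress))
  invisible(x)
}

# ANOSIM R on a dissimilarity matrix given group labels
anosim_r <- function(m, groups) {
  same <- outer(groups, groups, "==")
  dv <- lower_vec(m)
  within <- lower_vec(same)
  rk <- rank(dv)
  n_pairs <- length(dv)
  (mean(rk[!within]) - mean(rk[within])) / (n_pairs / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2` and ranks taken over all pairwise dissimilarities; the
#' permutation p-value uses the add-one convention (never exactly 0).
#'
#' @param d Dissimilarity matrix ([pairwise_matrix()], `dist` or matrix).
#' @param groups Group label per sample (>= 2 groups of >= 2 members for the
#'   global test).
#' @param n_perm Number of label permutations.
#' @param seed Optional RNG seed.
#' @param pairwise Also run every two-group comparison.
#' @return Object of class `anosim_result` with `statistic`, `p_value`,
#'   `n_perm`, and a `pairwise` tibble if requested.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL, pairwise = FALSE) {
  m <- as_square(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) {
    stop("groups length does not match the matrix", call. = FALSE)
  }
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  run_test <- function(mm, gg) {
    obs <- anosim_r(mm, gg)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (anosim_r(mm, sample(gg)) >= obs - 1e-12) hits <- hits + 1L
    }
    c(statistic = obs, p_value = (1 + hits) / (1 + n_perm))
  }
  run <- function() {
    global <- run_test(m, groups)
    pw <- NULL
    if (pairwise) {
      combos <- combn(names(sizes), 2L)
      pw <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
        g1 <- combos[1L, j]; g2 <- combos[2L, j]
        if (sizes[g1] < 2 || sizes[g2] < 2) {
          warning("skipping pair ", g1, " vs ", g2,
                  ": a group has a single member", call. = FALSE)
          return(tibble::tibble(group_a = g1, group_b = g2,
                                statistic = NA_real_, p_value = NA_real_))
        }
        keep <- groups %in% c(g1, g2)
        r <- run_test(m[keep, keep, drop = FALSE], groups[keep])
        tibble::tibble(group_a = g1, group_b = g2,
                       statistic = r[["statistic"]], p_value = r[["p_value"]])
      })
    }
    list(global = global, pairwise = pw)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(statistic = unname(res$global["statistic"]),
                 p_value = unname(res$global["p_value"]),
                 n_perm = n_perm, groups = groups, pairwise = res$pairwise),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: Global R = %.3f, P = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Similarity percentages (SIMPER)
#'
#' Decomposes between-group Bray-Curtis dissimilarity into per-OTU
#' contributions: for a sample pair `(x, y)` the contribution of OTU i is
#' `|x_i - y_i| / (sum(x) + sum(y))`, so contributions sum exactly to the
#' pair's Bray-Curtis. Contributions are averaged over all between-group
#' pairs and ranked.
#'
#' @param table Community table.
#' @param groups Group label per sample.
#' @return Tibble with one row per comparison x OTU: `comparison`, `otu_id`,
#'   `average` (mean contribution), `rank`, `cumulative_pct`.
#' @export
simper <- function(table, groups) {
  m <- as_count_matrix(table)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) {
    stop("groups length does not match the table", call. = FALSE)
  }
  lv <- unique(groups)
  if (length(lv) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  combos <- combn(lv, 2L)
  purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    g1 <- which(groups == combos[1L, j])
    g2 <- which(groups == combos[2L, j])
    contrib <- matrix(0, length(g1) * length(g2), ncol(m))
    r <- 0L
    for (a in g1) for (b in g2) {
      r <- r + 1L
      contrib[r, ] <- abs(m[a, ] - m[b, ]) / (sum(m[a, ]) + sum(m[b, ]))
    }
    avg <- colMeans(contrib)
    ord <- order(avg, decreasing = TRUE)
    tibble::tibble(
      comparison = paste(combos[, j], collapse = " vs "),
      otu_id = colnames(m)[ord],
      average = avg[ord],
      rank = seq_along(avg),
      cumulative_pct = 100 * cumsum(avg[ord]) / sum(avg)
    )
  })
}

#' Iterative variance-inflation-factor pruning
#'
#' Repeatedly drops the variable with the largest VIF
#' (`VIF_i = 1 / (1 - R_i^2)` from regressing variable i on the others) until
#' all VIF are at or below `threshold`. Constant variables are dropped first
#' with a warning.
#'
#' @param env Data frame of numeric explanatory variables (>= 2 columns).
#' @param threshold Maximum tolerated VIF (10 by convention).
#' @return List with `kept` (data frame), `dropped` (character), and `vif`
#'   (tibble of final VIFs).
#' @export
vif_prune <- function(env, threshold = 10) {
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric variable(s): ", paste(names(env)[!num], collapse = ", "),
         call. = FALSE)
  }
  if (ncol(env) < 2) stop("need at least 2 variables", call. = FALSE)
  dropped <- character()
  const <- vapply(env, function(x) var(x) == 0, logical(1))
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(names(env)[const], collapse = ", "), call. = FALSE)
    dropped <- names(env)[const]
    env <- env[!const]
  }
  vifs_of <- function(df) {
    vapply(seq_along(df), function(i) {
      r2 <- summary(lm(df[[i]] ~ ., data = df[-i]))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  while (ncol(env) >= 2) {
    v <- vifs_of(env)
    if (max(v) <= threshold) break
    worst <- which.max(v)
    dropped <- c(dropped, names(env)[worst])
    env <- env[-worst]
  }
  v <- if (ncol(env) >= 2) vifs_of(env) else rep(1, ncol(env))
  list(kept = env, dropped = dropped,
       vif = tibble::tibble(variable = names(env), vif = v))
}

#' Canonical correspondence analysis with permutation tests
#'
#' Constrained ordination of the community table on standardized
#' environmental variables (via [vegan::cca()]); marginal per-variable
#' significance by permutation ([vegan::anova.cca()] with `by = "margin"`).
#' An `rda` switch runs redundancy analysis instead when the community
#' gradient is short.
#'
#' @param table Community table.
#' @param env Data frame of explanatory variables (pre-prune with
#'   [vif_prune()]).
#' @param n_perm Number of permutations for significance tests.
#' @param seed Optional RNG seed.
#' @param method `"cca"` (default) or `"rda"`.
#' @return Object of class `cca_ord`: eigenvalues, total and constrained
#'   inertia, sample scores, biplot scores, per-variable `terms` tibble.
#' @export
constrained_ordination <- function(table, env, n_perm = 999, seed = NULL,
                                   method = c("cca", "rda")) {
  method <- match.arg(method)
  m <- as_count_matrix(table)
  env <- as.data.frame(env)
  env <- env[setdiff(names(env), "sample_id")]
  if (ncol(env) > nrow(m) - 1) {
    stop("more explanatory variables than samples - 1", call. = FALSE)
  }
  fit_fun <- if (method == "cca") vegan::cca else vegan::rda
  mod <- fit_fun(m ~ ., data = env)
  run <- function() {
    an <- vegan::anova.cca(mod, by = "margin", permutations = n_perm)
    tibble::tibble(
      variable = rownames(an)[seq_len(nrow(an) - 1L)],
      chi_square = an[seq_len(nrow(an) - 1L), 1L],
      f_statistic = an$F[seq_len(nrow(an) - 1L)],
      p_value = an$`Pr(>F)`[seq_len(nrow(an) - 1L)]
    )
  }
  terms <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  sc <- vegan::scores(mod, display = c("sites", "bp"), scaling = 2)
  n_ax <- ncol(sc$sites)
  structure(list(
    method = method,
    eigenvalues = mod$CCA$eig,
    total_inertia = mod$tot.chi,
    constrained_inertia = mod$CCA$tot.chi,
    scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                              tibble::as_tibble(sc$sites)),
    biplot = dplyr::bind_cols(
      tibble::tibble(variable = rownames(sc$biplot)),
      tibble::as_tibble(sc$biplot)),
    terms = terms,
    model = mod
  ), class = "cca_ord")
}

#' @export
print.cca_ord <- function(x, ...) {
  cat(sprintf("%s: constrained %.3f of %.3f total inertia (%.1f%%)\n",
              toupper(x$method), x$constrained_inertia, x$total_inertia,
              100 * x$constrained_inertia / x$total_inertia))
  print(x$terms)
  invisible(x)
}

#' Cluster water masses from temperature and salinity
#'
#' Partitioning-around-medoids ([cluster::pam()]) on standardized variables
#' for each k in `k_range`; k is chosen by maximum average silhouette width.
#'
#' @param metadata Sample metadata with the clustering variables.
#' @param variables Column names to cluster on (standardized internally).
#' @param k_range Candidate numbers of clusters.
#' @return Object of class `watermass_clustering`: `labels` tibble, `k`,
#'   `silhouette`, and the per-k silhouette profile.
#' @export
cluster_water_masses <- function(metadata, variables = c("temperature",
                                                         "salinity"),
                                 k_range = 2:6) {
  md <- as.data.frame(metadata)
  missing <- setdiff(variables, names(md))
  if (length(missing) > 0) {
    stop("metadata lacks variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- scale(as.matrix(md[variables]))
  n <- nrow(x)
  if (max(k_range) > n - 1) {
    stop("k_range upper bound must be below the number of samples (", n, ")",
         call. = FALSE)
  }
  profile <- purrr::map_dfr(k_range, function(k) {
    fit <- cluster::pam(x, k = k)
    tibble::tibble(k = k, avg_silhouette = fit$silinfo$avg.width)
  })
  best_k <- profile$k[which.max(profile$avg_silhouette)]
  fit <- cluster::pam(x, k = best_k)
  ids <- if ("sample_id" %in% names(md)) md$sample_id else
    sprintf("S%02d", seq_len(n))
  structure(list(
    labels = tibble::tibble(sample_id = ids,
                            group = paste0("WM", fit$clustering)),
    k = best_k,
    silhouette = max(profile$avg_silhouette),
    profile = profile
  ), class = "watermass_clustering")
}

#' @export
print.watermass_clustering <- function(x, ...) {
  cat(sprintf("Water-mass clustering: k = %d (avg silhouette %.3f)\n",
              x$k, x$silhouette))
  invisible(x)
}
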