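# Geographic distances, distance-decay, PCNM spatial eigenvectors,
# Mantel/partial Mantel tests, and three-block variation partitioning.

#' Pairwise geographic distances between samples
#'
#' `model = "spheroid"` uses the WGS84 ellipsoid ([geosphere::distGeo()]),
#' `"sphere"` the haversine formula with Earth radius 6371.0 km, and
#' `"planar"` Euclidean distance on `x`/`y` columns (synthetic coordinates,
#' assumed km).
#'
#' @param metadata Tibble with `lat`/`lon` columns (degrees) or `x`/`y`
#'   (planar km), plus `sample_id`.
#' @param model Earth model.
#' @return A [pairwise_matrix()] of kind `geo_km` with a `model` attribute.
#' @export
geo_distances <- function(metadata, model = c("spheroid", "sphere",
                                              "planar")) {
  model <- match.arg(model)
  md <- as.data.frame(metadata)
  ids <- if ("sample_id" %in% names(md)) as.character(md$sample_id) else
    sprintf("S%02d", seq_len(nrow(md)))
  if (model == "planar") {
    xy <- intersect(c("x", "y", "x_km", "y_km"), names(md))
    if (length(xy) < 2) stop("planar model needs x/y columns", call. = FALSE)
    pts <- as.matrix(md[xy[1:2]])
    if (anyNA(pts)) stop("missing coordinates", call. = FALSE)
    m <- as.matrix(dist(pts))
  } else {
    if (!all(c("lat", "lon") %in% names(md))) {
      stop("metadata needs lat/lon columns", call. = FALSE)
    }
    if (anyNA(md$lat) || anyNA(md$lon)) {
      stop("missing coordinates", call. = FALSE)
    }
    pts <- cbind(md$lon, md$lat)
    n <- nrow(pts)
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      di <- if (model == "spheroid") {
        geosphere::distGeo(pts[i, , drop = FALSE], pts)
      } else {
        geosphere::distHaversine(pts[i, , drop = FALSE], pts, r = 6371000)
      }
      m[i, ] <- di / 1000
    }
    m <- (m + t(m)) / 2  # symmetrize numerical round-off
    diag(m) <- 0
  }
  dimnames(m) <- list(ids, ids)
  out <- pairwise_matrix(m, kind = "geo_km")
  attr(out, "model") <- model
  out
}

# correlation of lower triangles, optionally on ranks
triangle_cor <- function(a, b, method) {
  va <- lower_vec(a); vb <- lower_vec(b)
  if (sd(va) == 0 || sd(vb) == 0) {
    stop("constant matrix: correlation undefined", call. = FALSE)
  }
  cor(va, vb, method = method)
}

#' Mantel test between two distance matrices
#'
#' `r` is the (Pearson or Spearman) correlation of the lower-triangle
#' entries; the p-value permutes the rows and columns of `b` simultaneously
#' (add-one convention). `alternative = "greater"` is the classic Mantel
#' test; use `"less"` for negative associations such as distance-decay.
#'
#' @param a,b Square symmetric matrices ([pairwise_matrix()], `dist` or
#'   matrix) with matching labels.
#' @param method Correlation method.
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @param alternative Direction of the test.
#' @return Object of class `mantel_result` with `r`, `p_value`, `n_perm`.
#' @export
mantel <- function(a, b, method = c("pearson", "spearman"), n_perm = 999,
                   seed = NULL, alternative = c("greater", "less",
                                                "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  ma <- as_square(a); mb <- as_square(b)
  if (nrow(ma) != nrow(mb)) stop("matrix sizes differ", call. = FALSE)
  obs <- triangle_cor(ma, mb, method)
  run <- function() {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(nrow(mb))
      r <- triangle_cor(ma, mb[p, p], method)
      ok <- switch(alternative,
                   greater = r >= obs - 1e-12,
                   less = r <= obs + 1e-12,
                   two.sided = abs(r) >= abs(obs) - 1e-12)
      if (ok) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(r = obs, p_value = p, n_perm = n_perm, method = method,
                 alternative = alternative, partial = FALSE),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Correlation between `a` and `b` controlling for `c` by linear
#' residualization (first-order partial correlation); the Spearman variant
#' rank-transforms all three lower triangles first. Significance by
#' simultaneous row/column permutation of `a`.
#'
#' @inheritParams mantel
#' @param c Control matrix.
#' @return A `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel <- function(a, b, c, method = c("pearson", "spearman"),
                           n_perm = 999, seed = NULL,
                           alternative = c("greater", "less", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  ma <- as_square(a); mb <- as_square(b); mc <- as_square(c)
  rbc <- triangle_cor(mb, mc, method)
  if (abs(rbc) > 1 - 1e-12) {
    stop("control matrix is collinear with `b`; partial correlation ",
         "undefined", call. = FALSE)
  }
  partial_r <- function(x) {
    rab <- triangle_cor(x, mb, method)
    rac <- triangle_cor(x, mc, method)
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  }
  obs <- partial_r(ma)
  run <- function() {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(nrow(ma))
      r <- partial_r(ma[p, p])
      ok <- switch(alternative,
                   greater = r >= obs - 1e-12,
                   less = r <= obs + 1e-12,
                   two.sided = abs(r) >= abs(obs) - 1e-12)
      if (ok) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(r = obs, p_value = p, n_perm = n_perm, method = method,
                 alternative = alternative, partial = TRUE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%sMantel (%s): r = %.3f, P = %.4g (%d permutations, %s)\n",
              if (x$partial) "Partial " else "", x$method, x$r, x$p_value,
              x$n_perm, x$alternative))
  invisible(x)
}

#' Distance-decay of community similarity
#'
#' Spearman Mantel test between Bray-Curtis similarity (`1 - BC`, optionally
#' `log(x+1)`-transformed, which leaves the rank statistic unchanged) and
#' geographic distance, one-sided for a negative association.
#'
#' @param table Community table.
#' @param geo Geographic distance matrix from [geo_distances()].
#' @param method Correlation method.
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @param log_transform Apply `log(x+1)` to the similarities.
#' @param samples Optional subset of sample ids (e.g. surface samples only).
#' @return Object of class `distance_decay`: the `mantel_result` plus a
#'   per-pair `scatter` tibble (`distance_km`, `similarity`).
#' @export
distance_decay <- function(table, geo, method = c("spearman", "pearson"),
                           n_perm = 999, seed = NULL, log_transform = FALSE,
                           samples = NULL) {
  method <- match.arg(method)
  m <- as_count_matrix(table)
  g <- as_square(geo)
  if (!is.null(samples)) {
    m <- m[rownames(m) %in% samples, , drop = FALSE]
    g <- g[rownames(g) %in% samples, rownames(g) %in% samples, drop = FALSE]
  }
  if (nrow(m) < 4) stop("need at least 4 samples", call. = FALSE)
  g <- g[rownames(m), rownames(m)]
  sim <- as.matrix(bray_curtis(m, as = "similarity"))
  if (log_transform) sim <- transform_log1(sim)
  mt <- mantel(sim, g, method = method, n_perm = n_perm, seed = seed,
               alternative = "less")
  idx <- which(lower.tri(g), arr.ind = TRUE)
  scatter <- tibble::tibble(
    sample_a = rownames(g)[idx[, 2L]],
    sample_b = rownames(g)[idx[, 1L]],
    distance_km = g[idx],
    similarity = sim[idx]
  )
  structure(list(mantel = mt, scatter = scatter), class = "distance_decay")
}

#' @export
print.distance_decay <- function(x, ...) {
  cat(sprintf("Distance-decay: rho = %.3f, P = %.4g over %d pairs\n",
              x$mantel$r, x$mantel$p_value, nrow(x$scatter)))
  invisible(x)
}

#' PCNM spatial eigenvectors
#'
#' Principal coordinates of neighbor matrices ([vegan::pcnm()]): distances
#' above the truncation threshold (default: the longest edge of the minimum
#' spanning tree) are replaced by four times the threshold, the truncated
#' matrix is double-centered, and eigenvectors with positive eigenvalues are
#' returned, column-centered and scaled to unit norm.
#'
#' @param geo Geographic distance matrix.
#' @param truncation Optional truncation distance.
#' @return Tibble of `sample_id` plus `PCNM1..k`, with attributes
#'   `eigenvalues` and `truncation`.
#' @export
pcnm_vectors <- function(geo, truncation = NULL) {
  g <- as_square(geo)
  if (nrow(g) < 3) stop("need at least 3 samples", call. = FALSE)
  if (max(g) == 0) stop("degenerate coordinates: all distances zero",
                        call. = FALSE)
  fit <- if (is.null(truncation)) {
    vegan::pcnm(stats::as.dist(g))
  } else {
    vegan::pcnm(stats::as.dist(g), threshold = truncation)
  }
  v <- as.matrix(fit$vectors)
  v <- scale(v, center = TRUE, scale = FALSE)
  v <- sweep(v, 2L, sqrt(colSums(v^2)), "/")
  colnames(v) <- paste0("PCNM", seq_len(ncol(v)))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(g)),
                          tibble::as_tibble(v))
  attr(out, "eigenvalues") <- fit$values[fit$values > 0]
  attr(out, "truncation") <- fit$threshold
  out
}

#' Encode a second community as explanatory variables
#'
#' Principal-coordinate axes of the second table's Bray-Curtis matrix, for
#' use as an explanatory block in variation partitioning. The number of axes
#' defaults to a broken-stick choice over the positive eigenvalues.
#'
#' @param second_table Community table aligned to the response samples.
#' @param k Number of axes (default: broken stick; at least 1).
#' @return Tibble of `sample_id` plus `Axis1..k`, attribute `eigenvalues`.
#' @export
community_as_predictors <- function(second_table, k = NULL) {
  m <- as_count_matrix(second_table)
  n <- nrow(m)
  if (!is.null(k) && k >= n) stop("k must be below the number of samples",
                                  call. = FALSE)
  d <- stats::as.dist(as.matrix(bray_curtis(m)))
  # cmdscale warns when fewer than k eigenvalues are positive; the positive
  # subset is all we keep
  pc <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  pos <- which(pc$eig > sqrt(.Machine$double.eps))
  ax <- pc$points[, pos, drop = FALSE]
  if (is.null(k)) {
    eig <- pc$eig[pos]
    p <- length(eig)
    bs <- rev(cumsum(1 / rev(seq_len(p)))) / p  # broken-stick proportions
    keep <- which(eig / sum(eig) > bs)
    k <- if (length(keep) > 0) max(1L, max(keep)) else 1L
    k <- min(k, p)
  }
  ax <- ax[, seq_len(min(k, ncol(ax))), drop = FALSE]
  colnames(ax) <- paste0("Axis", seq_len(ncol(ax)))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                          tibble::as_tibble(ax))
  attr(out, "eigenvalues") <- pc$eig[pos]
  out
}

# strip the sample_id column from an explanatory block
drop_id <- function(x) {
  x <- as.data.frame(x)
  x[setdiff(names(x), "sample_id")]
}

#' Three-block variation partitioning
#'
#' Partitions the variance of the (by default Hellinger-transformed)
#' community table among an environmental block `E`, a second-community
#' block `B` and a spatial block `S` by redundancy analysis with adjusted
#' R-squared ([vegan::varpart()]). Pure-fraction significance is tested by
#' permutation on the corresponding partial RDA. Pure and shared fractions
#' plus the residual sum to 1 exactly (inclusion-exclusion closure);
#' individual adjusted fractions may be negative.
#'
#' @param response Community table (the response).
#' @param env,second,space Explanatory blocks (data frames; a `sample_id`
#'   column is ignored). Pre-prune with [vif_prune()] where relevant.
#' @param n_perm Permutations for the pure-fraction tests.
#' @param seed Optional RNG seed.
#' @param transform `"hellinger"` (default) or `"none"`.
#' @return Object of class `varpart_result`: `fractions` tibble (adjusted
#'   R-squared per fraction), `tests` tibble, `residual`.
#' @export
varpart3 <- function(response, env, second, space, n_perm = 999, seed = NULL,
                     transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  m <- as_count_matrix(response)
  e <- drop_id(env); b <- drop_id(second); s <- drop_id(space)
  n <- nrow(m)
  if (ncol(e) + ncol(b) + ncol(s) >= n - 1) {
    stop("explanatory columns (", ncol(e) + ncol(b) + ncol(s),
         ") must stay below samples - 1 (", n - 1, "): model saturated",
         call. = FALSE)
  }
  y <- if (transform == "hellinger") {
    as.matrix(vegan::decostand(m, "hellinger"))
  } else {
    m
  }
  vp <- vegan::varpart(y, e, b, s)
  ind <- vp$part$indfract
  frac_names <- c(`[a]` = "E_pure", `[b]` = "B_pure", `[c]` = "S_pure",
                  `[d]` = "E_B_shared", `[e]` = "B_S_shared",
                  `[f]` = "E_S_shared", `[g]` = "E_B_S_shared",
                  `[h]` = "residual")
  key <- sub("^(\\[[a-h]\\]).*", "\\1", rownames(ind))
  fractions <- tibble::tibble(
    fraction = unname(frac_names[key]),
    adj_r_squared = ind$Adj.R.square
  )
  run_tests <- function() {
    purrr::map_dfr(
      list(list("E_pure", e, cbind(b, s)),
           list("B_pure", b, cbind(e, s)),
           list("S_pure", s, cbind(e, b))),
      function(spec) {
        mod <- vegan::rda(y, spec[[2L]], spec[[3L]])
        an <- vegan::anova.cca(mod, permutations = n_perm)
        tibble::tibble(fraction = spec[[1L]], f_statistic = an$F[1L],
                       p_value = an$`Pr(>F)`[1L])
      })
  }
  tests <- if (is.null(seed)) run_tests() else {
    withr::with_seed(seed, run_tests())
  }
  structure(list(fractions = fractions, tests = tests,
                 residual = fractions$adj_r_squared[fractions$fraction ==
                                                      "residual"],
                 transform = transform, n = n),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("Variation partitioning (adjusted R-squared)\n")
  f <- x$fractions
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-12s %7.3f\n", f$fraction[i], f$adj_r_squared[i]))
  }
  print(x$tests)
  invisible(x)
}
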