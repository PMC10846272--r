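# Phylogenetic and taxonomic null models: betaMNTD, betaNTI under a
# tip-shuffle null, the abundance-informed Raup-Crick metric on Bray-Curtis,
# and the five-process classification of pairwise turnover.

#' Null-model configuration
#'
#' @param n_null Number of null replicates (>= 99; default 999, the usual
#'   convention for these null models).
#' @param weighted Abundance-weight betaMNTD (default) or use presence/absence
#'   weights `1/richness`.
#' @param seed Optional RNG seed applied to the null draws.
#' @param bnti_threshold Threshold on |betaNTI| separating selection from
#'   stochasticity (2 by convention; strict inequality).
#' @param rc_threshold Threshold on |RC-BC| separating dispersal processes
#'   from drift (0.95; strict inequality).
#' @return List of class `null_model_config`.
#' @export
null_model_config <- function(n_null = 999, weighted = TRUE, seed = NULL,
                              bnti_threshold = 2, rc_threshold = 0.95) {
  if (n_null < 99) {
    stop("n_null must be at least 99 for meaningful null quantiles",
         call. = FALSE)
  }
  if (bnti_threshold <= 0 || rc_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  structure(list(n_null = as.integer(n_null), weighted = isTRUE(weighted),
                 seed = seed, bnti_threshold = bnti_threshold,
                 rc_threshold = rc_threshold),
            class = "null_model_config")
}

#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree `phylo` object with branch lengths.
#' @return Symmetric tip-by-tip distance matrix with zero diagonal.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; patristic distances undefined",
         call. = FALSE)
  }
  stats::cophenetic(tree)
}

# abundance (or presence) weights, rows summing to 1
relative_weights <- function(m, weighted) {
  if (!weighted) m <- (m > 0) * 1
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("empty community: ", paste(rownames(m)[tot == 0], collapse = ", "),
         call. = FALSE)
  }
  m / tot
}

# column minima via pmin reduction (fast for many small calls)
col_min_over <- function(pd, idx) {
  # for every OTU i: min over j in idx of pd[i, j]
  do.call(pmin, as.data.frame(pd[, idx, drop = FALSE]))
}

# core betaMNTD on a weights matrix (samples x OTUs, rows sum 1) and a
# patristic matrix in the same OTU order
beta_mntd_engine <- function(w, pd, presence) {
  dmin <- vapply(seq_len(nrow(w)),
                 function(k) col_min_over(pd, which(presence[k, ])),
                 numeric(ncol(w)))
  g <- w %*% dmin  # g[k, m] = sum_i w_ik * min_{j in m} d_ij
  b <- (g + t(g)) / 2
  dimnames(b) <- list(rownames(w), rownames(w))
  b
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For communities k and m, betaMNTD is the average patristic distance from
#' each taxon to its phylogenetically nearest taxon in the other community:
#' `0.5 * (sum_i f_ik min_j d_ij + sum_j f_jm min_i d_ij)`, with `f` the
#' relative abundances (`weighted = TRUE`) or `1/richness` otherwise.
#'
#' @param table Community table.
#' @param patristic Patristic distance matrix covering the table's OTUs (see
#'   [patristic_matrix()]), or a `phylo` tree.
#' @param weighted Abundance weighting flag.
#' @return A [pairwise_matrix()] of kind `dissimilarity`.
#' @export
beta_mntd <- function(table, patristic, weighted = TRUE) {
  m <- as_count_matrix(table)
  if (inherits(patristic, "phylo")) patristic <- patristic_matrix(patristic)
  missing <- setdiff(colnames(m), colnames(patristic))
  if (length(missing) > 0) {
    stop("OTUs absent from the distance matrix: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  pd <- patristic[colnames(m), colnames(m)]
  w <- relative_weights(m, weighted)
  b <- beta_mntd_engine(w, pd, m > 0)
  pairwise_matrix(b, kind = "dissimilarity")
}

#' Standardized betaMNTD (betaNTI) under a tip-shuffle null
#'
#' Null replicates randomize taxa across the tips of the phylogeny — a joint
#' permutation of the rows and columns of the patristic matrix — while the
#' community table stays fixed. betaNTI is the number of null SDs separating
#' the observed betaMNTD from the null mean. Pairs whose null SD is zero are
#' masked as degenerate rather than coerced to 0.
#'
#' @param table Community table.
#' @param tree `phylo` tree (or precomputed patristic matrix).
#' @param config A [null_model_config()].
#' @return Object of class `bnti_result` with per-pair observed betaMNTD,
#'   null mean/SD, betaNTI and a degenerate-pair mask.
#' @export
beta_nti <- function(table, tree, config = null_model_config()) {
  stopifnot(inherits(config, "null_model_config"))
  m <- as_count_matrix(table)
  pd <- if (inherits(tree, "phylo")) patristic_matrix(tree) else as.matrix(tree)
  missing <- setdiff(colnames(m), colnames(pd))
  if (length(missing) > 0) {
    stop("OTUs absent from the tree: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  pd <- pd[colnames(m), colnames(m)]
  w <- relative_weights(m, config$weighted)
  pres <- m > 0
  obs <- beta_mntd_engine(w, pd, pres)

  run_nulls <- function() {
    n_otu <- ncol(m)
    s <- matrix(0, nrow(m), nrow(m))
    s2 <- matrix(0, nrow(m), nrow(m))
    for (r in seq_len(config$n_null)) {
      perm <- sample.int(n_otu)
      b <- beta_mntd_engine(w, pd[perm, perm], pres)
      s <- s + b
      s2 <- s2 + b * b
    }
    mu <- s / config$n_null
    v <- pmax(s2 / config$n_null - mu * mu, 0) *
      config$n_null / (config$n_null - 1)
    list(mean = mu, sd = sqrt(v))
  }
  nl <- if (is.null(config$seed)) run_nulls() else {
    withr::with_seed(config$seed, run_nulls())
  }
  degenerate <- nl$sd < 1e-12
  bnti <- (obs - nl$mean) / nl$sd
  bnti[degenerate] <- NA_real_
  diag(degenerate) <- TRUE
  diag(bnti) <- NA_real_
  dimnames(nl$mean) <- dimnames(nl$sd) <- dimnames(degenerate) <- dimnames(obs)
  structure(list(labels = rownames(m), observed = obs, null_mean = nl$mean,
                 null_sd = nl$sd, bnti = pairwise_matrix(bnti, kind = "bnti"),
                 degenerate = degenerate, n_null = config$n_null,
                 weighted = config$weighted),
            class = "bnti_result")
}

#' @export
print.bnti_result <- function(x, ...) {
  v <- lower_vec(as.matrix(x$bnti))
  v <- v[!is.na(v)]
  cat(sprintf("betaNTI over %d sample pairs (%d null replicates, %s)\n",
              length(lower_vec(x$observed)), x$n_null,
              if (x$weighted) "abundance-weighted" else "unweighted"))
  cat(sprintf("  betaNTI range: [%.2f, %.2f]; |betaNTI| > 2: %.1f%%\n",
              min(v), max(v), 100 * mean(abs(v) > 2)))
  invisible(x)
}

# one null community: `s` species drawn without replacement with probability
# proportional to occurrence frequency, then `n` individuals spread as one
# individual per drawn species plus a multinomial on metacommunity relative
# abundances
rc_draw_community <- function(s, n, occ_w, ab_w) {
  n_pool <- length(occ_w)
  out <- numeric(n_pool)
  chosen <- sample.int(n_pool, size = s, prob = occ_w)
  out[chosen] <- 1
  if (n > s) {
    out[chosen] <- out[chosen] +
      as.vector(rmultinom(1L, n - s, ab_w[chosen]))
  }
  out
}

#' Raup-Crick metric on Bray-Curtis dissimilarities (RC-BC)
#'
#' For each sample pair, null community pairs are assembled that preserve each
#' observed richness (species drawn with probability proportional to
#' metacommunity occurrence frequency) and each observed total abundance
#' (individuals assigned with probability proportional to metacommunity
#' relative abundance). RC-BC is the rank of the observed Bray-Curtis within
#' the null Bray-Curtis distribution, ties counted at half weight, rescaled to
#' `[-1, 1]`.
#'
#' @param table Community table of integer counts.
#' @param config A [null_model_config()].
#' @param metacommunity Optional list with named numeric vectors `occurrence`
#'   and `abundance` overriding the metacommunity profile estimated from the
#'   table (used for null-calibration diagnostics).
#' @return A [pairwise_matrix()] of kind `rc`.
#' @export
raup_crick_bc <- function(table, config = null_model_config(),
                          metacommunity = NULL) {
  stopifnot(inherits(config, "null_model_config"))
  m <- as_count_matrix(table, require_integer = TRUE)
  prof <- rc_profile(m, metacommunity)
  if (sum(prof$occurrence > 0) < 2) {
    stop("metacommunity has fewer than 2 OTUs", call. = FALSE)
  }
  s_obs <- rowSums(m > 0)
  n_obs <- rowSums(m)
  obs_bc <- as.matrix(vegan::vegdist(m, method = "bray"))

  run <- function() {
    less <- matrix(0L, nrow(m), nrow(m))
    ties <- matrix(0L, nrow(m), nrow(m))
    for (r in seq_len(config$n_null)) {
      nullm <- t(vapply(seq_len(nrow(m)), function(k) {
        rc_draw_community(s_obs[k], n_obs[k], prof$occurrence, prof$abundance)
      }, numeric(ncol(m))))
      nb <- as.matrix(vegan::vegdist(nullm, method = "bray"))
      d <- nb - obs_bc
      less <- less + (d < -1e-9)
      ties <- ties + (abs(d) <= 1e-9)
    }
    list(less = less, ties = ties)
  }
  cnt <- if (is.null(config$seed)) run() else {
    withr::with_seed(config$seed, run())
  }
  rc <- ((cnt$less + 0.5 * cnt$ties) / config$n_null - 0.5) * 2
  dimnames(rc) <- dimnames(obs_bc)
  pairwise_matrix(rc, kind = "rc")
}

# metacommunity profile: occurrence frequency and relative abundance
rc_profile <- function(m, metacommunity = NULL) {
  if (is.null(metacommunity)) {
    list(occurrence = colSums(m > 0), abundance = colSums(m) / sum(m))
  } else {
    occ <- metacommunity$occurrence[colnames(m)]
    ab <- metacommunity$abundance[colnames(m)]
    if (anyNA(occ) || anyNA(ab)) {
      stop("metacommunity profile does not cover all OTUs", call. = FALSE)
    }
    list(occurrence = occ, abundance = ab / sum(ab))
  }
}

#' Replace every sample by a draw from the Raup-Crick null
#'
#' Diagnostic generator: each sample keeps its observed richness and total
#' abundance but its composition is redrawn from the RC null model. Data
#' produced this way should yield an RC-BC distribution approximately uniform
#' on `[-1, 1]`.
#'
#' @param table Community table of integer counts.
#' @param metacommunity Optional profile override, as in [raup_crick_bc()].
#' @param seed Optional RNG seed.
#' @return Community table of the same shape.
#' @export
draw_rc_null <- function(table, metacommunity = NULL, seed = NULL) {
  m <- as_count_matrix(table, require_integer = TRUE)
  prof <- rc_profile(m, metacommunity)
  s_obs <- rowSums(m > 0)
  n_obs <- rowSums(m)
  run <- function() {
    out <- t(vapply(seq_len(nrow(m)), function(k) {
      rc_draw_community(s_obs[k], n_obs[k], prof$occurrence, prof$abundance)
    }, numeric(ncol(m))))
    dimnames(out) <- dimnames(m)
    out
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  community_tbl(out)
}

#' Classify pairwise turnover into the five assembly processes
#'
#' Decision rule (strict inequalities): `betaNTI > +2` heterogeneous
#' selection; `betaNTI < -2` homogeneous selection; otherwise `RC-BC > +0.95`
#' dispersal limitation, `RC-BC < -0.95` homogenizing dispersal, and
#' `|RC-BC| <= 0.95` drift. Fractions are taken over non-degenerate pairs;
#' degenerate pairs (null SD of betaMNTD = 0) are reported separately.
#'
#' @param bnti A `bnti_result` (or a [pairwise_matrix()] of betaNTI values).
#' @param rc A [pairwise_matrix()] of RC-BC values from [raup_crick_bc()].
#' @param config A [null_model_config()] carrying the thresholds.
#' @return Object of class `assembly_result`: per-pair tibble (`pairs`),
#'   per-process fractions (`fractions`) and the degenerate-pair list.
#' @export
classify_processes <- function(bnti, rc, config = null_model_config()) {
  bm <- if (inherits(bnti, "bnti_result")) as.matrix(bnti$bnti) else {
    as.matrix(bnti)
  }
  rcm <- as.matrix(rc)
  if (!identical(rownames(bm), rownames(rcm))) {
    stop("betaNTI and RC-BC labels differ", call. = FALSE)
  }
  idx <- which(lower.tri(bm), arr.ind = TRUE)
  b <- bm[idx]
  r <- rcm[idx]
  if (any(is.na(r[!is.na(b) & abs(b) <= config$bnti_threshold]))) {
    stop("RC-BC missing for pair(s) within the stochastic betaNTI band",
         call. = FALSE)
  }
  proc <- classify_pair(b, r, config$bnti_threshold, config$rc_threshold)
  pairs <- tibble::tibble(
    sample_a = rownames(bm)[idx[, 2L]],
    sample_b = rownames(bm)[idx[, 1L]],
    bnti = b, rc = r, process = proc
  )
  levels5 <- c("heterogeneous_selection", "homogeneous_selection",
               "dispersal_limitation", "homogenizing_dispersal", "drift")
  classified <- pairs[!is.na(pairs$process), ]
  n_tab <- table(factor(classified$process, levels = levels5))
  fractions <- tibble::tibble(
    process = levels5,
    n = as.integer(n_tab),
    fraction = if (nrow(classified) > 0) as.integer(n_tab) / nrow(classified)
               else rep(NA_real_, 5L)
  )
  structure(list(pairs = pairs, fractions = fractions,
                 degenerate = pairs[is.na(pairs$process), c("sample_a",
                                                            "sample_b")],
                 n_classified = nrow(classified)),
            class = "assembly_result")
}

# vectorized decision rule; NA betaNTI (degenerate pair) -> NA process
classify_pair <- function(bnti, rc, bnti_threshold = 2, rc_threshold = 0.95) {
  out <- rep(NA_character_, length(bnti))
  det_hi <- !is.na(bnti) & bnti > bnti_threshold
  det_lo <- !is.na(bnti) & bnti < -bnti_threshold
  sto <- !is.na(bnti) & abs(bnti) <= bnti_threshold
  out[det_hi] <- "heterogeneous_selection"
  out[det_lo] <- "homogeneous_selection"
  out[sto & rc > rc_threshold] <- "dispersal_limitation"
  out[sto & rc < -rc_threshold] <- "homogenizing_dispersal"
  out[sto & abs(rc) <= rc_threshold] <- "drift"
  out
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("Assembly processes over %d classified pair(s) (%d degenerate)\n",
              x$n_classified, nrow(x$degenerate)))
  f <- x$fractions
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-24s %3d  (%.1f%%)\n", f$process[i], f$n[i],
                100 * f$fraction[i]))
  }
  invisible(x)
}
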