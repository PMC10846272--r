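# Independent naive (loop-based) oracles and small random-instance
# generators. The oracles deliberately share no code with the package
# implementations they check.

random_table <- function(n_samples, n_otus, max_count = 20,
                         min_total = 1) {
  lambda <- max(3, ceiling(2 * min_total / n_otus))
  repeat {
    m <- matrix(rpois(n_samples * n_otus, lambda = lambda),
                n_samples, n_otus)
    m[m > max_count] <- max_count
    if (all(rowSums(m) >= min_total) && all(colSums(m) > 0)) break
  }
  rownames(m) <- sprintf("S%02d", seq_len(n_samples))
  colnames(m) <- paste0("OTU_", seq_len(n_otus))
  m
}

random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips)
  tr$tip.label <- paste0("OTU_", seq_len(n_tips))
  tr
}

# Bray-Curtis by explicit double loop over OTUs
oracle_bray <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s_min <- 0
    for (k in seq_len(ncol(m))) s_min <- s_min + min(m[i, k], m[j, k])
    out[i, j] <- 1 - 2 * s_min / (sum(m[i, ]) + sum(m[j, ]))
  }
  out
}

# betaMNTD by explicit triple loop
oracle_beta_mntd <- function(m, pd, weighted = TRUE) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  w <- m
  if (!weighted) w <- (m > 0) * 1
  w <- w / rowSums(w)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    acc <- 0
    for (i in which(m[a, ] > 0)) {
      dmin <- Inf
      for (j in which(m[b, ] > 0)) {
        dmin <- min(dmin, pd[colnames(m)[i], colnames(m)[j]])
      }
      acc <- acc + w[a, i] * dmin
    }
    for (j in which(m[b, ] > 0)) {
      dmin <- Inf
      for (i in which(m[a, ] > 0)) {
        dmin <- min(dmin, pd[colnames(m)[i], colnames(m)[j]])
      }
      acc <- acc + w[b, j] * dmin
    }
    out[a, b] <- acc / 2
  }
  out
}

# ANOSIM R from first principles: rank all pairs, average by pair type
oracle_anosim_r <- function(d, groups) {
  n <- nrow(d)
  dv <- c(); wv <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dv <- c(dv, d[i, j])
    wv <- c(wv, groups[i] == groups[j])
  }
  rk <- rank(dv)
  (mean(rk[!wv]) - mean(rk[wv])) / (length(dv) / 2)
}

# SIMPER contribution of every OTU averaged over between-group pairs
oracle_simper <- function(m, groups, g1, g2) {
  contribs <- rep(0, ncol(m))
  n_pairs <- 0
  for (a in which(groups == g1)) for (b in which(groups == g2)) {
    n_pairs <- n_pairs + 1
    for (k in seq_len(ncol(m))) {
      contribs[k] <- contribs[k] +
        abs(m[a, k] - m[b, k]) / (sum(m[a, ]) + sum(m[b, ]))
    }
  }
  setNames(contribs / n_pairs, colnames(m))
}

# Mantel r as the plain correlation of vectorized lower triangles
oracle_mantel_r <- function(a, b, method = "pearson") {
  va <- c(); vb <- c()
  for (i in seq_len(nrow(a) - 1)) for (j in seq(i + 1, nrow(a))) {
    va <- c(va, a[j, i]); vb <- c(vb, b[j, i])
  }
  cor(va, vb, method = method)
}

# patristic distance by explicit root-path traversal
oracle_patristic <- function(tree, tip_a, tip_b) {
  n_tip <- length(tree$tip.label)
  parent_of <- function(node) {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0) NULL else list(parent = tree$edge[e, 1],
                                       len = tree$edge.length[e])
  }
  path_to_root <- function(tip) {
    node <- tip; acc <- c(); nodes <- c(node)
    repeat {
      p <- parent_of(node)
      if (is.null(p)) break
      acc <- c(acc, p$len); node <- p$parent; nodes <- c(nodes, node)
    }
    list(nodes = nodes, cum = c(0, cumsum(acc)))
  }
  ia <- which(tree$tip.label == tip_a)
  ib <- which(tree$tip.label == tip_b)
  pa <- path_to_root(ia); pb <- path_to_root(ib)
  mrca <- intersect(pa$nodes, pb$nodes)[1]
  pa$cum[match(mrca, pa$nodes)] + pb$cum[match(mrca, pb$nodes)]
}

# the worked 4-tip tree used in several exactness checks
four_tip_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}
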