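# Table-level preprocessing and diversity statistics.

#' Remove singleton OTUs
#'
#' A singleton is an OTU whose total count summed across all samples equals
#' one (it occurred exactly once in the whole dataset); per-sample singletons
#' with larger dataset totals are kept.
#'
#' @param table Community table of integer counts.
#' @return Table without singleton OTUs.
#' @export
remove_singletons <- function(table) {
  m <- as_count_matrix(table, require_integer = TRUE)
  keep <- colSums(m) != 1
  community_tbl(m[, keep, drop = FALSE])
}

#' Subsample (rarefy) each sample to a fixed depth
#'
#' Draws without replacement (multivariate hypergeometric per sample, via
#' [vegan::rrarefy()]) so that every row sums exactly to `depth`. A faster
#' with-replacement multinomial variant is available for very large depths.
#'
#' @param table Community table of integer counts.
#' @param depth Target reads per sample; every sample total must be >= depth.
#' @param seed Optional RNG seed.
#' @param replace Draw with replacement (multinomial) instead.
#' @return Subsampled community table; zero cells are never created counts.
#' @export
subsample_counts <- function(table, depth, seed = NULL, replace = FALSE) {
  m <- as_count_matrix(table, require_integer = TRUE)
  tot <- rowSums(m)
  if (any(tot < depth)) {
    off <- rownames(m)[tot < depth]
    stop("sample(s) shallower than depth ", depth, ": ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  draw <- function() {
    if (replace) {
      out <- t(apply(m, 1L, function(x) {
        as.vector(rmultinom(1L, depth, x / sum(x)))
      }))
      dimnames(out) <- dimnames(m)
      out
    } else {
      # rrarefy warns when the smallest positive count exceeds 1; counts are
      # already validated as integers above
      withCallingHandlers(
        vegan::rrarefy(m, depth),
        warning = function(w) {
          if (grepl("observed counts", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    }
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  community_tbl(out)
}

#' Good's coverage per sample
#'
#' `C = 1 - F1 / N`, where `F1` is the number of OTUs observed exactly once in
#' the sample and `N` the sample total. Empty samples are flagged with `NA`.
#'
#' @param table Community table of integer counts.
#' @return Tibble with `sample_id`, `n_reads`, `f1`, `coverage`.
#' @export
goods_coverage <- function(table) {
  m <- as_count_matrix(table, require_integer = TRUE)
  n <- rowSums(m)
  f1 <- rowSums(m == 1)
  cov <- ifelse(n > 0, 1 - f1 / n, NA_real_)
  if (any(n == 0)) {
    warning("empty sample(s): ", paste(rownames(m)[n == 0], collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(sample_id = rownames(m), n_reads = unname(n),
                 f1 = unname(f1), coverage = unname(cov))
}

#' Alpha diversity per sample
#'
#' Richness (observed OTUs) and Shannon H' with natural logarithms.
#'
#' @param table Community table.
#' @return Tibble with `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  m <- as_count_matrix(table)
  n <- rowSums(m)
  if (any(n == 0)) {
    warning("empty sample(s): ", paste(rownames(m)[n == 0], collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(
    sample_id = rownames(m),
    richness = unname(rowSums(m > 0)),
    shannon = unname(ifelse(n > 0, vegan::diversity(m, index = "shannon"),
                            NA_real_))
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))`; the similarity
#' view `1 - BC` is available via `as = "similarity"`.
#'
#' @param table Community table.
#' @param as Return the dissimilarity (default) or similarity matrix.
#' @return A [pairwise_matrix()].
#' @export
bray_curtis <- function(table, as = c("dissimilarity", "similarity")) {
  as <- match.arg(as)
  m <- as_count_matrix(table)
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(rowSums(m) == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "),
         call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  if (as == "similarity") {
    pairwise_matrix(1 - d, kind = "similarity")
  } else {
    pairwise_matrix(d, kind = "dissimilarity")
  }
}

#' log(x + 1) transform
#'
#' Elementwise `log(x + 1)` of non-negative values; rank statistics such as
#' Spearman correlations are unchanged by this monotone transform.
#'
#' @param x Non-negative numeric vector or matrix.
#' @return Transformed values, same shape.
#' @export
transform_log1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("negative input", call. = FALSE)
  log1p(x)
}

#' Hellinger transform of a community table
#'
#' Square root of row-normalized counts (via [vegan::decostand()]); each
#' transformed row has unit sum of squares. The standard response transform
#' for RDA-based variation partitioning of count data.
#'
#' @param table Community table.
#' @return Transformed table as a tibble.
#' @export
hellinger <- function(table) {
  m <- as_count_matrix(table)
  community_tbl(as.matrix(vegan::decostand(m, method = "hellinger")))
}

#' Occupancy-abundance relationship
#'
#' Per-OTU occupancy (fraction of samples with a positive count) and mean
#' relative abundance, plus the Spearman correlation between the two with a
#' permutation p-value (add-one convention).
#'
#' @param table Community table.
#' @param n_perm Number of permutations for the correlation test.
#' @param seed Optional RNG seed.
#' @return Tibble of per-OTU records with attributes `rho` and `p_value`.
#' @export
occupancy_abundance <- function(table, n_perm = 999, seed = NULL) {
  m <- as_count_matrix(table)
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  rel <- m / rowSums(m)
  rec <- tibble::tibble(
    otu_id = colnames(m),
    occupancy = unname(colMeans(m > 0)),
    mean_rel_abundance = unname(colMeans(rel))
  )
  rho <- cor(rec$occupancy, rec$mean_rel_abundance, method = "spearman")
  perm_p <- function() {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      r <- cor(sample(rec$occupancy), rec$mean_rel_abundance,
               method = "spearman")
      if (abs(r) >= abs(rho) - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  }
  p <- if (is.null(seed)) perm_p() else withr::with_seed(seed, perm_p())
  attr(rec, "rho") <- rho
  attr(rec, "p_value") <- p
  rec
}

#' Rarefaction curves
#'
#' Mean and SD of observed richness over replicate random subsamples at each
#' depth.
#'
#' @param table Community table of integer counts.
#' @param depths Subsampling depths; defaults to 10 depths spanning 1 to the
#'   minimum sample total.
#' @param reps Replicate subsamples per depth.
#' @param seed Optional RNG seed.
#' @return Tibble (`sample_id`, `depth`, `mean_richness`, `sd_richness`) of
#'   class `rarefaction_curve`.
#' @export
rarefaction_curve <- function(table, depths = NULL, reps = 10, seed = NULL) {
  m <- as_count_matrix(table, require_integer = TRUE)
  min_tot <- min(rowSums(m))
  if (is.null(depths)) {
    depths <- unique(round(seq(1, min_tot, length.out = 10)))
  }
  if (any(depths > min_tot)) {
    stop("depth exceeds the shallowest sample total (", min_tot, ")",
         call. = FALSE)
  }
  run <- function() {
    purrr::map_dfr(depths, function(d) {
      rich <- replicate(reps, rowSums(vegan::rrarefy(m, d) > 0))
      if (is.null(dim(rich))) rich <- matrix(rich, nrow = 1,
                                             dimnames = list(rownames(m)))
      tibble::tibble(
        sample_id = rownames(m),
        depth = d,
        mean_richness = unname(rowMeans(rich)),
        sd_richness = unname(apply(rich, 1L, sd))
      )
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("rarefaction_curve", class(out))
  out
}
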