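# broom-style tidy()/glance() methods for the fitted result objects.

#' Tidy a betaNTI result
#'
#' @param x A `bnti_result` from [beta_nti()].
#' @param ... Unused.
#' @return Tibble with one row per sample pair: observed betaMNTD, null mean
#'   and SD, betaNTI and the degenerate flag.
#' @method tidy bnti_result
#' @export
tidy.bnti_result <- function(x, ...) {
  m <- x$observed
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(
    sample_a = rownames(m)[idx[, 2L]],
    sample_b = rownames(m)[idx[, 1L]],
    beta_mntd = m[idx],
    null_mean = x$null_mean[idx],
    null_sd = x$null_sd[idx],
    bnti = as.matrix(x$bnti)[idx],
    degenerate = x$degenerate[idx]
  )
}

#' @rdname tidy.bnti_result
#' @method glance bnti_result
#' @export
glance.bnti_result <- function(x, ...) {
  v <- tidy.bnti_result(x)
  ok <- !v$degenerate
  tibble::tibble(
    n_pairs = nrow(v),
    n_degenerate = sum(v$degenerate),
    n_null = x$n_null,
    weighted = x$weighted,
    mean_bnti = mean(v$bnti[ok]),
    frac_deterministic = mean(abs(v$bnti[ok]) > 2)
  )
}

#' Tidy an assembly-process classification
#'
#' @param x An `assembly_result` from [classify_processes()].
#' @param ... Unused.
#' @return The per-pair tibble (`tidy`) or the per-process fractions in wide
#'   form (`glance`).
#' @method tidy assembly_result
#' @export
tidy.assembly_result <- function(x, ...) x$pairs

#' @rdname tidy.assembly_result
#' @method glance assembly_result
#' @export
glance.assembly_result <- function(x, ...) {
  wide <- setNames(as.list(x$fractions$fraction), x$fractions$process)
  dplyr::bind_cols(tibble::as_tibble(wide),
                   tibble::tibble(n_classified = x$n_classified,
                                  n_degenerate = nrow(x$degenerate)))
}

#' @method tidy anosim_result
#' @export
tidy.anosim_result <- function(x, ...) {
  if (is.null(x$pairwise)) {
    tibble::tibble(comparison = "global", statistic = x$statistic,
                   p_value = x$p_value)
  } else {
    dplyr::bind_rows(
      tibble::tibble(comparison = "global", statistic = x$statistic,
                     p_value = x$p_value),
      dplyr::mutate(x$pairwise,
                    comparison = paste(.data$group_a, "vs", .data$group_b),
                    .keep = "unused", .before = 1L))
  }
}

#' @method glance anosim_result
#' @export
glance.anosim_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_perm = x$n_perm, n_groups = length(unique(x$groups)))
}

#' @method tidy mantel_result
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, method = x$method,
                 alternative = x$alternative, partial = x$partial)
}

#' @method glance mantel_result
#' @export
glance.mantel_result <- function(x, ...) tidy.mantel_result(x)

#' @method tidy nmds_ord
#' @export
tidy.nmds_ord <- function(x, ...) x$scores

#' @method glance nmds_ord
#' @export
glance.nmds_ord <- function(x, ...) {
  tibble::tibble(stress = x$stress, n_dim = x$n_dim,
                 n_samples = nrow(x$scores))
}

#' @method tidy cca_ord
#' @export
tidy.cca_ord <- function(x, ...) x$terms

#' @method glance cca_ord
#' @export
glance.cca_ord <- function(x, ...) {
  tibble::tibble(method = x$method,
                 total_inertia = x$total_inertia,
                 constrained_inertia = x$constrained_inertia,
                 constrained_fraction = x$constrained_inertia /
                   x$total_inertia)
}

#' @method tidy varpart_result
#' @export
tidy.varpart_result <- function(x, ...) x$fractions

#' @method glance varpart_result
#' @export
glance.varpart_result <- function(x, ...) {
  expl <- sum(x$fractions$adj_r_squared[x$fractions$fraction != "residual"])
  tibble::tibble(explained = expl, residual = x$residual, n = x$n,
                 transform = x$transform)
}

#' @method tidy watermass_clustering
#' @export
tidy.watermass_clustering <- function(x, ...) x$labels

#' @method glance watermass_clustering
#' @export
glance.watermass_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, avg_silhouette = x$silhouette)
}

#' @method tidy distance_decay
#' @export
tidy.distance_decay <- function(x, ...) x$scatter

#' @method glance distance_decay
#' @export
glance.distance_decay <- function(x, ...) glance.mantel_result(x$mantel)
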