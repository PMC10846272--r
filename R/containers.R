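# Internal coercions between the tidy user surface (tibbles with a sample_id
# column) and the numeric matrices that vegan/ape expect.

#' Coerce a community table to a counts matrix
#'
#' Accepts either a numeric matrix with sample row names or a data frame whose
#' first column (or a column named `sample_id`) holds sample identifiers.
#' Used internally by every table-first function; exported because it is handy
#' when dropping down to vegan directly.
#'
#' @param table Community table: samples in rows, OTUs in columns.
#' @param require_integer Error unless all counts are whole numbers.
#' @return Numeric matrix with sample row names and OTU column names.
#' @export
as_count_matrix <- function(table, require_integer = FALSE) {
  if (is.matrix(table)) {
    m <- table
    if (is.null(rownames(m))) {
      stop("community matrix must have sample row names", call. = FALSE)
    }
  } else if (is.data.frame(table)) {
    df <- as.data.frame(table)
    id_col <- if ("sample_id" %in% names(df)) {
      "sample_id"
    } else if (!is.numeric(df[[1L]])) {
      names(df)[1L]
    } else {
      NA_character_
    }
    if (!is.na(id_col)) {
      ids <- as.character(df[[id_col]])
      df[[id_col]] <- NULL
    } else {
      ids <- rownames(df)
    }
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    if (length(bad) > 0) {
      stop("non-numeric count column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    m <- as.matrix(df)
    rownames(m) <- ids
  } else {
    stop("`table` must be a matrix or data frame", call. = FALSE)
  }
  if (is.null(colnames(m))) {
    stop("community table must have OTU column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate OTU ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(m)) stop("community table contains missing values", call. = FALSE)
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count for sample '%s', OTU '%s'",
                 rownames(m)[idx[1L]], colnames(m)[idx[2L]]), call. = FALSE)
  }
  if (require_integer && any(abs(m - round(m)) > 1e-8)) {
    idx <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count for sample '%s', OTU '%s'",
                 rownames(m)[idx[1L]], colnames(m)[idx[2L]]), call. = FALSE)
  }
  m
}

# matrix -> tibble with a sample_id column
community_tbl <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

#' Construct a labelled pairwise matrix
#'
#' Thin S3 wrapper around a square symmetric matrix carrying a `kind` tag
#' (`"dissimilarity"`, `"similarity"`, `"bnti"`, `"rc"` or `"geo_km"`).
#' Dissimilarity and geographic matrices must have a zero diagonal; the
#' diagonal of `bnti`/`rc` matrices is undefined and stored as `NA`.
#'
#' @param m Square numeric matrix with matching dimnames.
#' @param kind Matrix kind tag.
#' @return Object of class `pairwise_matrix` (still a matrix).
#' @export
pairwise_matrix <- function(m, kind = c("dissimilarity", "similarity",
                                        "bnti", "rc", "geo_km")) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("pairwise matrix must be square", call. = FALSE)
  if (is.null(rownames(m)) && is.null(colnames(m))) {
    rownames(m) <- colnames(m) <- paste0("S", seq_len(nrow(m)))
  } else if (is.null(rownames(m))) {
    rownames(m) <- colnames(m)
  } else if (is.null(colnames(m))) {
    colnames(m) <- rownames(m)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels differ", call. = FALSE)
  }
  off <- m[lower.tri(m)] - t(m)[lower.tri(m)]
  if (any(abs(off[!is.na(off)]) > 1e-12)) {
    stop("matrix is not symmetric (tolerance 1e-12)", call. = FALSE)
  }
  if (kind %in% c("dissimilarity", "geo_km") &&
      any(abs(diag(m)) > 1e-12, na.rm = TRUE)) {
    stop("diagonal must be zero for a ", kind, " matrix", call. = FALSE)
  }
  if (kind %in% c("bnti", "rc")) diag(m) <- NA_real_
  structure(m, kind = kind, class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix [%s], %d samples>\n",
              attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))], ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
as.matrix.pairwise_matrix <- function(x, ...) {
  attr(x, "kind") <- NULL
  class(x) <- NULL
  x
}

#' @export
as.dist.pairwise_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(as.matrix(m), diag = diag, upper = upper)
}

#' Long-format view of a pairwise matrix
#'
#' @param x A [pairwise_matrix()].
#' @param ... Unused.
#' @return Tibble with one row per unordered sample pair (`sample_a`,
#'   `sample_b`, `value`).
#' @method tidy pairwise_matrix
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  m <- as.matrix(x)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(
    sample_a = rownames(m)[idx[, 2L]],
    sample_b = rownames(m)[idx[, 1L]],
    value    = m[idx]
  )
}

# coerce dist/matrix/pairwise_matrix to a plain square matrix with labels
as_square <- function(d) {
  if (inherits(d, "dist")) {
    m <- as.matrix(d)
  } else {
    m <- as.matrix(d)
  }
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("S", seq_len(nrow(m)))
  m
}

# lower-triangle vector in a fixed order
lower_vec <- function(m) m[lower.tri(m)]
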