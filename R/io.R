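# Readers and writers for the plain-text artifact formats: TSV community
# tables and metadata, Newick trees, labelled square pairwise matrices.

#' Read a community table from TSV
#'
#' The canonical orientation is samples as rows: a header row of OTU ids and a
#' first column of sample ids. Tables stored in the transposed dialect (OTUs
#' as rows) are handled by `otus_as_rows = TRUE`; there is no silent
#' auto-detection.
#'
#' @param path Path to a tab-separated file.
#' @param otus_as_rows The file stores OTUs as rows and samples as columns.
#' @return Tibble with a `sample_id` column followed by one numeric column
#'   per OTU.
#' @export
read_community_table <- function(path, otus_as_rows = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    stop("no data: '", path, "' is empty", call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop("no data: '", path, "' has no counts", call. = FALSE)
  }
  ids <- as.character(raw[[1L]])
  feat <- names(raw)[-1L]
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)), USE.NAMES = TRUE))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(ids, feat))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[idx[1L]], feat[idx[2L]], path), call. = FALSE)
  }
  if (otus_as_rows) num <- t(num)
  if (any(num < 0)) {
    idx <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count for sample '%s', OTU '%s' in %s",
                 rownames(num)[idx[1L]], colnames(num)[idx[2L]], path),
         call. = FALSE)
  }
  rownames(num) <- trimws(rownames(num))
  colnames(num) <- trimws(colnames(num))
  community_tbl(as_count_matrix(num))
}

#' Write a community table to TSV (samples as rows)
#'
#' @param table Community table (see [as_count_matrix()]).
#' @param path Output path.
#' @export
write_community_table <- function(table, path) {
  m <- as_count_matrix(table)
  readr::write_tsv(community_tbl(m), path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects a `sample_id` column; validates latitude/longitude ranges when the
#' columns are present.
#'
#' @param path Path to a tab-separated metadata file.
#' @return Tibble of per-sample metadata.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  md <- readr::read_tsv(path, col_types = readr::cols())
  if (!"sample_id" %in% names(md)) {
    names(md)[1L] <- "sample_id"
  }
  md$sample_id <- trimws(as.character(md$sample_id))
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  if ("lat" %in% names(md) && any(abs(md$lat) > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if ("lon" %in% names(md) && any(abs(md$lon) > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  md
}

#' @rdname read_sample_metadata
#' @param metadata Metadata tibble.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path)
  invisible(path)
}

#' Read a rooted phylogeny from Newick
#'
#' @param path Path to a Newick file containing a single tree.
#' @return An [ape::phylo] object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("failed to parse Newick in '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("failed to parse Newick in '", path, "'", call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr),
                               call. = FALSE)
    tr <- tr[[1L]]
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels in tree", call. = FALSE)
  }
  tr
}

#' @rdname read_phylogeny
#' @param tree `phylo` object.
#' @export
write_phylogeny <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read/write a labelled square pairwise matrix
#'
#' Pairwise matrices are stored as a TSV with sample ids in both the header
#' and the first column.
#'
#' @param path File path.
#' @param kind Matrix kind tag (see [pairwise_matrix()]).
#' @return A [pairwise_matrix()].
#' @export
read_pairwise_matrix <- function(path, kind = "dissimilarity") {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    sample_id = readr::col_character()))
  m <- as.matrix(df[-1L])
  rownames(m) <- df$sample_id
  pairwise_matrix(m, kind = kind)
}

#' @rdname read_pairwise_matrix
#' @param m A [pairwise_matrix()] (or square matrix).
#' @export
write_pairwise_matrix <- function(m, path) {
  mm <- as.matrix(m)
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(sample_id = rownames(mm)),
                                    tibble::as_tibble(mm)), path)
  invisible(path)
}

#' Read a community table from a BIOM file
#'
#' Converter entry point for BIOM-format tables; requires the Bioconductor
#' package \pkg{biomformat}.
#'
#' @param path Path to a BIOM file.
#' @return Tibble in the canonical samples-as-rows orientation.
#' @export
read_biom_community <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("package 'biomformat' is required to read BIOM files", call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))  # biom stores OTUs as rows
  community_tbl(as_count_matrix(m))
}

#' Harmonize a community table, phylogeny and metadata
#'
#' Restricts all three inputs to their shared sample and OTU identifiers:
#' OTUs are intersected with the tree's tip set (the tree is pruned when
#' `prune = TRUE`), samples with the metadata's `sample_id`. Dropped
#' identifiers are reported in the `dropped` attribute and as a message.
#'
#' @param table Community table.
#' @param tree `phylo` object whose tips cover (a superset of) the table OTUs.
#' @param metadata Optional per-sample metadata tibble.
#' @param prune Prune the tree to the shared OTU set.
#' @return List with elements `table`, `tree`, `metadata` and attribute
#'   `dropped` (list of dropped OTU/sample/tip ids).
#' @export
harmonize <- function(table, tree = NULL, metadata = NULL, prune = TRUE) {
  m <- as_count_matrix(table)
  dropped <- list(otus = character(), samples = character(),
                  tips = character())
  if (!is.null(tree)) {
    shared_otus <- intersect(colnames(m), tree$tip.label)
    if (length(shared_otus) == 0) {
      stop("no OTUs shared between table and tree", call. = FALSE)
    }
    dropped$otus <- setdiff(colnames(m), shared_otus)
    dropped$tips <- setdiff(tree$tip.label, shared_otus)
    m <- m[, shared_otus, drop = FALSE]
    if (prune && length(dropped$tips) > 0) {
      tree <- ape::keep.tip(tree, shared_otus)
    }
    if (length(dropped$tips) > 0 && !prune) {
      warning("tree tips absent from table: ",
              paste(head(dropped$tips, 5L), collapse = ", "),
              if (length(dropped$tips) > 5L) ", ...", call. = FALSE)
    }
  }
  if (!is.null(metadata)) {
    shared_samples <- intersect(rownames(m), metadata$sample_id)
    if (length(shared_samples) == 0) {
      stop("no samples shared between table and metadata", call. = FALSE)
    }
    dropped$samples <- union(setdiff(rownames(m), shared_samples),
                             setdiff(metadata$sample_id, shared_samples))
    m <- m[shared_samples, , drop = FALSE]
    metadata <- metadata[match(shared_samples, metadata$sample_id), ,
                         drop = FALSE]
  }
  if (length(unlist(dropped)) > 0) {
    message("harmonize: dropped ", length(dropped$otus), " table OTU(s), ",
            length(dropped$tips), " tree tip(s), ",
            length(dropped$samples), " sample(s)")
  }
  out <- list(table = community_tbl(m), tree = tree, metadata = metadata)
  attr(out, "dropped") <- dropped
  out
}
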