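# End-to-end orchestration: a config-driven pipeline reproducing the whole
# analysis graph on any table + tree + metadata triplet, with per-stage
# seeds, TSV/JSON artifacts and a machine-readable run manifest.

PIPELINE_KEYS <- c("table", "tree", "metadata", "second_table", "out_dir",
                   "seed", "subsample_depth", "n_null", "n_perm", "weighted",
                   "groups_column", "env_variables", "ordination",
                   "geo_model", "k_range", "run_null_model", "run_varpart")

# deterministic per-stage seeds derived from the global seed by a counter
stage_seed <- function(base, stage_index) {
  if (is.null(base)) NULL else as.integer((base + 1000L * stage_index) %%
                                            .Machine$integer.max)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  config
}

#' Validate a pipeline configuration
#'
#' Checks key names, path existence and cross-references (subsample depth
#' against the shallowest sample, clustering `k_range` against the sample
#' count, tree presence when the null model is requested) without running
#' any analysis.
#'
#' @param config Named list or path to a YAML configuration.
#' @return Tibble of findings (`level`, `message`); zero rows means valid.
#' @export
validate_config <- function(config) {
  config <- read_config(config)
  findings <- list()
  note <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(level = level,
                                                         message = msg)
  }
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown) > 0) {
    note("error", paste0("unknown config key(s): ",
                         paste(unknown, collapse = ", ")))
  }
  if (is.null(config$table)) {
    note("error", "config lacks required key 'table'")
  } else if (is.character(config$table) && !file.exists(config$table)) {
    note("error", paste0("table path does not exist: ", config$table))
  }
  for (key in c("tree", "metadata", "second_table")) {
    if (is.character(config[[key]]) && !file.exists(config[[key]])) {
      note("error", paste0(key, " path does not exist: ", config[[key]]))
    }
  }
  if (isTRUE(config$run_null_model) && is.null(config$tree)) {
    note("error", "null model requested but no tree supplied")
  }
  tbl <- tryCatch(load_table_input(config$table), error = function(e) NULL)
  if (!is.null(tbl)) {
    tot <- rowSums(as_count_matrix(tbl))
    depth <- config$subsample_depth
    if (!is.null(depth) && !identical(depth, "min") && any(tot < depth)) {
      shallowest <- names(tot)[which.min(tot)]
      note("error", sprintf(
        "subsample depth %s exceeds the shallowest sample '%s' (%d reads)",
        depth, shallowest, min(tot)))
    }
    if (!is.null(config$k_range) && max(config$k_range) >= nrow(tbl)) {
      note("error", sprintf(
        "k_range upper bound %d must be below the sample count %d",
        max(config$k_range), nrow(tbl)))
    }
  }
  if (length(findings) == 0) {
    tibble::tibble(level = character(), message = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

load_table_input <- function(x) {
  if (is.character(x) && length(x) == 1L) read_community_table(x) else
    community_tbl(as_count_matrix(x))
}

#' Run the full analysis pipeline
#'
#' Stage order: harmonize, preprocessing (singleton removal, subsampling to
#' the minimum sample total by default), diversity summaries, Bray-Curtis +
#' NMDS (+ ANOSIM and SIMPER when a group column is present), constrained
#' ordination on VIF-pruned environmental variables, the betaNTI/RC-BC null
#' models with process classification, distance-decay, and PCNM + three-block
#' variation partitioning when a second community table is supplied. Every
#' stochastic stage receives a deterministic per-stage seed derived from the
#' global seed, so identical configs give byte-identical artifacts and any
#' stage can be re-run in isolation.
#'
#' @param config Named list or YAML path. Recognized keys: `table`, `tree`,
#'   `metadata`, `second_table` (paths or in-memory objects), `out_dir`,
#'   `seed`, `subsample_depth` (`"min"` or integer), `n_null`, `n_perm`,
#'   `weighted`, `groups_column`, `env_variables`, `ordination`
#'   (`"cca"`/`"rda"`), `geo_model`, `k_range`, `run_null_model`,
#'   `run_varpart`.
#' @return Named list of stage results (invisibly also written under
#'   `out_dir` with a `manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  findings <- validate_config(config)
  if (any(findings$level == "error")) {
    stop("invalid config:\n  ",
         paste(findings$message[findings$level == "error"],
               collapse = "\n  "), call. = FALSE)
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  seed <- config$seed
  n_null <- config$n_null %||% 999
  n_perm <- config$n_perm %||% 999
  weighted <- config$weighted %||% TRUE
  geo_model <- config$geo_model %||% "spheroid"

  emit_tsv <- function(x, name) {
    if (!is.null(out_dir)) readr::write_tsv(x, file.path(out_dir, name))
  }
  emit_json <- function(x, name) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                           digits = NA)
    }
  }
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  results <- list()
  manifest <- list(package = "betanull",
                   version = as.character(utils::packageVersion("betanull")),
                   config = config[setdiff(names(config), "out_dir")],
                   seeds = list(), parameters = list(n_null = n_null,
                                                     n_perm = n_perm,
                                                     weighted = weighted))

  # stage 1: load + harmonize
  results$inputs <- with_stage("harmonize", {
    tbl <- load_table_input(config$table)
    tree <- if (!is.null(config$tree)) {
      if (is.character(config$tree)) read_phylogeny(config$tree) else
        config$tree
    }
    md <- if (!is.null(config$metadata)) {
      if (is.character(config$metadata)) {
        read_sample_metadata(config$metadata)
      } else {
        config$metadata
      }
    }
    harmonize(tbl, tree, md, prune = TRUE)
  })
  h <- results$inputs

  # stage 2: preprocessing
  results$table <- with_stage("preprocess", {
    tbl <- remove_singletons(h$table)
    depth <- config$subsample_depth %||% "min"
    if (identical(depth, "min")) depth <- min(rowSums(as_count_matrix(tbl)))
    manifest$parameters$subsample_depth <- depth
    manifest$seeds$subsample <- stage_seed(seed, 1L)
    subsample_counts(tbl, depth, seed = stage_seed(seed, 1L))
  })
  emit_tsv(results$table, "table_subsampled.tsv")

  # stage 3: diversity
  results$diversity <- with_stage("diversity", {
    dplyr::left_join(goods_coverage(results$table),
                     alpha_diversity(results$table), by = "sample_id")
  })
  emit_tsv(results$diversity, "diversity.tsv")

  # stage 4: Bray-Curtis + NMDS (+ ANOSIM/SIMPER when groups available)
  results$bray <- with_stage("bray_curtis", bray_curtis(results$table))
  if (!is.null(out_dir)) {
    write_pairwise_matrix(results$bray, file.path(out_dir,
                                                  "bray_curtis.tsv"))
  }
  manifest$seeds$nmds <- stage_seed(seed, 2L)
  results$nmds <- with_stage("nmds",
    nmds(results$bray, seed = stage_seed(seed, 2L)))
  emit_tsv(results$nmds$scores, "nmds_scores.tsv")

  groups <- NULL
  if (!is.null(config$groups_column) && !is.null(h$metadata) &&
      config$groups_column %in% names(h$metadata)) {
    groups <- h$metadata[[config$groups_column]][
      match(results$nmds$scores$sample_id, h$metadata$sample_id)]
  }
  if (!is.null(groups) && length(unique(groups)) >= 2) {
    manifest$seeds$anosim <- stage_seed(seed, 3L)
    results$anosim <- with_stage("anosim",
      anosim(results$bray, groups, n_perm = n_perm,
             seed = stage_seed(seed, 3L), pairwise = TRUE))
    emit_json(list(global_r = results$anosim$statistic,
                   p_value = results$anosim$p_value), "anosim.json")
    results$simper <- with_stage("simper", simper(results$table, groups))
    emit_tsv(results$simper, "simper.tsv")
  }

  # stage 5: constrained ordination on VIF-pruned environment
  if (!is.null(config$env_variables) && !is.null(h$metadata)) {
    results$cca <- with_stage("constrained_ordination", {
      env <- as.data.frame(h$metadata)[config$env_variables]
      pruned <- vif_prune(env)
      manifest$parameters$env_kept <- names(pruned$kept)
      manifest$seeds$cca <- stage_seed(seed, 4L)
      constrained_ordination(results$table, pruned$kept, n_perm = n_perm,
                             seed = stage_seed(seed, 4L),
                             method = config$ordination %||% "cca")
    })
    emit_tsv(results$cca$terms, "cca_terms.tsv")
  }

  # stage 6: null models + classification
  if (!is.null(h$tree) && !identical(config$run_null_model, FALSE)) {
    cfg_b <- null_model_config(n_null = n_null, weighted = weighted,
                               seed = stage_seed(seed, 5L))
    cfg_r <- null_model_config(n_null = n_null, weighted = weighted,
                               seed = stage_seed(seed, 6L))
    manifest$seeds$beta_nti <- stage_seed(seed, 5L)
    manifest$seeds$raup_crick <- stage_seed(seed, 6L)
    results$bnti <- with_stage("beta_nti",
      beta_nti(results$table, h$tree, cfg_b))
    results$rc <- with_stage("raup_crick", raup_crick_bc(results$table,
                                                         cfg_r))
    results$assembly <- with_stage("classify",
      classify_processes(results$bnti, results$rc, cfg_b))
    if (!is.null(out_dir)) {
      write_pairwise_matrix(results$bnti$bnti, file.path(out_dir,
                                                         "bnti.tsv"))
      write_pairwise_matrix(results$rc, file.path(out_dir, "rc_bc.tsv"))
    }
    emit_tsv(results$assembly$pairs, "process_pairs.tsv")
    emit_json(setNames(as.list(results$assembly$fractions$fraction),
                       results$assembly$fractions$process),
              "process_fractions.json")
  }

  # stage 7: spatial analyses
  has_coords <- !is.null(h$metadata) &&
    (all(c("lat", "lon") %in% names(h$metadata)) ||
       all(c("x", "y") %in% names(h$metadata)))
  if (has_coords) {
    results$geo <- with_stage("geo_distances",
      geo_distances(h$metadata, model = geo_model))
    manifest$seeds$distance_decay <- stage_seed(seed, 7L)
    results$distance_decay <- with_stage("distance_decay",
      distance_decay(results$table, results$geo, n_perm = n_perm,
                     seed = stage_seed(seed, 7L)))
    emit_tsv(results$distance_decay$scatter, "distance_decay.tsv")
    emit_json(list(rho = results$distance_decay$mantel$r,
                   p_value = results$distance_decay$mantel$p_value),
              "distance_decay.json")

    if (!is.null(config$second_table) && !is.null(config$env_variables) &&
        !identical(config$run_varpart, FALSE)) {
      results$varpart <- with_stage("varpart", {
        second <- load_table_input(config$second_table)
        b_axes <- community_as_predictors(second)
        s_vecs <- pcnm_vectors(results$geo)
        env <- as.data.frame(h$metadata)[config$env_variables]
        # cap the spatial block at its leading eigenvectors so the three
        # blocks stay below saturation
        n_s <- nrow(env)
        room <- n_s - 2 - ncol(env) - (ncol(b_axes) - 1)
        if (ncol(s_vecs) - 1 > room) {
          s_vecs <- s_vecs[, seq_len(max(room, 1) + 1)]
        }
        manifest$seeds$varpart <- stage_seed(seed, 8L)
        varpart3(results$table, env, b_axes, s_vecs, n_perm = n_perm,
                 seed = stage_seed(seed, 8L))
      })
      emit_json(setNames(as.list(results$varpart$fractions$adj_r_squared),
                         results$varpart$fractions$fraction),
                "varpart_fractions.json")
    }
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
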