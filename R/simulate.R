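# Synthetic-community simulator: birth-death phylogenies, Brownian niche
# evolution, and OTU tables assembled under one of five known ecological
# processes, so that the inference chain can be validated by process
# recovery.

SCENARIO_NAMES <- c("heterogeneous_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal", "drift")

#' Define a simulation scenario
#'
#' One scenario assembles all samples under a single ecological process (no
#' mixtures), so the truth label of a generated dataset is unambiguous.
#'
#' @param name One of `"heterogeneous_selection"`, `"homogeneous_selection"`,
#'   `"dispersal_limitation"`, `"homogenizing_dispersal"`, `"drift"`.
#' @param n_otus Number of OTUs in the metacommunity (>= 2).
#' @param n_samples Number of local communities (>= 2).
#' @param reads_per_sample Sequencing depth per sample (row sums are exact).
#' @param sigma_bm Brownian-motion rate for niche evolution (niche units^2
#'   per unit branch length).
#' @param sigma_sel Niche breadth of the Gaussian environmental filter (niche
#'   units); must be positive for selection scenarios.
#' @param env_values Environmental optima of the sample groups for
#'   heterogeneous selection (two well-separated values) or the single value
#'   for homogeneous selection.
#' @param migration Metacommunity mixing rate in `[0, 1]` for the dispersal
#'   scenarios (default 0.01 for `dispersal_limitation`, 1 for
#'   `homogenizing_dispersal`).
#' @param n_eff Effective resample size for drift/founder steps.
#' @param meanlog,sdlog Lognormal metacommunity rank-abundance parameters.
#' @param birth_rate,death_rate Birth-death rates for the simulated phylogeny.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(name, n_otus = 200, n_samples = 16,
                         reads_per_sample = 10000, sigma_bm = 1,
                         sigma_sel = 0.5, env_values = c(-2, 2),
                         migration = NULL, n_eff = 500,
                         meanlog = 0, sdlog = 1.5,
                         birth_rate = 1, death_rate = 0) {
  if (!name %in% SCENARIO_NAMES) {
    stop("unknown scenario '", name, "'; must be one of: ",
         paste(SCENARIO_NAMES, collapse = ", "), call. = FALSE)
  }
  if (n_otus < 2 || n_samples < 2 || reads_per_sample < 2 || n_eff < 2) {
    stop("all counts must be >= 2", call. = FALSE)
  }
  if (grepl("selection", name) && sigma_sel <= 0) {
    stop("sigma_sel must be positive for selection scenarios", call. = FALSE)
  }
  if (is.null(migration)) {
    migration <- switch(name, dispersal_limitation = 0.01,
                        homogenizing_dispersal = 1, 0)
  }
  if (migration < 0 || migration > 1) {
    stop("migration must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, n_otus = as.integer(n_otus),
                 n_samples = as.integer(n_samples),
                 reads_per_sample = as.integer(reads_per_sample),
                 sigma_bm = sigma_bm, sigma_sel = sigma_sel,
                 env_values = env_values, migration = migration,
                 n_eff = as.integer(n_eff), meanlog = meanlog, sdlog = sdlog,
                 birth_rate = birth_rate, death_rate = death_rate),
            class = "sim_scenario")
}

#' Simulate a birth-death phylogeny
#'
#' Rooted binary tree with `n_otus` tips labelled `OTU_1 .. OTU_n` and
#' strictly positive branch lengths, via [ape::rphylo()].
#'
#' @param n_otus Number of tips (>= 2).
#' @param birth_rate Speciation rate; must exceed `death_rate`.
#' @param death_rate Extinction rate (>= 0).
#' @param seed Optional RNG seed.
#' @return A `phylo` object.
#' @export
sim_tree <- function(n_otus, birth_rate = 1, death_rate = 0, seed = NULL) {
  if (n_otus < 2) stop("n_otus must be >= 2", call. = FALSE)
  if (death_rate < 0 || birth_rate <= death_rate) {
    stop("need birth_rate > death_rate >= 0", call. = FALSE)
  }
  run <- function() ape::rphylo(n_otus, birth = birth_rate,
                                death = death_rate)
  tr <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tr$tip.label <- paste0("OTU_", seq_len(n_otus))
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  tr
}

#' Simulate niche optima by Brownian motion
#'
#' One trait value per tip, evolved from a root value of 0 with independent
#' Gaussian increments of variance `sigma_bm * branch length`. Close
#' relatives therefore carry similar niche optima — the phylogenetic signal
#' that the betaNTI null model assumes.
#'
#' @param tree `phylo` object with branch lengths.
#' @param sigma_bm Brownian rate (trait variance per unit branch length).
#' @param seed Optional RNG seed.
#' @return Named numeric vector of tip niche optima.
#' @export
sim_niches <- function(tree, sigma_bm = 1, seed = NULL) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (sum(tree$edge.length) <= 0) {
    stop("total tree depth is zero; Brownian motion undefined", call. = FALSE)
  }
  run <- function() {
    tr <- stats::reorder(tree)  # cladewise: parents before children
    n_tip <- length(tr$tip.label)
    val <- numeric(n_tip + tr$Nnode)
    val[n_tip + 1L] <- 0  # root
    steps <- rnorm(nrow(tr$edge), mean = 0,
                   sd = sqrt(sigma_bm * tr$edge.length))
    for (e in seq_len(nrow(tr$edge))) {
      val[tr$edge[e, 2L]] <- val[tr$edge[e, 1L]] + steps[e]
    }
    setNames(val[seq_len(n_tip)], tr$tip.label)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out[tree$tip.label]
}

#' Assemble communities under a known ecological process
#'
#' Metacommunity abundances are lognormal. Selection scenarios weight each
#' OTU by a Gaussian filter of its niche optimum around the sample's
#' environment and draw multinomial communities; drift inserts a per-sample
#' bottleneck resample of size `n_eff`; dispersal limitation runs a serial
#' founder chain along a one-dimensional transect with metacommunity
#' immigration at rate `migration`; homogenizing dispersal resamples every
#' community from one shared pool.
#'
#' @param scenario A [sim_scenario()].
#' @param tree Phylogeny from [sim_tree()] (tips = OTUs).
#' @param niche_optima Named vector from [sim_niches()].
#' @param seed Optional RNG seed.
#' @return List of class `sim_output`: `table` (tibble of counts), `tree`,
#'   `metadata` (tibble), `niche_optima`, `truth` (scenario name).
#' @export
assemble_communities <- function(scenario, tree, niche_optima, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  otus <- tree$tip.label
  if (length(otus) != scenario$n_otus) {
    stop("tree has ", length(otus), " tips but scenario expects ",
         scenario$n_otus, call. = FALSE)
  }
  if (!all(otus %in% names(niche_optima))) {
    stop("niche_optima does not cover all tree tips", call. = FALSE)
  }
  opt <- niche_optima[otus]
  run <- function() {
    n_s <- scenario$n_samples
    n_o <- scenario$n_otus
    reads <- scenario$reads_per_sample
    meta_ab <- rlnorm(n_o, meanlog = scenario$meanlog,
                      sdlog = scenario$sdlog)
    env <- assign_environments(scenario)
    counts <- matrix(0L, n_s, n_o,
                     dimnames = list(sprintf("S%02d", seq_len(n_s)), otus))
    if (scenario$name %in% c("heterogeneous_selection",
                             "homogeneous_selection")) {
      for (j in seq_len(n_s)) {
        w <- meta_ab * exp(-(opt - env$e[j])^2 / (2 * scenario$sigma_sel^2))
        if (sum(w) <= 0) w <- meta_ab
        counts[j, ] <- as.vector(rmultinom(1L, reads, w / sum(w)))
      }
    } else if (scenario$name == "drift") {
      for (j in seq_len(n_s)) {
        pool <- as.vector(rmultinom(1L, scenario$n_eff,
                                    meta_ab / sum(meta_ab)))
        counts[j, ] <- as.vector(rmultinom(1L, reads, pool / sum(pool)))
      }
    } else if (scenario$name == "homogenizing_dispersal") {
      pool <- as.vector(rmultinom(1L, scenario$n_eff,
                                  meta_ab / sum(meta_ab)))
      for (j in seq_len(n_s)) {
        counts[j, ] <- as.vector(rmultinom(1L, reads, pool / sum(pool)))
      }
    } else {  # dispersal_limitation: serial founder chain
      meta_p <- meta_ab / sum(meta_ab)
      pool <- as.vector(rmultinom(1L, scenario$n_eff, meta_p))
      counts[1L, ] <- as.vector(rmultinom(1L, reads, pool / sum(pool)))
      for (j in seq_len(n_s)[-1L]) {
        mix <- (1 - scenario$migration) * pool / sum(pool) +
          scenario$migration * meta_p
        pool <- as.vector(rmultinom(1L, scenario$n_eff, mix))
        counts[j, ] <- as.vector(rmultinom(1L, reads, pool / sum(pool)))
      }
    }
    metadata <- tibble::tibble(
      sample_id = rownames(counts),
      lat = 18 + rnorm(n_s, 0, 0.02),
      lon = 110 + (seq_len(n_s) - 1) * 0.5,
      depth_m = 5,
      temperature = env$temperature,
      salinity = 33.5 + 0.05 * (seq_len(n_s) - 1) + rnorm(n_s, 0, 0.02),
      group = env$group
    )
    list(counts = counts, metadata = metadata, meta_ab = meta_ab)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(table = community_tbl(out$counts), tree = tree,
                 metadata = out$metadata, niche_optima = opt,
                 metacommunity = out$meta_ab, truth = scenario$name,
                 scenario = scenario),
            class = "sim_output")
}

# per-sample environments, temperatures and group labels
assign_environments <- function(scenario) {
  n_s <- scenario$n_samples
  if (scenario$name == "heterogeneous_selection") {
    half <- floor(n_s / 2)
    e <- c(rep(scenario$env_values[1L], half),
           rep(scenario$env_values[2L], n_s - half))
    group <- c(rep("G1", half), rep("G2", n_s - half))
    list(e = e, temperature = e, group = group)
  } else if (scenario$name == "homogeneous_selection") {
    e <- rep(scenario$env_values[1L], n_s)
    list(e = e, temperature = e, group = rep("G1", n_s))
  } else {
    thirds <- cut(seq_len(n_s), 3L, labels = c("CWM", "sOWM", "ssOWM"))
    list(e = rep(NA_real_, n_s),
         temperature = 25 + rnorm(n_s, 0, 0.5),
         group = as.character(thirds))
  }
}

#' Simulate a complete dataset for one scenario
#'
#' Convenience wrapper chaining [sim_tree()], [sim_niches()] and
#' [assemble_communities()] under a single seed.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Optional RNG seed (drives tree, niches and assembly).
#' @return A `sim_output` list.
#' @export
simulate_dataset <- function(scenario, seed = NULL) {
  run <- function() {
    tree <- sim_tree(scenario$n_otus, scenario$birth_rate,
                     scenario$death_rate)
    niche <- sim_niches(tree, scenario$sigma_bm)
    assemble_communities(scenario, tree, niche)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write a simulated dataset to disk
#'
#' Emits the OTU table (TSV, samples as rows), tree (Newick), metadata (TSV)
#' and a truth sidecar (JSON) into `dir`.
#'
#' @param x A `sim_output` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_sim_output <- function(x, dir) {
  stopifnot(inherits(x, "sim_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "otu_table.tsv"),
             tree = file.path(dir, "tree.nwk"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_community_table(x$table, paths["table"])
  write_phylogeny(x$tree, paths["tree"])
  write_sample_metadata(x$metadata, paths["metadata"])
  jsonlite::write_json(list(truth = x$truth,
                            scenario = unclass(x$scenario)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output: %s, %d samples x %d OTUs, %d reads/sample>\n",
              x$truth, nrow(x$table), ncol(x$table) - 1L,
              x$scenario$reads_per_sample))
  invisible(x)
}
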