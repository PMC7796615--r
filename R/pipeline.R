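# End-to-end orchestration: simulate -> coverage -> expression ->
# rearrange -> editing -> associate, from a single config with a single
# seed, writing TSV/JSON outputs plus a run manifest.

#' Pipeline run configuration
#'
#' @param n_species number of synthetic species.
#' @param sim a [sim_config()] for the ancestral genome and the per-species
#'   read simulation.
#' @param k_step inversions per speciation step along the species chain.
#' @param n_edit_sites injected C-to-U sites per species.
#' @param edit_efficiency_range efficiency range for injected sites.
#' @param caller a [caller_config()].
#' @param distance_method "dcj" or "breakpoint".
#' @param transform expression transform, "log10p1" or "raw".
#' @param window coverage window size (bp).
#' @param stages character vector of stages to run, a subset of
#'   `c("coverage", "expression", "rearrangement", "editing", "association")`.
#' @param seed master seed; per-species and per-stage seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_species = 6L, sim = sim_config(), k_step = 2L,
                       n_edit_sites = 8L, edit_efficiency_range = c(0.2, 0.9),
                       caller = caller_config(), distance_method = "dcj",
                       transform = "log10p1", window = 100L,
                       stages = c("coverage", "expression", "rearrangement",
                                  "editing", "association"),
                       seed = 1L) {
  stopifnot(n_species >= 2L, inherits(sim, "sim_config"),
            inherits(caller, "caller_config"),
            distance_method %in% c("dcj", "breakpoint"),
            transform %in% c("log10p1", "raw"))
  bad <- setdiff(stages, c("coverage", "expression", "rearrangement",
                           "editing", "association"))
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(list(n_species = as.integer(n_species), sim = sim,
                 k_step = as.integer(k_step),
                 n_edit_sites = as.integer(n_edit_sites),
                 edit_efficiency_range = edit_efficiency_range,
                 caller = caller, distance_method = distance_method,
                 transform = transform, window = as.integer(window),
                 stages = stages, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Flat key/value JSON; keys mirror the arguments of [run_config()],
#' [sim_config()] (prefix `sim_`) and [caller_config()] (prefix `caller_`).
#'
#' @param path JSON file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(prefix, fn) {
    keys <- names(raw)[startsWith(names(raw), prefix)]
    args <- raw[keys]
    names(args) <- substring(names(args), nchar(prefix) + 1L)
    do.call(fn, args)
  }
  sim <- pick("sim_", sim_config)
  caller <- pick("caller_", caller_config)
  top <- raw[!grepl("^(sim_|caller_)", names(raw))]
  do.call(run_config, c(top, list(sim = sim, caller = caller)))
}

#' Run the pipeline end to end
#'
#' Simulates a chain of `n_species` rearranged plastomes with stranded
#' reads and injected edits, then runs the requested stages and writes
#' machine-readable outputs under `out_dir`: per-species expression and
#' coverage TSVs, editing site tables, block/distance matrices, the pair
#' table, a JSON summary with the two headline tests, and a run manifest
#' recording parameters and seeds. Deterministic given the config.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); NULL to skip
#'   writing files.
#' @return result bundle (list) with the per-stage objects, invisibly
#'   written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[plastidflow] stage: %s", name))
  res <- list(config = config)
  write_out <- !is.null(out_dir)
  if (write_out) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage("simulate")
  species <- paste0("sp", seq_len(config$n_species))
  sims <- vector("list", config$n_species)
  names(sims) <- species
  genome <- NULL
  for (i in seq_len(config$n_species)) {
    cfg_i <- config$sim
    cfg_i$seed <- child_seed(config$seed, i)
    sims[[i]] <- simulate_species(
      cfg_i, id = species[i],
      k_inversions = if (i == 1L) 0L else config$k_step * (i - 1L),
      n_edit_sites = config$n_edit_sites,
      edit_efficiency_range = config$edit_efficiency_range
    )
    message(sprintf("  %s: %d bp, %d genes, %d read pairs, %d injected edits",
                    species[i], sims[[i]]$genome$length,
                    nrow(sims[[i]]$genome$features),
                    cfg_i$n_read_pairs,
                    if (is.null(sims[[i]]$manifest$edits)) 0L else nrow(sims[[i]]$manifest$edits)))
  }
  res$species <- species
  res$sims <- sims

  if ("coverage" %in% config$stages) {
    stage("coverage")
    res$coverage <- lapply(sims, function(s) {
      cov <- per_base_coverage(s$records, s$genome)
      list(coverage = cov,
           fraction = transcribed_fraction(cov),
           windows_plus = window_scores(cov$plus, config$window),
           windows_minus = window_scores(cov$minus, config$window))
    })
    if (write_out) {
      for (sp in species) {
        wp <- res$coverage[[sp]]$windows_plus; wp$strand <- "+"
        wm <- res$coverage[[sp]]$windows_minus; wm$strand <- "-"
        utils::write.table(rbind(wp, wm),
                           file.path(out_dir, paste0(sp, "_coverage_windows.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  if ("expression" %in% config$stages || "association" %in% config$stages) {
    stage("expression")
    res$expression <- lapply(sims, function(s) expression_table(s$records, s$genome))
    if (write_out) {
      for (sp in species) {
        utils::write.table(res$expression[[sp]],
                           file.path(out_dir, paste0(sp, "_expression.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  if ("rearrangement" %in% config$stages || "association" %in% config$stages) {
    stage("rearrangement")
    orders <- lapply(sims, function(s) gene_order(s$genome))
    blocks <- find_synteny_blocks(orders)
    res$blocks <- blocks
    res$pr_matrix <- pairwise_matrix(blocks$genomes, method = config$distance_method)
    message(sprintf("  %d syntenic blocks; pairwise %s distances 0-%d",
                    blocks$n_blocks, config$distance_method, max(res$pr_matrix)))
    if (write_out) {
      utils::write.table(res$pr_matrix, file.path(out_dir, "rearrangement_matrix.tsv"),
                         sep = "\t", quote = FALSE)
      bl <- do.call(rbind, lapply(species, function(sp) {
        perm <- blocks$genomes[[sp]]
        data.frame(species = sp, order_index = seq_along(perm),
                   block = paste0("B", abs(perm)), sign = sign(perm))
      }))
      utils::write.table(bl, file.path(out_dir, "synteny_blocks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("editing" %in% config$stages) {
    stage("editing")
    res$editing <- lapply(sims, function(s) {
      pu <- build_pileup(s$records, s$genome)
      sites <- call_c2u(pu, s$genome, config$caller)
      classify_sites(sites, s$genome, s$genome)
    })
    if (write_out) {
      for (sp in species) {
        utils::write.table(res$editing[[sp]],
                           file.path(out_dir, paste0(sp, "_editing_sites.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  if ("association" %in% config$stages) {
    stage("association")
    res$expr_matrix <- expression_correlation_matrix(res$expression,
                                                     transform = config$transform)
    # Genetic distances from a clock-like chain tree over the species.
    nwk <- chain_tree_newick(species, step = 0.01)
    tree <- ape::read.tree(text = nwk)
    res$tree <- tree
    res$dist_matrix <- patristic_distances(tree, species)
    res$pair_table <- build_pair_table(res$expr_matrix, res$pr_matrix, res$dist_matrix)
    res$headline <- headline_analysis(res$pair_table)
    message(sprintf("  PR ~ distance: r = %.3f, p = %.3g; PR ~ r_expr: r = %.3f, p = %.3g",
                    res$headline$pr_vs_distance$r, res$headline$pr_vs_distance$p,
                    res$headline$pr_vs_expression$r, res$headline$pr_vs_expression$p))
    if (write_out) {
      utils::write.table(res$pair_table, file.path(out_dir, "pair_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(pr_vs_distance = res$headline$pr_vs_distance,
             pr_vs_expression = res$headline$pr_vs_expression),
        file.path(out_dir, "headline.json"), auto_unbox = TRUE, digits = NA
      )
    }
  }

  if (write_out) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("plastidflow")),
      r_version = R.version.string,
      seed = config$seed,
      n_species = config$n_species,
      stages = config$stages,
      n_read_pairs = config$sim$n_read_pairs,
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

# Newick for a clock-like caterpillar tree over the species chain.
chain_tree_newick <- function(species, step = 0.01) {
  n <- length(species)
  tip <- function(i, len) sprintf("%s:%g", species[i], len)
  sub <- tip(n, step)
  for (i in (n - 1L):1L) {
    sub <- sprintf("(%s,%s):%g", tip(i, step), sub, if (i > 1L) step else 0)
  }
  paste0(sub, ";")
}

#' Subsample read pairs mate-consistently
#'
#' Uniform sample of `n` read pairs without replacement; both mates of a
#' selected pair are kept.
#'
#' @param records alignment-record data.frame.
#' @param n number of pairs to keep.
#' @param seed RNG seed.
#' @return subsampled records (original row order preserved).
#' @export
subsample_reads <- function(records, n, seed = 1L) {
  ids <- unique(records$read_id)
  if (n > length(ids)) stopf("requested %d pairs but only %d present", n, length(ids))
  if (n == 0L) return(records[0L, , drop = FALSE])
  keep <- with_seed(seed, sample(ids, n))
  records[records$read_id %in% keep, , drop = FALSE]
}
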