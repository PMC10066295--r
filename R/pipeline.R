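## End-to-end orchestration over the stage functions. Plain-text outputs
## only (TSV + JSON) so every artifact is diffable; a JSON run manifest
## records the tool version, canonical config hash, seeds, checksums and
## the resolved analysis parameters (window, fence multiplier, sigma(0)
## convention) so published defaults are auditable in outputs.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    counts = list(n_groups = 1000L, baseline_mean = 36,
                  distances = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5),
                  species = c("A", "B", "C", "D", "E", "F")),
    trends = list(multiplier = 1.5),
    genomes = list(n_chromosomes = 2L, genes_per_chromosome = 30L,
                   gene_length = 300L, intergenic_length = 200L,
                   neutral_rate = 0),
    loss = list(window = 5L, evalue = 1e-5),
    simulate = list(n_genes = 10L, connectivity = 1, k_values = c(2L, 5L, 8L),
                    trials_per_k = 50L, modes = c("deletion", "duplication")),
    stages = c("synthetic", "trends", "loss", "simulate"))
}

validate_config <- function(user, defaults = pipeline_defaults(),
                            path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      validate_config(user[[key]], defaults[[key]], full)
    }
  }
  invisible(TRUE)
}

## Canonical hash of a config: md5 of its JSON with recursively sorted
## keys, so the hash is stable under key reordering.
config_hash <- function(config) {
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, sort_rec)
    } else x
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(sort_rec(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the requested stages in dependency order: synthetic-data
#' generation, the copy-number trend scan, the synteny-anchored loss
#' caller, and the network perturbation ensembles. All outputs are
#' plain-text TSV/JSON under `out_dir`; a `manifest.json` records the
#' package version, config hash, seed, per-file md5 checksums and resolved
#' parameters. Reruns with the same config and seed produce byte-identical
#' data outputs (the manifest's timestamp differs).
#'
#' @param config `NULL` (defaults), a named list, or the path of a YAML or
#'   JSON config file. Recognised keys: `seed`, `counts`, `trends`,
#'   `genomes`, `loss`, `simulate`, `stages`; unknown keys are rejected by
#'   name.
#' @param out_dir Output directory.
#' @param seed Optional override of the config seed.
#' @param verbose Emit per-stage messages.
#' @return The run manifest, invisibly.
#' @export
run_full_pipeline <- function(config = NULL, out_dir, seed = NULL,
                              verbose = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  validate_config(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- as.integer(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[genelossr] ", sprintf(...))
  outputs <- character(0)
  resolved <- list(sigma0_convention = "+1",
                   deleted_state = 0,
                   fence_multiplier = cfg$trends$multiplier,
                   window = cfg$loss$window,
                   evalue_threshold = cfg$loss$evalue)

  counts_obj <- NULL; toy <- NULL
  if ("synthetic" %in% cfg$stages) {
    say("stage make-synthetic")
    ccfg <- count_synth_config(
      n_groups = cfg$counts$n_groups, species = cfg$counts$species,
      distances = cfg$counts$distances,
      baseline_mean = cfg$counts$baseline_mean,
      seed = derive_seed(cfg$seed, 101L))
    counts_obj <- make_count_matrix(ccfg)
    outputs <- c(outputs, write_tsv(
      data.frame(group_id = rownames(counts_obj$counts),
                 counts_obj$counts, check.names = FALSE),
      file.path(out_dir, "counts.tsv")))
    outputs <- c(outputs, write_tsv(counts_obj$truth,
                                    file.path(out_dir, "counts_truth.tsv")))
    tree_txt <- make_tree(cfg$counts$species, cfg$counts$distances)
    writeLines(tree_txt, file.path(out_dir, "counts_tree.nwk"))
    outputs <- c(outputs, file.path(out_dir, "counts_tree.nwk"))
    gcfg <- genome_synth_config(
      n_chromosomes = cfg$genomes$n_chromosomes,
      genes_per_chromosome = cfg$genomes$genes_per_chromosome,
      gene_length = cfg$genomes$gene_length,
      intergenic_length = cfg$genomes$intergenic_length,
      neutral_rate = cfg$genomes$neutral_rate,
      seed = derive_seed(cfg$seed, 102L))
    toy <- make_toy_genomes(gcfg)
    outputs <- c(outputs, write_genomes(toy, file.path(out_dir, "genomes")))
  }

  trends <- NULL
  if ("trends" %in% cfg$stages && !is.null(counts_obj)) {
    say("stage trends")
    trends <- classify_trends(counts_obj$counts, counts_obj$distances,
                              multiplier = cfg$trends$multiplier)
    outputs <- c(outputs,
                 write_tsv(as.data.frame(trends),
                           file.path(out_dir, "rates.tsv")))
    s <- attr(trends, "summary"); f <- attr(trends, "fences")
    outputs <- c(outputs, write_tsv(
      data.frame(n_groups = s["n_groups"], n_eligible = s["n_eligible"],
                 n_contracting = s["n_contracting"],
                 n_expanding = s["n_expanding"],
                 lower_fence = f$lower_fence, upper_fence = f$upper_fence),
      file.path(out_dir, "rates_summary.tsv")))
  }

  loss <- NULL
  if ("loss" %in% cfg$stages && !is.null(toy)) {
    say("stage classify-loss")
    loss <- classify_loss(toy$genomes, toy$table,
                          contracting_ids = unname(toy$groups),
                          anchor_species = toy$anchor_species,
                          species_tree = toy$tree,
                          window = cfg$loss$window,
                          threshold = cfg$loss$evalue)
    outputs <- c(outputs,
                 write_tsv(loss$calls, file.path(out_dir, "loss_calls.tsv")),
                 write_tsv(loss$patterns,
                           file.path(out_dir, "loss_patterns.tsv")),
                 write_tsv(as.data.frame(loss$summary$per_species),
                           file.path(out_dir, "loss_per_species.tsv")))
    if (!is.null(loss$chisq)) {
      outputs <- c(outputs, write_tsv(
        data.frame(statistic = loss$chisq$statistic, df = loss$chisq$df,
                   p_value = loss$chisq$p_value),
        file.path(out_dir, "loss_chisq.tsv")))
    }
  }

  sim <- NULL
  if ("simulate" %in% cfg$stages) {
    say("stage simulate")
    scfg <- simulation_config(
      n_genes = cfg$simulate$n_genes,
      connectivity = cfg$simulate$connectivity,
      k_values = cfg$simulate$k_values,
      trials_per_k = cfg$simulate$trials_per_k,
      seed = derive_seed(cfg$seed, 103L))
    sim <- do.call(rbind, lapply(cfg$simulate$modes, function(m) {
      run_ensemble(scfg, m)
    }))
    outputs <- c(outputs, write_tsv(as.data.frame(sim),
                                    file.path(out_dir, "simulation.tsv")))
  }

  manifest <- list(
    tool = "genelossr",
    version = as.character(utils::packageVersion("genelossr")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    parameters = resolved,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %d outputs", length(outputs))
  invisible(manifest)
}
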