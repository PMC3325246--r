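recipe_catalogue <- function() {
  data.frame(
    recipe = c("stability_vs_N", "stability_vs_density", "map_comparison",
               "weight_comparison", "steepness_sweep", "topology_comparison",
               "zero_convention_comparison", "period_distribution",
               "transient_scaling", "discovery_curve",
               "bimodality_enumeration"),
    emulates = c("stability versus network size (main size sweep)",
                 "stability versus density/in-degree (sparse vs dense)",
                 "+/-1 map versus 0/1 map stability",
                 "binary +/-1 versus Gaussian weight stability",
                 "sigmoid steepness sweep against the step norm",
                 "regular vs Poisson vs exponential-in/power-law-out",
                 "sigma(0) tie-break convention comparison",
                 "attractor period distribution with parity split",
                 "mean fixed-point transient versus network size",
                 "samples needed to discover distinct stable phenotypes",
                 "exact per-matrix stability histogram (bimodality)"),
    stringsAsFactors = FALSE)
}

#' List the built-in experiment recipes
#'
#' Each recipe is a reproducible, seeded experiment tying the generator,
#' dynamics and stability modules together, named for the model comparison
#' it performs.
#'
#' @return data frame with columns `recipe` and `emulates`.
#' @examples
#' list_recipes()
#' @export
list_recipes <- function() recipe_catalogue()

cfg_get <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

cfg_ensemble <- function(config, defaults = list()) {
  get2 <- function(name, fallback) cfg_get(config, name,
                                           cfg_get(defaults, name, fallback))
  args <- list(n_genes = get2("n_genes", 10),
               topology = get2("topology", "regular"),
               weight_scheme = get2("weight_scheme", "binary_pm1"),
               allow_self_loops = get2("allow_self_loops", TRUE))
  k <- cfg_get(config, "k", cfg_get(defaults, "k", NULL))
  density <- cfg_get(config, "density", cfg_get(defaults, "density", NULL))
  if (is.null(k) && is.null(density)) density <- 1
  args$k <- k; args$density <- density
  do.call(ensemble_spec, args)
}

cfg_dynamics <- function(config) {
  dynamics_spec(map = cfg_get(config, "map", "pm1"),
                norm = cfg_get(config, "norm", "step"),
                steepness = cfg_get(config, "steepness", NULL),
                zero_convention = cfg_get(config, "zero_convention", "minus"),
                t_max = cfg_get(config, "t_max", NULL),
                eps = cfg_get(config, "eps", 1e-6),
                window = cfg_get(config, "window", 10L))
}

log_line <- function(log_path, ...) {
  cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
}

run_sweep_recipe <- function(axis, grid, config, out_dir, log_path) {
  ens <- cfg_ensemble(config)
  dyn <- cfg_dynamics(config)
  n_trials <- cfg_get(config, "n_trials", 10000L)
  tab <- sweep_stability(axis, grid, ens, dyn, n_trials,
                         seed = cfg_get(config, "seed", 1L))
  path <- file.path(out_dir, paste0(config$recipe, ".tsv"))
  write_sweep(tab, path)
  log_line(log_path, "grid points: %d, n_trials per point: %d",
           nrow(tab), n_trials)
  log_line(log_path, "unresolved fractions: %s",
           paste(sprintf("%s=%.4g", tab$value, tab$unresolved / tab$omega),
                 collapse = ", "))
  path
}

#' Run a named experiment recipe from a configuration file
#'
#' Reads a flat YAML configuration (field `recipe` selects the experiment;
#' `seed`, `n_trials`, `grid` and any [ensemble_spec()] / [dynamics_spec()]
#' field override the defaults), executes the recipe, and writes its results
#' to `out_dir`: one or more TSV tables, a JSON run manifest capturing the
#' full configuration, seed and package version, and a plain-text log with
#' the iteration-cap policy and unresolved-run fractions. Re-running the
#' same configuration and seed reproduces the tables byte for byte.
#'
#' @param config_path path to a YAML configuration file, or a named list
#'   with the same fields.
#' @param out_dir output directory (created if missing); defaults to the
#'   config's `out_dir` field, else a directory named after the recipe.
#' @return the output directory path, invisibly.
#' @export
run_experiment <- function(config_path, out_dir = NULL) {
  config <- if (is.character(config_path)) yaml::read_yaml(config_path)
            else config_path
  recipes <- recipe_catalogue()$recipe
  if (is.null(config$recipe))
    stop("config is missing the `recipe` field", call. = FALSE)
  if (!config$recipe %in% recipes)
    stop(sprintf("unknown recipe '%s'; catalogued recipes: %s",
                 config$recipe, paste(recipes, collapse = ", ")),
         call. = FALSE)
  if (is.null(out_dir)) out_dir <- cfg_get(config, "out_dir", config$recipe)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)  # truncate
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  seed <- cfg_get(config, "seed", 1L)
  n_trials <- cfg_get(config, "n_trials", 10000L)
  log_line(log_path, "recipe: %s", config$recipe)
  log_line(log_path, "seed: %d", seed)
  log_line(log_path,
           "t_max policy: %s",
           if (is.null(config$t_max))
             "min(2^N + 1, max(1e4, 100 N)) discrete; max(1e4, 100 N) continuous"
           else sprintf("fixed at %d", config$t_max))

  outputs <- switch(config$recipe,
    stability_vs_N = run_sweep_recipe(
      "N", cfg_get(config, "grid", c(4, 8, 16)), config, out_dir, log_path),
    stability_vs_density = run_sweep_recipe(
      "c_or_K", cfg_get(config, "grid", c(2, 5, 10, 20)), config, out_dir,
      log_path),
    map_comparison = run_sweep_recipe(
      "map", cfg_get(config, "grid", c("pm1", "zero_one")), config, out_dir,
      log_path),
    weight_comparison = run_sweep_recipe(
      "weight_scheme", cfg_get(config, "grid",
                               c("binary_pm1", "real_gaussian")),
      config, out_dir, log_path),
    steepness_sweep = run_sweep_recipe(
      "steepness", cfg_get(config, "grid", c(1, 5, 25, 100)), config,
      out_dir, log_path),
    topology_comparison = run_sweep_recipe(
      "topology", cfg_get(config, "grid",
                          c("regular", "poisson", "bio_exp_in_pow_out")),
      config, out_dir, log_path),
    zero_convention_comparison = run_sweep_recipe(
      "zero_convention", cfg_get(config, "grid",
                                 c("minus", "plus", "keep_previous",
                                   "quenched_random")),
      config, out_dir, log_path),
    period_distribution = {
      dist <- period_distribution(cfg_ensemble(config), cfg_dynamics(config),
                                  n_trials, seed = seed)
      tab <- data.frame(period = dist$periods, count = dist$counts,
                        frequency = dist$counts / dist$total)
      path <- file.path(out_dir, "period_distribution.tsv")
      write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
      log_line(log_path, "resolved attractors: %d; unresolved: %d",
               dist$total, dist$n_unresolved)
      log_line(log_path, "even/odd cycle counts: %d / %d",
               dist$even_cycles, dist$odd_cycles)
      path
    },
    transient_scaling = {
      grid <- cfg_get(config, "grid", c(4, 8, 16))
      specs <- lapply(grid, function(nv)
        cfg_ensemble(list(n_genes = nv), defaults = config))
      tab <- transient_summary(specs, cfg_dynamics(config), n_trials,
                               seed = seed)
      path <- file.path(out_dir, "transient_scaling.tsv")
      write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
      path
    },
    discovery_curve = {
      curve <- discovery_curve(cfg_ensemble(config), cfg_dynamics(config),
                               target_count = cfg_get(config, "target_count",
                                                      NULL),
                               max_samples = cfg_get(config, "max_samples",
                                                     n_trials),
                               seed = seed)
      path <- file.path(out_dir, "discovery_curve.tsv")
      write.table(curve$events, path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      log_line(log_path, "discovered %d phenotypes in %d samples%s",
               curve$n_discovered, curve$total_samples,
               if (curve$censored) " (censored)" else "")
      path
    },
    bimodality_enumeration = {
      n <- cfg_get(config, "n_genes", 3L)
      k <- cfg_get(config, "k", n)
      est <- exact_stability(n, k, cfg_dynamics(config))
      tab <- as.data.frame(table(stability = est$per_matrix),
                           stringsAsFactors = FALSE)
      names(tab) <- c("stability", "n_matrices")
      path <- file.path(out_dir, "bimodality_enumeration.tsv")
      write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
      log_line(log_path, "exact S = %.6f over %d pairs", est$s, est$omega)
      path
    })

  manifest <- list(
    recipe = config$recipe,
    config = config,
    seed = seed,
    package_version = as.character(packageVersion("rtnstab")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}
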