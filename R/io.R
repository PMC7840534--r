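## CSV and YAML I/O, run configuration and the pipeline driver.

.plant_cols <- function() c("plant_id", trait_names(), "total_seeds")

#' Read and validate a plant table
#'
#' Expects a UTF-8 CSV with header columns `plant_id`, the six traits
#' (see [trait_names()]) and `total_seeds`. Rows with missing values are
#' kept (the selection stage applies listwise deletion and reports it);
#' negative seed counts are an error.
#'
#' @param path CSV file path.
#' @return Validated plant data frame.
#' @export
read_plant_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.plant_cols(), names(df))
  if (length(miss))
    stop_validation("plant table ", path, " missing column(s): ",
                    paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop_validation("plant table ", path, " is empty")
  if (any(df$total_seeds < 0, na.rm = TRUE))
    stop_validation("negative seed counts in ", path)
  if (anyDuplicated(df$plant_id))
    stop_validation("duplicate plant_id values in ", path)
  message("read ", nrow(df), " plants from ", path)
  df[, .plant_cols()]
}

#' Read and validate a visit table
#'
#' Expects columns `plant_id`, `species`, `flowers_visited`. Duplicate
#' plant x species rows (separate observation bouts) are summed with a
#' note. Species labels can be validated against an expected set.
#'
#' @param path CSV file path.
#' @param species Optional character vector of allowed species labels.
#' @return Aggregated visit data frame, one row per plant x species.
#' @export
read_visit_table <- function(path, species = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "species", "flowers_visited")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation("visit table ", path, " missing column(s): ",
                    paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop_validation("visit table ", path, " is empty")
  if (!is.null(species)) {
    bad <- setdiff(unique(df$species), species)
    if (length(bad))
      stop_validation("unknown species in ", path, ": ",
                      paste(bad, collapse = ", "))
  }
  n0 <- nrow(df)
  agg <- aggregate_visits(df)
  if (nrow(agg) < n0)
    message("summed ", n0 - nrow(agg), " duplicate plant x species row(s)")
  message("read ", nrow(agg), " visit records from ", path)
  agg
}

#' Write a data frame as UTF-8 CSV
#' @param df Data frame. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble or read a run configuration
#'
#' A run configuration bundles everything a pipeline run needs: input
#' paths (or a simulate block), species tripping rates, fitness bases,
#' bootstrap and permutation settings, the log-model policy and the global
#' seed. `read_config()` loads it from YAML; `run_config()` builds it in
#' code. Unspecified fields take the defaults below.
#'
#' @param plants,visits Input CSV paths (ignored when `simulate` is set).
#' @param simulate `NULL`, or a list with optional `n_plants` and model
#'   overrides, to generate inputs instead of reading them.
#' @param tripping_rates Named per-species rates.
#' @param bases Fitness bases to run.
#' @param bootstrap List: `B`, `level`, `restandardize`.
#' @param permutations Permutation count for the DSD stage.
#' @param log_model,log_offset Log-model policy (see [selection_report()]).
#' @param out_dir Output directory.
#' @param seed Global seed; all stage streams derive from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(plants = NULL, visits = NULL, simulate = NULL,
                       tripping_rates = c(bumble = 0.55, honey = 0.25,
                                          leafcutting = 0.80),
                       bases = c("visited", "tripped", "total"),
                       bootstrap = list(B = 1000, level = 0.95,
                                        restandardize = TRUE),
                       permutations = 1999,
                       log_model = TRUE, log_offset = NULL,
                       out_dir = ".", seed = 1) {
  if (is.null(simulate) && (is.null(plants) || is.null(visits)))
    stop_config("either input paths (plants, visits) or a simulate block ",
                "is required")
  if ("tripped" %in% bases && is.null(tripping_rates))
    stop_config("tripped basis requested but no tripping rates configured")
  assert_scalar_number(seed, "seed")
  structure(list(plants = plants, visits = visits, simulate = simulate,
                 tripping_rates = tripping_rates, bases = bases,
                 bootstrap = bootstrap, permutations = permutations,
                 log_model = log_model, log_offset = log_offset,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML config file path.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tr <- raw$tripping_rates
  if (!is.null(tr)) tr <- unlist(tr)
  do.call(run_config, c(
    raw[intersect(names(raw), setdiff(names(formals(run_config)),
                                      "tripping_rates"))],
    if (!is.null(tr)) list(tripping_rates = tr)))
}

#' Run the full pipeline and write its artifacts
#'
#' Stages: simulate (optional) -> attribute -> select -> dsd. Writes
#' `plants.csv`/`visits.csv` (when simulating), `fitness.csv`,
#' `selection_report.csv`, `dsd_report.csv` and `manifest.yaml` (seed,
#' settings, package version, row counts) under `config$out_dir`.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @param stages Subset of `c("simulate", "attribute", "select", "dsd")`;
#'   default runs everything configured.
#' @return Invisible named list of artifact paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "attribute", "select", "dsd")) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config"))
    stop_config("config must be a run_config or a YAML path")
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(config$simulate) && "simulate" %in% stages) {
    sim <- step("simulate", {
      s <- config$simulate
      simulate_study(n_plants = s$n_plants %||% 153,
                     traits = s$traits %||% trait_model(),
                     preference = s$preference %||% preference_model(),
                     yield = s$yield %||% yield_model(),
                     seed = config$seed)
    })
    plants <- sim$plants; visits <- sim$visits
    paths$plants <- write_table_csv(plants, file.path(config$out_dir, "plants.csv"))
    paths$visits <- write_table_csv(visits, file.path(config$out_dir, "visits.csv"))
    paths$truth <- write_table_csv(sim$truth, file.path(config$out_dir, "truth.csv"))
  } else {
    plants <- step("read", read_plant_table(config$plants))
    visits <- step("read", read_visit_table(config$visits,
                                            names(config$tripping_rates)))
  }
  if ("attribute" %in% stages) {
    ft <- step("attribute",
               fitness_table(plants, visits, config$tripping_rates,
                             bases = config$bases))
    ft$seed <- config$seed
    paths$fitness <- write_table_csv(ft, file.path(config$out_dir, "fitness.csv"))
  }
  if ("select" %in% stages) {
    bs <- bootstrap_settings(B = config$bootstrap$B %||% 1000,
                             level = config$bootstrap$level %||% 0.95,
                             seed = stage_seed(config$seed, "bootstrap"),
                             restandardize =
                               config$bootstrap$restandardize %||% TRUE)
    sel <- step("select",
                selection_report(plants, visits, config$tripping_rates,
                                 settings = bs, bases = config$bases,
                                 log_model = config$log_model,
                                 log_offset = config$log_offset))
    paths$selection <- write_table_csv(
      sel, file.path(config$out_dir, "selection_report.csv"))
  }
  if ("dsd" %in% stages) {
    dr <- step("dsd",
               dsd_report(plants, visits, config$tripping_rates,
                          bases = config$bases, B = config$permutations,
                          seed = stage_seed(config$seed, "permutation")))
    paths$dsd <- write_table_csv(dr, file.path(config$out_dir, "dsd_report.csv"))
  }
  manifest <- list(
    package = "pollselect",
    version = as.character(utils::packageVersion("pollselect")),
    seed = config$seed,
    bases = config$bases,
    tripping_rates = as.list(config$tripping_rates),
    bootstrap = config$bootstrap,
    permutations = config$permutations,
    n_plants = nrow(plants),
    n_visit_rows = nrow(visits),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  paths$manifest <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)
  message("pipeline complete; artifacts in ", config$out_dir)
  invisible(paths)
}
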