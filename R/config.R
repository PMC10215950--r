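#' Validate a pipeline configuration
#'
#' Accepts a raw list (e.g. parsed from YAML) or a YAML file path, fills in
#' the study defaults (alpha 0.005, k grid 1,2,3,5,10,20,30,50, 100
#' replicates), and reports every invalid field at once.
#'
#' Recognized fields:
#' \describe{
#'   \item{input}{path of the genotype CSV/TSV (omit when `simulate` given).}
#'   \item{dialect}{`csv` (default) or `tsv`.}
#'   \item{outcome_column}{outcome column name (default `syntax_score`).}
#'   \item{learner}{`alpha`, `test`, `max_cond`.}
#'   \item{resampling}{`k_grid`, `replicates`, `master_seed`.}
#'   \item{simulate}{`n_snps`, `n`, `strength`, `seed`, `mb_size`,
#'     `missing_rate` for the synthetic generator.}
#'   \item{outcome_bins}{quantile bins for the local-structure analysis.}
#'   \item{output_dir}{artifact directory.}
#'   \item{force}{overwrite an existing output directory.}
#' }
#'
#' @param raw list, YAML file path, or `NULL` for an all-default config.
#' @return object of class `run_config`.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw)) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a mapping")
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)
  get <- function(path, default) {
    x <- raw
    for (p in path) {
      if (!is.list(x) || is.null(x[[p]])) return(default)
      x <- x[[p]]
    }
    x
  }
  cfg <- list(
    input = get("input", NULL),
    dialect = get("dialect", "csv"),
    outcome_column = get("outcome_column", "syntax_score"),
    alpha = get(c("learner", "alpha"), 0.005),
    test = get(c("learner", "test"), "g2"),
    max_cond = get(c("learner", "max_cond"), 3L),
    k_grid = get(c("resampling", "k_grid"),
                 c(1L, 2L, 3L, 5L, 10L, 20L, 30L, 50L)),
    replicates = get(c("resampling", "replicates"), 100L),
    master_seed = get(c("resampling", "master_seed"), 1L),
    simulate = get("simulate", NULL),
    outcome_bins = get("outcome_bins", 3L),
    output_dir = get("output_dir", "causalstab-output"),
    force = isTRUE(get("force", FALSE)))
  if (!is.numeric(cfg$alpha) || length(cfg$alpha) != 1 ||
      cfg$alpha <= 0 || cfg$alpha >= 1)
    note("learner.alpha must be a number in (0, 1)")
  if (!cfg$test %in% c("g2", "symmetric"))
    note("learner.test must be 'g2' or 'symmetric'")
  if (!is.numeric(cfg$max_cond) || cfg$max_cond < 0)
    note("learner.max_cond must be a non-negative integer")
  if (!is.numeric(cfg$k_grid) || !length(cfg$k_grid) ||
      any(cfg$k_grid < 0) ||
      is.unsorted(cfg$k_grid, strictly = TRUE))
    note("resampling.k_grid must be strictly increasing non-negative integers")
  if (!is.numeric(cfg$replicates) || cfg$replicates < 1)
    note("resampling.replicates must be a positive integer")
  if (!is.numeric(cfg$outcome_bins) || cfg$outcome_bins < 2)
    note("outcome_bins must be an integer >= 2")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    note(paste0("input file not found: ", cfg$input))
  if (!cfg$dialect %in% c("csv", "tsv"))
    note("dialect must be 'csv' or 'tsv'")
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  structure(cfg, class = "run_config")
}

config_plan <- function(cfg) {
  resampling_plan(cfg$k_grid, cfg$replicates, cfg$master_seed)
}

config_settings <- function(cfg) {
  learner_settings(alpha = cfg$alpha, test = cfg$test,
                   max_cond = cfg$max_cond)
}

load_input <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    arg <- function(nm, default) if (is.null(sim[[nm]])) default else sim[[nm]]
    sc <- gess_like_scenario(n_snps = arg("n_snps", 25L),
                             n = arg("n", 597L),
                             seed = arg("seed", cfg$master_seed),
                             strength = arg("strength", 5),
                             mb_size = arg("mb_size", 4L),
                             missing_rate = arg("missing_rate", 0))
    list(ds = simulate_dataset(sc), scenario = sc)
  } else {
    if (is.null(cfg$input)) stop("either 'input' or 'simulate' must be given")
    list(ds = read_genotype_table(cfg$input, cfg$dialect,
                                  outcome_column = cfg$outcome_column),
         scenario = NULL)
  }
}

#' Run a pipeline stage
#'
#' Entry point wiring the modules into the study flow. Commands:
#' \describe{
#'   \item{simulate}{write a synthetic dataset, its true structure, and a
#'     scenario manifest into `output_dir`.}
#'   \item{learn}{learn the CPDAG of the (filtered) input and write it.}
#'   \item{pillar1}{leave-k-out stability of the zero-outcome and
#'     positive-outcome structures.}
#'   \item{pillar2}{stability of the similarity between the two structures.}
#'   \item{pillar3}{stability of the outcome's Markov blanket (positive-
#'     outcome subjects).}
#'   \item{all}{all three pillars plus the summary tables.}
#' }
#'
#' @param command one of `"simulate"`, `"learn"`, `"pillar1"`, `"pillar2"`,
#'   `"pillar3"`, `"all"`.
#' @param config a `run_config`, raw list, YAML path or `NULL`.
#' @return the output directory, invisibly.
#' @export
run_command <- function(command = c("all", "simulate", "learn", "pillar1",
                                    "pillar2", "pillar3"),
                        config = NULL) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir <- cfg$output_dir
  if (dir.exists(dir) && !cfg$force)
    stop("output directory exists (set force: true): ", dir)
  plan <- config_plan(cfg)
  settings <- config_settings(cfg)

  if (command == "simulate") {
    inp <- load_input(if (is.null(cfg$simulate)) {
      cfg$simulate <- list(); cfg
    } else cfg)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genotype_table(inp$ds, file.path(dir, "dataset.csv"))
    write_graph(inp$scenario$dag, file.path(dir, "true_structure.graph"))
    yaml::write_yaml(list(
      n = inp$scenario$n, seed = inp$scenario$seed,
      outcome = inp$scenario$outcome_name,
      planted_mb = inp$scenario$planted_mb,
      cardinalities = as.list(inp$scenario$cardinalities)),
      file.path(dir, "scenario.yaml"))
    return(invisible(dir))
  }

  inp <- load_input(cfg)
  ds <- complete_case_filter(inp$ds, quiet = TRUE)

  if (command == "learn") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    parts <- split_by_outcome(ds)
    g0 <- learn_with(parts$zero_part, settings)
    g1 <- learn_with(parts$positive_part, settings)
    write_graph(g0, file.path(dir, "structure_ss0.graph"))
    write_graph(g1, file.path(dir, "structure_ss1.graph"))
    return(invisible(dir))
  }

  parts <- split_by_outcome(ds)
  p1a <- p1b <- p2 <- p3 <- NULL
  if (command %in% c("pillar1", "all")) {
    p1a <- run_pillar_one(parts$zero_part, plan, settings)
    p1b <- run_pillar_one(parts$positive_part, plan, settings)
  }
  if (command %in% c("pillar2", "all"))
    p2 <- run_pillar_two(parts$zero_part, parts$positive_part, plan, settings)
  if (command %in% c("pillar3", "all")) {
    pos <- split_by_outcome(ds, drop_outcome = FALSE)$positive_part
    pos <- discretize_outcome(pos, bins = cfg$outcome_bins)
    p3 <- run_pillar_three(pos, plan = plan, settings = settings)
  }
  echo <- unclass(cfg)
  echo$output_dir <- NULL  # destination-independent manifest
  echo$force <- NULL
  summarize_tables(dir,
                   pillar1 = if (!is.null(p1a)) p1a,
                   pillar2 = p2, pillar3 = p3,
                   config = echo, force = cfg$force)
  if (!is.null(p1b)) {
    utils::write.csv(format_pillar_one(p1b),
                     file.path(dir, "pillar1_positive_wide.csv"),
                     row.names = FALSE)
    utils::write.csv(p1b$long, file.path(dir, "pillar1_positive_long.csv"),
                     row.names = FALSE)
    write_graph(p1b$reference, file.path(dir, "pillar1_positive_reference.graph"))
  }
  invisible(dir)
}

#' @rdname run_command
#' @export
run_all <- function(config = NULL) run_command("all", config)
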