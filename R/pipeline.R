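#' Read a pipeline configuration file
#'
#' Plain `key = value` text. Unknown keys are errors (typo safety); known
#' keys are typed and given defaults.
#'
#' @param path config file path (omit for all defaults).
#' @return named list of typed settings.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    n_participants = 20L, n_mazes = 8L, n_rooms = 4L,
    model_mix = "DU=1", tau_range = "0.2,1.5", gamma_range = "0.2,0.9",
    beta_range = "0.35,1.5", b_range = "0.5,10", k_range = "0,1",
    time_initial = "2880,-163,530", time_subsequent = "1069,55,-134",
    time_sd = 400, models = "EU,DU,Steps,Cells,Steps-Cells,Random",
    grid = "coarse", n_folds = 5L, n_boot = 1000L)
  cfg <- defaults
  if (!is.null(path)) {
    kv <- read_kv(path)
    unknown <- setdiff(names(kv), names(defaults))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (k in names(kv)) {
      cfg[[k]] <- if (is.numeric(defaults[[k]])) as.numeric(kv[[k]])
        else if (is.integer(defaults[[k]])) as.integer(kv[[k]])
        else kv[[k]]
    }
  }
  cfg
}

parse_mix <- function(s) {
  parts <- strsplit(strsplit(s, ",")[[1]], "=")
  v <- vapply(parts, function(p) as.numeric(p[2]), 1)
  names(v) <- vapply(parts, `[`, "", 1)
  v
}

parse_range <- function(s) as.numeric(strsplit(s, ",")[[1]])

config_to_cohort <- function(cfg, mazes, seed) {
  cohort_config(
    n_participants = as.integer(cfg$n_participants), mazes = mazes,
    model_mix = parse_mix(cfg$model_mix),
    param_ranges = list(tau = parse_range(cfg$tau_range),
                        gamma = parse_range(cfg$gamma_range),
                        beta = parse_range(cfg$beta_range),
                        B = parse_range(cfg$b_range),
                        k_weight = parse_range(cfg$k_range)),
    time_initial = parse_range(cfg$time_initial),
    time_subsequent = parse_range(cfg$time_subsequent),
    time_sd = as.numeric(cfg$time_sd),
    seed = derive_seed(seed, "cohort"))
}

#' Write a run manifest
#'
#' Records the command, the configuration snapshot, the master seed, the
#' package version, and digests of the output files, so every artifact can
#' be traced to the run that produced it.
#' @param command subcommand name.
#' @param cfg configuration list.
#' @param seed master seed.
#' @param outputs character vector of output paths.
#' @param path manifest destination (JSON).
#' @export
write_manifest <- function(command, cfg, seed, outputs, path) {
  digests <- if (length(outputs)) as.list(tools::md5sum(outputs)) else list()
  jsonlite::write_json(list(
    command = command, config = cfg, seed = seed,
    version = as.character(utils::packageVersion("mazeplan")),
    outputs = digests), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

cli_log <- function(...) message("[mazeplan] ", sprintf(...))

#' Command-line pipeline entry point
#'
#' Subcommands (all accept `--seed`, `--config`, `--out`):
#' \describe{
#'   \item{maze}{`maze validate <file>` / `maze tree <file|fixture>`:
#'     validate a maze or export its decision tree.}
#'   \item{simulate}{generate mazes and a synthetic cohort; writes the
#'     decision log, maze files, and generating parameters.}
#'   \item{fit}{fit a model list to a decision log.}
#'   \item{compare}{rank fitted models and label individuals by family.}
#'   \item{correlate}{aggregate first choices and bootstrap the
#'     correlation with each model's predictions.}
#'   \item{regress}{decision-time regression tables.}
#'   \item{recover}{end-to-end parameter-recovery study (simulate, fit,
#'     report the generating-vs-fitted correlation).}
#' }
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return exit status (0 on success), invisibly.
#' @export
mst_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({ mst_cli_run(args); 0L },
                     error = function(e) {
                       message("error: ", conditionMessage(e))
                       1L
                     })
  invisible(status)
}

cli_flag <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1] == length(args)) stop("missing value for ", flag, call. = FALSE)
  args[i[1] + 1L]
}

mst_cli_run <- function(args) {
  if (!length(args)) stop("usage: <maze|simulate|fit|compare|correlate|regress|recover> ...")
  cmd <- args[1]
  seed <- as.integer(cli_flag(args, "--seed", "1"))
  out <- cli_flag(args, "--out", "mazeplan_out")
  cfg <- read_config(cli_flag(args, "--config"))
  if (!dir.exists(out) && cmd != "maze") dir.create(out, recursive = TRUE)

  load_mazes_dir <- function(dir) {
    files <- list.files(dir, pattern = "\\.maze$", full.names = TRUE)
    mz <- lapply(files, read_maze_ascii)
    names(mz) <- vapply(mz, `[[`, "", "maze_id")
    mz
  }
  load_log <- function() {
    path <- file.path(out, "decisions.tsv")
    if (!file.exists(path)) stop("no decision log at ", path)
    read_decision_log(path)
  }

  switch(cmd,
    "maze" = {
      sub <- args[2]
      target <- args[3]
      fx <- fixture_mazes()
      mz <- if (target %in% names(fx)) fx[[target]] else
        read_maze_ascii(target)
      if (identical(sub, "validate")) {
        v <- validate_maze(mz)
        cat(jsonlite::toJSON(v, auto_unbox = TRUE, pretty = TRUE), "\n")
        if (!v$ok) stop("maze failed validation")
      } else if (identical(sub, "tree")) {
        tr <- build_tree(mz)
        dest <- cli_flag(args, "--out", paste0(mz$maze_id, "_tree.tsv"))
        write_tree(tr, dest)
        cli_log("wrote %s (%d nodes)", dest, length(tr$nodes))
      } else stop("unknown maze subcommand: ", sub)
    },
    "simulate" = {
      mazes <- lapply(seq_len(cfg$n_mazes), function(i)
        generate_maze(n_rooms = as.integer(cfg$n_rooms),
                      seed = derive_seed(seed, paste0("maze", i)),
                      maze_id = sprintf("m%03d", i)))
      names(mazes) <- vapply(mazes, `[[`, "", "maze_id")
      cc <- config_to_cohort(cfg, mazes, seed)
      res <- generate_cohort(cc)
      write_decision_log(res$decisions, file.path(out, "decisions.tsv"))
      utils::write.table(res$participants, file.path(out, "participants.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      for (mid in names(mazes))
        write_maze_ascii(mazes[[mid]], file.path(out, paste0(mid, ".maze")))
      write_manifest("simulate", cfg, seed,
                     file.path(out, c("decisions.tsv", "participants.tsv")),
                     file.path(out, "manifest.json"))
      cli_log("simulated %d participants on %d mazes (%d decisions)",
              cc$n_participants, length(mazes), nrow(res$decisions))
    },
    "fit" = {
      mazes <- load_mazes_dir(out)
      decisions <- load_log()
      trees <- lapply(mazes, build_tree)
      models <- strsplit(cfg$models, ",")[[1]]
      grids <- if (identical(cfg$grid, "coarse")) coarse_grids()
               else default_grids()
      fits <- fit_cohort(decisions, trees, models, grids,
                         n_folds = as.integer(cfg$n_folds),
                         seed = derive_seed(seed, "folds"))
      utils::write.table(fits$table, file.path(out, "fits.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      write_manifest("fit", cfg, seed, file.path(out, "fits.tsv"),
                     file.path(out, "manifest_fit.json"))
      cli_log("fitted %d models to %d participants", length(models),
              length(unique(decisions$participant_id)))
    },
    "compare" = {
      fits <- utils::read.table(file.path(out, "fits.tsv"), header = TRUE,
                                sep = "\t")
      cmpr <- compare_models(fits)
      utils::write.table(cmpr$ranking, file.path(out, "ranking.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(cmpr$individuals, file.path(out, "families.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      print(cmpr$ranking)
    },
    "correlate" = {
      mazes <- load_mazes_dir(out)
      decisions <- load_log()
      trees <- lapply(mazes, build_tree)
      fits <- utils::read.table(file.path(out, "fits.tsv"), header = TRUE,
                                sep = "\t")
      models <- unique(fits$model_id)
      rows <- list()
      for (m in setdiff(models, "Sampling")) {
        fm <- fits[fits$model_id == m, , drop = FALSE]
        mean_pars <- list(model_id = m)
        for (p in c("tau", "gamma", "beta", "B", "k_weight")) {
          v <- suppressWarnings(mean(fm[[p]], na.rm = TRUE))
          if (is.finite(v)) mean_pars[[p]] <- v
        }
        pars <- do.call(model_params, mean_pars)
        pred <- predict_choice_probs(trees, pars)
        bc <- bootstrap_model_correlation(decisions, pred,
                                          n_boot = as.integer(cfg$n_boot),
                                          seed = derive_seed(seed, "boot"))
        rows[[m]] <- data.frame(model_id = m, r = bc$r, lo = bc$ci[1],
                                hi = bc$ci[2], n = bc$n)
      }
      tab <- do.call(rbind, rows)
      utils::write.table(tab, file.path(out, "correlations.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      print(tab)
    },
    "regress" = {
      decisions <- load_log()
      fits <- utils::read.table(file.path(out, "fits.tsv"), header = TRUE,
                                sep = "\t")
      model <- intersect(c("PW-DU", "DU-Num", "DU", "EU"),
                         unique(fits$model_id))[1]
      pars <- fits[fits$model_id == model, , drop = FALSE]
      sp <- split_decision_times(decisions)
      ri <- regress_times(sp$initial, pars, model)
      rs <- regress_times(sp$subsequent, pars, model)
      write_regression_table(ri, rs, file.path(out, "regression.tsv"))
      cli_log("decision-time regression on %s parameters (n = %d + %d)",
              model, ri$n, rs$n)
    },
    "recover" = {
      mazes <- lapply(seq_len(cfg$n_mazes), function(i)
        generate_maze(n_rooms = as.integer(cfg$n_rooms),
                      seed = derive_seed(seed, paste0("maze", i)),
                      maze_id = sprintf("m%03d", i)))
      names(mazes) <- vapply(mazes, `[[`, "", "maze_id")
      cc <- config_to_cohort(cfg, mazes, seed)
      res <- generate_cohort(cc)
      trees <- res$trees
      fits <- fit_cohort(res$decisions, trees, "DU", coarse_grids(),
                         seed = derive_seed(seed, "folds"))
      m <- merge(res$participants, fits$table, by = "participant_id",
                 suffixes = c("_true", "_fit"))
      r <- cor(m$gamma_true, m$gamma_fit)
      utils::write.table(m, file.path(out, "recovery.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      cli_log("gamma recovery correlation: %.3f (n = %d)", r, nrow(m))
      cat(sprintf("gamma_recovery_r\t%.4f\n", r))
    },
    stop("unknown subcommand: ", cmd))
  invisible(NULL)
}
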