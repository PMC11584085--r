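#' Default parameter grids for model fitting
#'
#' Likelihoods are maximized by grid search (the discrete, multi-modal
#' likelihood surface makes gradient methods unreliable). `tau` is
#' log-spaced on `[0.01, 10]`; `gamma` steps by 0.05; `beta` covers
#' `0.1..2` by 0.1 plus 2.5 and 3; `B` uses a coarse grid over
#' `[0.1, 10]` (channel tables are cached per value); `k_weight` steps by
#' 0.1.
#'
#' @param tau_n number of temperature grid points.
#' @return named list of numeric grids.
#' @export
default_grids <- function(tau_n = 31L) {
  list(
    tau = exp(seq(log(0.01), log(10), length.out = tau_n)),
    gamma = seq(0, 1, by = 0.05),
    beta = c(seq(0.1, 2, by = 0.1), 2.5, 3),
    B = c(0.1, 0.25, 0.5, 1, 2, 4, 7, 10),
    k_weight = seq(0, 1, by = 0.1),
    mcts_budget = c(20L, 100L, 400L),
    mcts_exploration = c(0.5, 1, 2)
  )
}

#' Reduced grids for large simulation studies
#' @rdname default_grids
#' @export
coarse_grids <- function() {
  list(
    tau = exp(seq(log(0.05), log(5), length.out = 7L)),
    gamma = seq(0, 1, by = 0.1),
    beta = seq(0.2, 2, by = 0.3),
    B = c(0.25, 1, 4, 10),
    k_weight = seq(0, 1, by = 0.25),
    mcts_budget = 100L,
    mcts_exploration = 1
  )
}

# names of non-tau ("cost") parameters each model reads
model_cost_params <- function(model_id) {
  switch(model_id,
    "EU" = character(0),
    "DU" = "gamma",
    "PW" = "beta",
    "PW-DU" = c("gamma", "beta"),
    "EU-Num" = "B",
    "DU-Num" = c("gamma", "B"),
    "Sampling" = c("mcts_budget", "mcts_exploration"),
    "Steps" = character(0),
    "Cells" = character(0),
    "Steps-Cells" = "k_weight",
    "Steps-Num" = "B",
    "Cells-Num" = "B",
    "Steps-Cells-Num" = c("k_weight", "B"),
    "Random" = character(0),
    stop("unknown model: ", model_id, call. = FALSE))
}

# expand the cost-parameter grid for a model: data.frame (>= 1 row)
cost_param_grid <- function(model_id, grids) {
  ps <- model_cost_params(model_id)
  if (!length(ps)) return(data.frame(.dummy = 0)[, 0, drop = FALSE])
  expand.grid(grids[ps], KEEP.OUT.ATTRS = FALSE)
}

# per-node cost vectors for one maze tree under one model and one row of
# cost parameters, memoized in `cache` (an environment)
cached_costs <- function(tree, model_id, cp, cache) {
  key <- paste(tree$maze_id, model_id,
               paste(sprintf("%.6g", as.numeric(cp)), collapse = "_"),
               sep = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  par <- do.call(model_params, c(list(model_id = model_id), as.list(cp)))
  v <- model_costs(tree, par)
  cache[[key]] <- v
  v
}

# option-level layout of a decision log: one row per (decision, option)
decision_layout <- function(decisions) {
  opt <- strsplit(decisions$option_ids, ",")
  n_opt <- lengths(opt)
  data.frame(
    decision = rep(seq_len(nrow(decisions)), n_opt),
    maze_id = rep(decisions$maze_id, n_opt),
    option_id = as.integer(unlist(opt)),
    chosen = as.integer(unlist(opt)) ==
      rep(decisions$chosen_id, n_opt)
  )
}

# log choice probability of each decision for every (cost combo x tau):
# returns matrix D x (n_cost * n_tau), cost combos varying slowest
decision_logp <- function(decisions, trees, model_id, grids,
                          cache = new.env(parent = emptyenv()),
                          mcts_seed = 1L) {
  D <- nrow(decisions)
  lay <- decision_layout(decisions)
  cpg <- cost_param_grid(model_id, grids)
  taus <- grids$tau
  if (model_id == "Random")
    return(matrix(rep(log(1 / decisions$n_options), 1), ncol = 1))

  n_cp <- max(1L, nrow(cpg))
  out <- matrix(NA_real_, D, n_cp * length(taus))
  for (j in seq_len(n_cp)) {
    cp <- cpg[j, , drop = FALSE]
    oc <- numeric(nrow(lay))
    for (mid in unique(lay$maze_id)) {
      rows <- lay$maze_id == mid
      tree <- trees[[mid]]
      if (model_id == "Sampling") {
        # stochastic value estimates, seeded per (maze, node, combo)
        drows <- which(decisions$maze_id == mid)
        for (d in drows) {
          opts <- lay$decision == d
          seedd <- (mcts_seed + 131L * decisions$node_id[d] + 7L * j) %%
            .Machine$integer.max
          oc[opts] <- mcts_node_values(
            tree, decisions$node_id[d],
            budget = cp$mcts_budget, exploration = cp$mcts_exploration,
            seed = seedd)
        }
      } else {
        cv <- cached_costs(tree, model_id, cp, cache)
        oc[rows] <- cv[lay$option_id[rows]]
      }
    }
    fac <- factor(lay$decision, levels = seq_len(D))
    for (t in seq_along(taus)) {
      z <- -oc / taus[t]
      per_mx <- as.numeric(tapply(z, fac, max))
      ez <- exp(z - per_mx[lay$decision])
      lse <- log(as.numeric(tapply(ez, fac, sum)))
      logp <- (z - per_mx[lay$decision])[lay$chosen] - lse
      out[, (j - 1L) * length(taus) + t] <- logp
    }
  }
  out
}

#' Fit one model to one individual's decisions
#'
#' Penalized maximum-likelihood grid search with fivefold
#' cross-validation. Decisions are randomly partitioned into folds
#' (seeded); on each fold's training set the parameters maximize the log
#' posterior (log-likelihood plus an improper `1/tau` prior, i.e.
#' `-ln tau`, with uniform priors on all other parameters); the fold's
#' test log-likelihood is evaluated at that MAP. Model performance is the
#' total test log-likelihood across folds.
#'
#' @param decisions data.frame of this individual's decisions (columns
#'   `maze_id`, `node_id`, `option_ids`, `chosen_id`, `n_options`); at
#'   least 5 rows, each with >= 2 options.
#' @param trees named list of `mst_tree` objects keyed by `maze_id`.
#' @param model_id model to fit.
#' @param grids parameter grids, see [default_grids()].
#' @param n_folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param cache optional environment memoizing cost vectors across calls
#'   (share it across participants fitting the same mazes).
#' @return a `fit_result` list: `model_id`, `best_params` (full-data MAP),
#'   `fold_test_ll`, `total_test_ll`, `train_ll` (full-data at MAP),
#'   `n_decisions`.
#' @export
fit_individual <- function(decisions, trees, model_id,
                           grids = default_grids(), n_folds = 5L, seed = 1L,
                           cache = new.env(parent = emptyenv())) {
  if (nrow(decisions) < n_folds)
    stop("insufficient data: need at least ", n_folds, " decisions",
         call. = FALSE)
  if (any(decisions$n_options < 2L))
    stop("single-option decisions must be excluded", call. = FALSE)
  if (!length(grids$tau)) stop("empty tau grid", call. = FALSE)

  logp <- decision_logp(decisions, trees, model_id, grids, cache)
  cpg <- cost_param_grid(model_id, grids)
  n_cp <- max(1L, nrow(cpg))
  if (model_id == "Random") {
    prior <- 0
    taus <- NA_real_
  } else {
    taus <- rep(grids$tau, times = n_cp)
    prior <- -log(taus) # improper 1/tau prior on the softmax temperature
  }

  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = nrow(decisions)))
  fold_ll <- numeric(n_folds)
  fold_best <- integer(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    train <- colSums(logp[tr, , drop = FALSE]) + prior
    best <- which.max(train)
    fold_best[f] <- best
    fold_ll[f] <- sum(logp[!tr, best, drop = FALSE])
  }

  full <- colSums(logp) + prior
  best <- which.max(full)
  best_params <- param_row(model_id, best, cpg, grids)

  structure(list(model_id = model_id, best_params = best_params,
                 fold_test_ll = fold_ll,
                 total_test_ll = sum(fold_ll),
                 train_ll = sum(logp[, best]),
                 n_decisions = nrow(decisions)),
            class = "fit_result")
}

# parameter values of grid column `idx` (cost combos vary slowest)
param_row <- function(model_id, idx, cpg, grids) {
  if (model_id == "Random") return(list())
  n_tau <- length(grids$tau)
  j <- (idx - 1L) %/% n_tau + 1L
  t <- (idx - 1L) %% n_tau + 1L
  out <- list(tau = grids$tau[t])
  if (nrow(cpg)) out <- c(out, as.list(cpg[j, , drop = FALSE]))
  out
}

#' Fit several models to every participant in a decision log
#'
#' @param decisions cohort decision log (must include `participant_id`).
#' @param trees named list of `mst_tree` keyed by `maze_id`.
#' @param models character vector of model ids.
#' @inheritParams fit_individual
#' @return list with `table` (one row per participant x model:
#'   `participant_id`, `model_id`, `total_test_ll`, `train_ll`,
#'   `n_decisions`, fitted parameter columns) and `fits` (nested list of
#'   `fit_result`).
#' @export
fit_cohort <- function(decisions, trees, models, grids = default_grids(),
                       n_folds = 5L, seed = 1L) {
  cache <- new.env(parent = emptyenv())
  pids <- unique(decisions$participant_id)
  rows <- list(); fits <- list()
  for (pid in pids) {
    dd <- decisions[decisions$participant_id == pid, , drop = FALSE]
    pseed <- (seed + 7919L * match(pid, pids)) %% .Machine$integer.max
    for (m in models) {
      fr <- fit_individual(dd, trees, m, grids, n_folds, seed = pseed,
                           cache = cache)
      fits[[as.character(pid)]][[m]] <- fr
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, model_id = m,
        total_test_ll = fr$total_test_ll, train_ll = fr$train_ll,
        n_decisions = fr$n_decisions,
        tau = fr$best_params$tau %||% NA_real_,
        gamma = fr$best_params$gamma %||% NA_real_,
        beta = fr$best_params$beta %||% NA_real_,
        B = fr$best_params$B %||% NA_real_,
        k_weight = fr$best_params$k_weight %||% NA_real_)
    }
  }
  list(table = do.call(rbind, rows), fits = fits)
}

#' Rank models and label individuals by best family
#'
#' Orders models by total test log-likelihood summed over participants
#' (reported as `delta_ll` against the best model; fits must cover the
#' same decisions for every model) and, per individual, compares the best
#' planning model against the best heuristic.
#'
#' @param fit_table the `table` element of [fit_cohort()].
#' @return list with `ranking` (model, total LL, delta_ll) and
#'   `individuals` (participant, best planner, best heuristic, winning
#'   family).
#' @export
compare_models <- function(fit_table) {
  chk <- tapply(fit_table$n_decisions, fit_table$participant_id,
                function(x) length(unique(x)))
  if (any(chk != 1L))
    stop("mismatched decision sets across models", call. = FALSE)
  tot <- aggregate(total_test_ll ~ model_id, fit_table, sum)
  tot <- tot[order(-tot$total_test_ll), ]
  tot$delta_ll <- max(tot$total_test_ll) - tot$total_test_ll
  ranking <- tot

  per <- split(fit_table, fit_table$participant_id)
  ind <- do.call(rbind, lapply(per, function(d) {
    pl <- d[d$model_id %in% planner_models, , drop = FALSE]
    he <- d[d$model_id %in% heuristic_models, , drop = FALSE]
    bp <- if (nrow(pl)) pl$model_id[which.max(pl$total_test_ll)] else NA
    bh <- if (nrow(he)) he$model_id[which.max(he$total_test_ll)] else NA
    fam <- if (!nrow(pl)) "heuristic" else if (!nrow(he)) "planner"
      else if (max(pl$total_test_ll) >= max(he$total_test_ll)) "planner"
      else "heuristic"
    data.frame(participant_id = d$participant_id[1],
               best_planner = bp, best_heuristic = bh, family = fam)
  }))
  rownames(ind) <- NULL
  list(ranking = ranking, individuals = ind)
}

#' Closed-form total test log-likelihood of the Random model
#'
#' The Random model assigns every option the same cost, so each decision
#' contributes `ln(1 / m)` for `m` available options regardless of folds
#' or parameters.
#' @param decisions decision log with an `n_options` column.
#' @return scalar log-likelihood.
#' @export
random_model_ll <- function(decisions) {
  sum(log(1 / decisions$n_options))
}

#' Empirical first-choice probabilities per maze
#'
#' Aggregates initial (root) decisions across participants into the
#' empirical probability of each root option.
#'
#' @param decisions cohort decision log.
#' @param initial_only use only `is_initial` decisions (default). When
#'   `FALSE`, all decision nodes are aggregated and options at nodes
#'   visited by fewer than `min_visit` of the participants are dropped.
#' @param min_visit visitation threshold for the all-decisions variant.
#' @return data.frame (`maze_id`, `node_id`, `option_id`, `prob`, `n`).
#' @export
aggregate_first_choices <- function(decisions, initial_only = TRUE,
                                    min_visit = 0.2) {
  dd <- if (initial_only) decisions[decisions$is_initial, , drop = FALSE]
        else decisions
  if (!nrow(dd)) return(data.frame(maze_id = character(0),
                                   node_id = integer(0),
                                   option_id = integer(0),
                                   prob = numeric(0), n = integer(0)))
  n_part <- length(unique(decisions$participant_id))
  lay <- decision_layout(dd)
  df <- data.frame(maze_id = lay$maze_id,
                   node_id = dd$node_id[lay$decision],
                   option_id = lay$option_id,
                   chosen = as.integer(lay$chosen), n = 1L)
  agg <- aggregate(cbind(chosen, n) ~ maze_id + node_id + option_id, df, sum)
  agg$prob <- agg$chosen / agg$n
  if (!initial_only && n_part > 0)
    agg <- agg[agg$n >= min_visit * n_part, , drop = FALSE]
  agg[order(agg$maze_id, agg$node_id, agg$option_id),
      c("maze_id", "node_id", "option_id", "prob", "n")]
}

#' Model-predicted choice probabilities at decision nodes
#'
#' Softmax probabilities over each multi-child node's children under one
#' parameterization (typically the cohort's mean fitted parameters).
#'
#' @param trees named list of `mst_tree`.
#' @param params a [model_params()] bundle.
#' @param root_only restrict to the root decision (default).
#' @return data.frame (`maze_id`, `node_id`, `option_id`, `prob`).
#' @export
predict_choice_probs <- function(trees, params, root_only = TRUE) {
  out <- list()
  for (mid in names(trees)) {
    tree <- trees[[mid]]
    costs <- if (params$model_id == "Sampling") NULL
             else model_costs(tree, params)
    ids <- if (root_only) 1L else seq_along(tree$nodes)
    for (id in ids) {
      ch <- tree$nodes[[id]]$children
      if (length(ch) < 2L) next
      cv <- if (is.null(costs))
        mcts_node_values(tree, id, params$mcts_budget,
                         params$mcts_exploration, seed = 1L)
        else costs[ch]
      pr <- if (params$model_id == "Random") rep(1 / length(ch), length(ch))
            else choice_probabilities(cv, params$tau)
      out[[length(out) + 1L]] <- data.frame(
        maze_id = mid, node_id = id, option_id = ch, prob = pr)
    }
  }
  do.call(rbind, out)
}

#' Bootstrapped correlation between empirical and predicted choices
#'
#' Pearson correlation between per-option empirical frequencies
#' (aggregated initial decisions) and model-predicted probabilities, with
#' a participant-level bootstrap confidence interval. When `predicted2`
#' is given, the bootstrap distribution of the difference in correlations
#' is returned as well.
#'
#' @param decisions cohort decision log.
#' @param predicted data.frame from [predict_choice_probs()].
#' @param predicted2 optional second model's predictions.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list with `r`, `ci`, optionally `r2`, `diff_ci`, and `n`
#'   (number of aligned options).
#' @export
bootstrap_model_correlation <- function(decisions, predicted,
                                        predicted2 = NULL, n_boot = 1000L,
                                        seed = NULL, conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  emp <- aggregate_first_choices(decisions)
  align <- function(pred) {
    m <- merge(emp, pred, by = c("maze_id", "node_id", "option_id"),
               suffixes = c("_emp", "_mod"))
    if (nrow(m) < 3L) stop("need >= 3 aligned options", call. = FALSE)
    m
  }
  m1 <- align(predicted)
  if (stats::sd(m1$prob_emp) == 0 || stats::sd(m1$prob_mod) == 0)
    stop("undefined correlation: zero-variance vector", call. = FALSE)
  r1 <- cor(m1$prob_emp, m1$prob_mod)
  m2 <- if (!is.null(predicted2)) align(predicted2)

  pids <- unique(decisions$participant_id)
  boot_r <- matrix(NA_real_, n_boot, 2L)
  for (b in seq_len(n_boot)) {
    take <- sample(pids, length(pids), replace = TRUE)
    dd <- do.call(rbind, lapply(seq_along(take), function(i) {
      x <- decisions[decisions$participant_id == take[i], , drop = FALSE]
      x$participant_id <- i
      x
    }))
    eb <- aggregate_first_choices(dd)
    mb <- merge(eb, predicted, by = c("maze_id", "node_id", "option_id"))
    boot_r[b, 1L] <- if (stats::sd(mb$prob.x) > 0 && stats::sd(mb$prob.y) > 0)
      cor(mb$prob.x, mb$prob.y) else NA_real_
    if (!is.null(predicted2)) {
      mb2 <- merge(eb, predicted2, by = c("maze_id", "node_id", "option_id"))
      boot_r[b, 2L] <- if (stats::sd(mb2$prob.x) > 0 &&
                             stats::sd(mb2$prob.y) > 0)
        cor(mb2$prob.x, mb2$prob.y) else NA_real_
    }
  }
  al <- (1 - conf) / 2
  out <- list(r = r1,
              ci = quantile(boot_r[, 1L], c(al, 1 - al), na.rm = TRUE),
              n = nrow(m1))
  if (!is.null(predicted2)) {
    out$r2 <- cor(m2$prob_emp, m2$prob_mod)
    out$diff_ci <- quantile(boot_r[, 1L] - boot_r[, 2L], c(al, 1 - al),
                            na.rm = TRUE)
  }
  out
}
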