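#' Model identifiers
#'
#' Planners evaluate the decision tree recursively; heuristics score only
#' the immediate node. `-Num` variants pass counts through the bit-limited
#' numerosity channel first.
#' @export
planner_models <- c("EU", "DU", "PW", "PW-DU", "EU-Num", "DU-Num", "Sampling")

#' @rdname planner_models
#' @export
heuristic_models <- c("Steps", "Cells", "Steps-Cells", "Steps-Num",
                      "Cells-Num", "Steps-Cells-Num", "Random")

#' @rdname planner_models
#' @export
all_models <- c(planner_models, heuristic_models)

#' Bundle model parameters
#'
#' Only the parameters relevant to `model_id` are read by the cost
#' functions; `tau` is required by every model.
#'
#' @param model_id one of [all_models].
#' @param tau softmax temperature (> 0).
#' @param gamma discount rate in `[0, 1]` (DU family).
#' @param beta probability-weighting exponent (>= 0; PW family).
#' @param B numerosity bit threshold in `[0.1, 10]` (Num variants).
#' @param k_weight Steps-Cells mixing weight in `[0, 1]`.
#' @param mcts_budget,mcts_exploration Sampling model controls.
#' @return a `model_params` list.
#' @export
model_params <- function(model_id, tau = 1, gamma = 1, beta = 1, B = 10,
                         k_weight = 0.5, mcts_budget = 200L,
                         mcts_exploration = 1) {
  model_id <- match.arg(model_id, all_models)
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (k_weight < 0 || k_weight > 1)
    stop("k_weight must be in [0, 1]", call. = FALSE)
  if (mcts_budget < 1) stop("mcts_budget must be >= 1", call. = FALSE)
  if (mcts_exploration < 0)
    stop("mcts_exploration must be >= 0", call. = FALSE)
  structure(list(model_id = model_id, tau = tau, gamma = gamma, beta = beta,
                 B = B, k_weight = k_weight, mcts_budget = as.integer(mcts_budget),
                 mcts_exploration = mcts_exploration),
            class = "model_params")
}

#' Softmax choice probabilities over option costs
#'
#' `P(k) = exp(-C_k / tau) / sum_j exp(-C_j / tau)`, computed with a
#' max-shift for numerical stability. Lower cost means higher probability;
#' as `tau` approaches 0 the minimum-cost option is chosen almost surely.
#'
#' @param costs numeric vector of option costs (>= 1 option).
#' @param tau softmax temperature (> 0).
#' @return probability vector summing to 1.
#' @export
choice_probabilities <- function(costs, tau) {
  if (length(costs) < 1L) stop("no options", call. = FALSE)
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  z <- -costs / tau
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Probability weighting function
#'
#' `pi(p) = exp(-|ln p|^beta)`: overweights small and underweights large
#' probabilities for `beta < 1`; identity at `beta = 1`. Boundaries:
#' `pi(0) = 0` and `pi(1) = 1` for `beta > 0`; at `beta = 0`,
#' `pi(p) = exp(-1)` for `p` in `(0, 1)` with the endpoints kept at 0 and
#' 1.
#'
#' @param p probability (vectorized), in `[0, 1]`.
#' @param beta weighting exponent (>= 0).
#' @return weighted probabilities in `[0, 1]`.
#' @export
weight_probability <- function(p, beta) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  out <- numeric(length(p))
  mid <- p > 0 & p < 1
  out[mid] <- exp(-abs(log(p[mid]))^beta)
  out[p == 0] <- 0
  out[p == 1] <- 1
  out
}

#' Distort a decision tree through a numerosity channel
#'
#' Replaces every node's step count `s`, revealed-cell count `cells`, and
#' remaining-total count by their expected subjective estimates `q(.)`;
#' recomputes `p = q(cells) / q(remaining)` and distorts `e` by applying
#' `q` to each tile's step count before averaging. A zero count maps to
#' zero.
#'
#' @param tree an `mst_tree` built by [build_tree()].
#' @param channel a `numerosity_channel`.
#' @return a distorted `mst_tree` (statistics only; topology unchanged).
#' @export
apply_numerosity <- function(tree, channel) {
  nodes <- lapply(tree$nodes, function(n) {
    n$s <- distort_count(channel, n$s)
    n$cells <- distort_count(channel, n$cells)
    rem <- distort_count(channel, n$remaining)
    n$remaining <- rem
    n$p <- if (n$cells > 0 && rem > 0) min(1, n$cells / rem) else 0
    n$e <- if (length(n$tile_dists)) mean(distort_count(channel, n$tile_dists))
           else 0
    n
  })
  out <- tree
  out$nodes <- nodes
  out$distorted_B <- channel$B
  out
}

# ---- cost functions ---------------------------------------------------------

# generic recursive planner cost over the whole tree:
#   C(i) = s_i + wp_i * e_i + disc * wq_i * min_children C(j)
# evaluated in reverse id order (children always have larger ids).
planner_cost_vector <- function(tree, wp, wq, disc) {
  n <- length(tree$nodes)
  cost <- numeric(n)
  for (i in rev(seq_len(n))) {
    nd <- tree$nodes[[i]]
    cont <- if (length(nd$children)) min(cost[nd$children]) else 0
    cost[i] <- nd$s + wp[i] * nd$e + disc * wq[i] * cont
  }
  cost
}

node_field <- function(tree, f) vapply(tree$nodes, function(n) as.numeric(n[[f]]), 1)

#' Node costs of every model on a decision tree
#'
#' Returns the cost assigned by the model to choosing each node from its
#' parent; softmax over a node's children gives the choice probabilities.
#' Numerosity variants distort the tree through the channel for
#' `params$B` first. The Sampling model has no closed-form cost vector
#' (see [mcts_plan()] and [mcts_node_values()]).
#'
#' @param tree an `mst_tree`.
#' @param params a [model_params()] bundle.
#' @return numeric vector of per-node costs.
#' @export
model_costs <- function(tree, params) {
  id <- params$model_id
  if (id == "Sampling")
    stop("Sampling has no closed-form cost vector; use mcts_node_values()",
         call. = FALSE)
  if (grepl("-Num$", id) || id %in% c("EU-Num", "DU-Num"))
    tree <- apply_numerosity(tree, get_channel(params$B))
  p <- node_field(tree, "p")
  s <- node_field(tree, "s")
  cells <- node_field(tree, "cells")
  switch(id,
    "EU" = , "EU-Num" =
      planner_cost_vector(tree, p, 1 - p, 1),
    "DU" = , "DU-Num" =
      planner_cost_vector(tree, p, 1 - p, params$gamma),
    "PW" =
      planner_cost_vector(tree, weight_probability(p, params$beta),
                          weight_probability(1 - p, params$beta), 1),
    "PW-DU" =
      planner_cost_vector(tree, weight_probability(p, params$beta),
                          weight_probability(1 - p, params$beta),
                          params$gamma),
    "Steps" = , "Steps-Num" = s,
    "Cells" = , "Cells-Num" = -cells,
    "Steps-Cells" = , "Steps-Cells-Num" =
      params$k_weight * s - (1 - params$k_weight) * cells,
    "Random" = rep(1, length(s)),
    stop("unknown model: ", id, call. = FALSE))
}

#' Expected-utility cost of one node
#'
#' Convenience wrappers around [model_costs()] for a single node.
#' @param tree an `mst_tree`.
#' @param node_id node index.
#' @param gamma,beta model parameters.
#' @return scalar cost.
#' @export
cost_eu <- function(tree, node_id = 1L) {
  model_costs(tree, model_params("EU"))[node_id]
}

#' @rdname cost_eu
#' @export
cost_du <- function(tree, node_id = 1L, gamma) {
  model_costs(tree, model_params("DU", gamma = gamma))[node_id]
}

#' @rdname cost_eu
#' @export
cost_pw <- function(tree, node_id = 1L, beta) {
  model_costs(tree, model_params("PW", beta = beta))[node_id]
}

#' @rdname cost_eu
#' @export
cost_pw_du <- function(tree, node_id = 1L, gamma, beta) {
  model_costs(tree, model_params("PW-DU", gamma = gamma, beta = beta))[node_id]
}

#' One-step heuristic cost of nodes
#'
#' @param tree an `mst_tree`.
#' @param model_id a heuristic model id.
#' @param k_weight Steps-Cells mixing weight.
#' @param B numerosity bits for `-Num` variants.
#' @return numeric vector of per-node costs.
#' @export
heuristic_cost <- function(tree, model_id, k_weight = 0.5, B = 10) {
  if (!model_id %in% heuristic_models)
    stop("not a heuristic model: ", model_id, call. = FALSE)
  model_costs(tree, model_params(model_id, k_weight = k_weight, B = B))
}

# ---- Monte Carlo Tree Search -----------------------------------------------

#' Monte Carlo tree search over the observation tree
#'
#' Approximates expected-utility planning with a sampling procedure:
#' `budget` iterations of UCB1 selection (minimization form,
#' `Q_j - c * sqrt(2 ln N / n_j)`), single-node expansion of a uniformly
#' random unexpanded child, a uniform-random rollout to a leaf whose value
#' accumulates expected steps with exit-probability weighting
#' (`s + p e + (1 - p) v_next`), and mean-cost backup. Reproducible given
#' the RNG state (use `set.seed()` or the `seed` argument).
#'
#' @param tree an `mst_tree`.
#' @param budget iteration count (>= 1).
#' @param exploration UCB1 exploration constant (>= 0).
#' @param root_id node whose children are compared (default the tree
#'   root).
#' @param seed optional integer seed.
#' @return list with `visits`, `proportions` and mean cost `values` per
#'   child of `root_id`, plus `children` ids.
#' @export
mcts_plan <- function(tree, budget = 200L, exploration = 1, root_id = 1L,
                      seed = NULL) {
  if (budget < 1L) stop("budget must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$nodes)
  visits <- integer(n); value <- numeric(n)
  expanded <- logical(n)
  expanded[root_id] <- TRUE

  s <- node_field(tree, "s"); e <- node_field(tree, "e")
  p <- node_field(tree, "p")
  kids <- lapply(tree$nodes, `[[`, "children")

  rollout_value <- function(id) {
    # uniform-random continuation; value via exit-probability weighting
    chain <- id
    cur <- id
    while (length(kids[[cur]])) {
      cur <- kids[[cur]][sample.int(length(kids[[cur]]), 1L)]
      chain <- c(chain, cur)
    }
    v <- 0
    for (j in rev(chain)) v <- s[j] + p[j] * e[j] + (1 - p[j]) * v
    v
  }

  for (it in seq_len(budget)) {
    # selection
    path <- root_id
    cur <- root_id
    repeat {
      ch <- kids[[cur]]
      if (!length(ch)) break
      unexp <- ch[!expanded[ch]]
      if (length(unexp)) {
        nxt <- unexp[sample.int(length(unexp), 1L)]
        expanded[nxt] <- TRUE
        path <- c(path, nxt)
        cur <- nxt
        break
      }
      ucb <- value[ch] - exploration *
        sqrt(2 * log(max(1L, visits[cur])) / pmax(1L, visits[ch]))
      cur <- ch[which.min(ucb)]
      path <- c(path, cur)
    }
    v <- rollout_value(cur)
    # backup: each node's estimate tracks the value of choosing it from
    # its parent; the rollout value already folds in cur's own statistics,
    # ancestors fold theirs around the child's value on the way up
    for (j in rev(seq_along(path))) {
      id <- path[j]
      if (id != root_id && j < length(path))
        v <- s[id] + p[id] * e[id] + (1 - p[id]) * v
      visits[id] <- visits[id] + 1L
      if (id != root_id)
        value[id] <- value[id] + (v - value[id]) / visits[id]
    }
  }
  ch <- kids[[root_id]]
  list(children = ch, visits = visits[ch],
       proportions = visits[ch] / sum(visits[ch]),
       values = value[ch])
}

#' Sampling-model cost estimates for a node's children
#'
#' Runs [mcts_plan()] at `node_id` and returns the backed-up mean costs of
#' its children, which the Sampling model feeds through the softmax.
#' @inheritParams mcts_plan
#' @param node_id the decision node.
#' @return numeric vector of estimated child costs (unvisited children get
#'   the worst visited cost plus one).
#' @export
mcts_node_values <- function(tree, node_id, budget = 200L, exploration = 1,
                             seed = NULL) {
  res <- mcts_plan(tree, budget = budget, exploration = exploration,
                   root_id = node_id, seed = seed)
  v <- res$values
  if (any(res$visits == 0L))
    v[res$visits == 0L] <- max(v[res$visits > 0L]) + 1
  v
}

# ---- agent simulation -------------------------------------------------------

#' Simulate one agent searching one maze
#'
#' At each decision node the agent samples a child through the softmax over
#' the model's costs, walks the shortest path to the chosen vantage, and
#' stops as soon as the room containing the exit has been revealed (then
#' walks to the exit). One decision record is emitted per multi-child node
#' visited.
#'
#' @param maze a `grid_maze`.
#' @param params a [model_params()] bundle.
#' @param tree optional prebuilt `mst_tree` for `maze`.
#' @param costs optional precomputed per-node cost vector (skips
#'   [model_costs()]).
#' @param seed optional integer seed.
#' @return list with `records` (data.frame: `maze_id`, `node_id`,
#'   `option_ids`, `chosen_id`, `is_initial`, per-option `s/e/p/cells`
#'   packed as strings), `path` (node ids), and `steps` (total steps to
#'   the exit).
#' @export
simulate_agent <- function(maze, params, tree = NULL, costs = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- build_tree(maze)
  exit_room <- maze$room_id[maze$exit]
  d <- maze_distances(maze)

  use_mcts <- params$model_id == "Sampling"
  if (!use_mcts && is.null(costs)) costs <- model_costs(tree, params)

  rec <- list()
  cur <- 1L
  path <- 1L
  steps <- 0
  found <- exit_room %in% tree$nodes[[1L]]$observed
  while (!found) {
    ch <- tree$nodes[[cur]]$children
    if (!length(ch)) stop("exit room never revealed (corrupt tree)",
                          call. = FALSE)
    if (length(ch) == 1L) {
      nxt <- ch
    } else {
      cvec <- if (use_mcts)
        mcts_node_values(tree, cur, params$mcts_budget,
                         params$mcts_exploration)
      else costs[ch]
      pr <- if (params$model_id == "Random") rep(1 / length(ch), length(ch))
            else choice_probabilities(cvec, params$tau)
      pick <- sample.int(length(ch), 1L, prob = pr)
      nxt <- ch[pick]
      rec[[length(rec) + 1L]] <- data.frame(
        maze_id = maze$maze_id, node_id = cur,
        option_ids = paste(ch, collapse = ","),
        chosen_id = nxt,
        n_options = length(ch),
        is_initial = cur == 1L)
    }
    steps <- steps + tree$nodes[[nxt]]$s
    cur <- nxt
    path <- c(path, cur)
    found <- exit_room %in% tree$nodes[[cur]]$new_rooms
  }
  last_v <- tree$nodes[[cur]]$vantage
  steps <- steps + d[last_v, maze$exit]
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(maze_id = character(0), node_id = integer(0),
               option_ids = character(0), chosen_id = integer(0),
               n_options = integer(0), is_initial = logical(0))
  list(records = records, path = path, steps = as.numeric(steps))
}
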