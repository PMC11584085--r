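#' Generate a validated random maze
#'
#' Mazes follow a "comb" construction compatible with the strict
#' corner-rule isovist: a corridor backbone with vertical stems hanging
#' below it; each stem ends in a dead-end vantage tile from which a
#' width-one pocket room extends perpendicularly. Rooms are therefore
#' never visible before their vantage tile, every room is fully visible
#' from it, and no room is visible from the start. For more than six
#' rooms the backbone is split into segments joined by jogs that pass
#' through single-tile "gate" rooms, which keeps the observation-order
#' tree enumerable.
#'
#' @param n_rooms number of rooms (pockets plus any gates), >= 2.
#' @param room_size range (min, max) of pocket-room tile counts.
#' @param stem_len range of stem lengths (>= 2, keeps rooms out of sight
#'   of the backbone).
#' @param size maximum `c(width, height)`; exceeding it is a
#'   generation-failure error.
#' @param seed RNG seed (same seed, same maze).
#' @param maze_id identifier.
#' @param max_tries rejection-sampling cap.
#' @return a `grid_maze` passing [validate_maze()] with no warnings.
#' @export
generate_maze <- function(n_rooms = 4L, room_size = c(2L, 3L),
                          stem_len = c(2L, 3L), size = c(80L, 12L),
                          seed = NULL, maze_id = NULL,
                          max_tries = 50L) {
  if (n_rooms < 2L) stop("need at least 2 rooms", call. = FALSE)
  if (min(stem_len) < 2L) stop("stem_len must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maze_id))
    maze_id <- sprintf("gen%06d", sample.int(999999L, 1L))

  for (try in seq_len(max_tries)) {
    mz <- try(comb_maze(n_rooms, room_size, stem_len, size, maze_id),
              silent = TRUE)
    if (inherits(mz, "try-error")) next
    v <- validate_maze(mz)
    if (v$ok && !length(v$warnings)) return(mz)
  }
  stop("maze generation failed after ", max_tries, " tries", call. = FALSE)
}

# segment plan: pockets per segment (gates join consecutive segments)
segment_plan <- function(n_rooms) {
  if (n_rooms <= 6L) return(n_rooms)
  # keep at most 3 free pockets per segment; each extra segment costs one
  # gate room
  for (n_seg in 2L:n_rooms) {
    pockets <- n_rooms - (n_seg - 1L)
    if (pockets <= 3L * n_seg && pockets >= n_seg) {
      base <- pockets %/% n_seg
      plan <- rep(base, n_seg)
      extra <- pockets - base * n_seg
      if (extra > 0L) plan[seq_len(extra)] <- plan[seq_len(extra)] + 1L
      cap <- if (n_rooms > 8L) 1L else 3L
      # "cap 1" still allows one 2-pocket segment when counts force it
      if (max(plan) <= cap || (n_rooms > 8L && sum(plan > 1L) <= 1L &&
                                 max(plan) <= 2L))
        return(plan)
    }
  }
  stop("no segment plan for ", n_rooms, " rooms", call. = FALSE)
}

comb_maze <- function(n_rooms, room_size, stem_len, size, maze_id) {
  plan <- segment_plan(n_rooms)
  n_seg <- length(plan)
  spacing <- 5L

  # geometry bookkeeping in (x, y); built into vectors at the end
  corr <- list(); rooms <- list(); room_no <- 0L
  seg_row <- 1L
  x <- 1L
  start_candidates <- list()
  for (sgi in seq_len(n_seg)) {
    n_p <- plan[sgi]
    stem_x <- x + 1L + spacing * (seq_len(n_p) - 1L)
    seg_end <- max(stem_x) + 2L
    for (bx in x:seg_end) corr[[length(corr) + 1L]] <- c(bx, seg_row)
    start_candidates[[sgi]] <- cbind(setdiff(x:seg_end, stem_x), seg_row)
    for (sx in stem_x) {
      L <- sample(seq(stem_len[1], stem_len[2]), 1L)
      dep <- sample(seq(room_size[1], room_size[2]), 1L)
      for (yy in seq_len(L)) corr[[length(corr) + 1L]] <- c(sx, seg_row + yy)
      room_no <- room_no + 1L
      rooms[[room_no]] <- cbind(sx + seq_len(dep), seg_row + L)
    }
    if (sgi < n_seg) {
      # jog through a single-tile gate room to the other backbone row
      gx <- seg_end + 2L
      next_row <- if (seg_row == 1L) 3L else 1L
      room_no <- room_no + 1L
      rooms[[room_no]] <- cbind(gx, 2L)
      corr[[length(corr) + 1L]] <- c(gx, seg_row)
      corr[[length(corr) + 1L]] <- c(gx, next_row)
      # short lead-in on the current row so the gate is adjacent
      for (bx in (seg_end + 1L):gx) corr[[length(corr) + 1L]] <- c(bx, seg_row)
      seg_row <- next_row
      x <- gx
    }
  }

  cxy <- do.call(rbind, corr)
  rxy <- do.call(rbind, rooms)
  width <- max(cxy[, 1], rxy[, 1]) + 2L
  height <- max(cxy[, 2], rxy[, 2]) + 2L
  if (width > size[1] || height > size[2])
    stop("generated maze exceeds size limit", call. = FALSE)

  kind <- rep("wall", width * height)
  room_id <- rep(NA_integer_, width * height)
  at <- function(m) 1L + m[, 1] + m[, 2] * width
  kind[at(cxy)] <- "corridor"
  for (r in seq_along(rooms)) {
    idx <- at(rooms[[r]])
    kind[idx] <- "room"
    room_id[idx] <- r
  }
  sc <- do.call(rbind, start_candidates)
  sc <- sc[kind[at(sc)] == "corridor", , drop = FALSE]
  start <- at(sc[sample.int(nrow(sc), 1L), , drop = FALSE])
  rt <- which(kind == "room")
  exit <- rt[sample.int(length(rt), 1L)]
  grid_maze(width, height, kind, room_id, start, exit, maze_id)
}

#' Hand-coded fixture mazes with model-discriminating designs
#'
#' Returns named mazes whose decision-tree statistics realize classic
#' contrasts between planning models and heuristics, verified at load
#' time (a failed property check is an error):
#' \describe{
#'   \item{heuristic_tie}{the two root options tie on steps and revealed
#'     cells (`s = 2`, `cells = 6`), so every one-step heuristic is
#'     indifferent, but a third room behind one side makes planners
#'     prefer it.}
#'   \item{eu_tie}{a small near room (3 tiles, 2 steps) versus a big far
#'     room (6 tiles, 4 steps) balanced so expected-utility planning is
#'     exactly indifferent while discounting, probability weighting with
#'     `beta < 1`, and the Steps heuristic all prefer the near room.}
#'   \item{long_compact}{two observations of 6 hidden tiles each, both 5
#'     steps away and equally likely to hold the exit: a long 1x6 room
#'     (mean exit distance 3.5, worst case 6) versus a compact pair of
#'     co-revealed 3-tile pockets flanking the vantage (mean 2, worst
#'     case 3). Expected utility, probability weighting, and every
#'     heuristic are exactly indifferent; only a limited planning
#'     horizon (discounting) breaks the tie, toward the compact side.}
#'   \item{four_rooms}{a four-room maze whose root offers all four
#'     observations at once.}
#'   \item{looped}{a two-room maze where one room can be observed from
#'     two different locations, giving more than two root options.}
#' }
#'
#' @return named list of `grid_maze` objects.
#' @export
fixture_mazes <- function() {
  fx <- list(
    heuristic_tie = maze_from_ascii(c(
      "############",
      "############",
      "############",
      "##..S....###",
      "##a###b#c###",
      "##a###b#c###",
      "##a###b#c###",
      "##a###b#####",
      "##a###b#####",
      "##A###b#####",
      "############"), maze_id = "heuristic_tie"),
    eu_tie = maze_from_ascii(c(
      "############",
      "###..S....##",
      "###a#####b##",
      "###a#####b##",
      "###A#####b##",
      "#########b##",
      "#########b##",
      "#########b##",
      "############"), maze_id = "eu_tie"),
    long_compact = maze_from_ascii(c(
      "###################",
      "####...S....#######",
      "####.######.aaaaaA#",
      "#bbb.ccc###########",
      "###################"), maze_id = "long_compact"),
    four_rooms = maze_from_ascii(c(
      "#########",
      "###aa.###",
      "#####.###",
      "###..S..#",
      "###b#.#d#",
      "####c.#D#",
      "#########"), maze_id = "four_rooms"),
    looped = maze_from_ascii(c(
      "######",
      "#S...#",
      "#.##a#",
      "#.##a#",
      "#....#",
      "#.####",
      "#.bB##",
      "######"), maze_id = "looped")
  )
  check_fixture_properties(fx)
  fx
}

check_fixture_properties <- function(fx) {
  fail <- function(...) stop("fixture property check failed: ",
                             sprintf(...), call. = FALSE)
  for (nm in names(fx)) {
    v <- validate_maze(fx[[nm]])
    if (!v$ok) fail("%s does not validate: %s", nm, v$failures[1])
    if (length(v$warnings)) fail("%s has visibility hazards: %s", nm,
                                 v$warnings[1])
  }
  stats_of <- function(tree) {
    ch <- tree$nodes[[1]]$children
    do.call(rbind, lapply(ch, function(i)
      data.frame(id = i, t(node_statistics(tree, i)))))
  }

  tA <- build_tree(fx$heuristic_tie)
  sA <- stats_of(tA)
  if (nrow(sA) != 2L || !all(sA$s == 2) || !all(sA$cells == 6))
    fail("heuristic_tie root options must both have (s, cells) = (2, 6)")
  eu <- model_costs(tA, model_params("EU"))
  if (abs(diff(eu[sA$id])) < 1e-9)
    fail("heuristic_tie: planners must not be indifferent")

  tB <- build_tree(fx$eu_tie)
  sB <- stats_of(tB)
  euB <- model_costs(tB, model_params("EU"))
  if (abs(diff(euB[sB$id])) > 1e-9)
    fail("eu_tie: EU root costs must tie (got %g)", diff(euB[sB$id]))
  duB <- model_costs(tB, model_params("DU", gamma = 0.8))
  near <- sB$id[which.min(sB$s)]
  if (duB[near] >= min(duB[setdiff(sB$id, near)]))
    fail("eu_tie: DU must prefer the near room")

  tC <- build_tree(fx$long_compact)
  sC <- stats_of(tC)
  if (!(all(sC$s == 5) && all(sC$cells == 6) &&
          abs(diff(sC$p)) < 1e-12 && abs(diff(sC$e)) > 1e-9))
    fail("long_compact root options must tie on s, cells, p and differ in e")
  wd <- vapply(sC$id, function(i)
    max(tC$nodes[[i]]$tile_dists), 1)
  if (!(min(wd) < max(wd) && max(wd) == 6))
    fail("long_compact worst-case exit distances must differ (long = 6)")

  tD <- build_tree(fx$four_rooms)
  if (length(tD$nodes[[1]]$children) != 4L)
    fail("four_rooms must offer 4 observations at the root")

  tE <- build_tree(fx$looped)
  if (length(tE$nodes[[1]]$children) <= 2L)
    fail("looped must have more than 2 root options")
  invisible(TRUE)
}

#' Cohort configuration for synthetic behavioral data
#'
#' The generator emulates the structure of a behavioral dataset from the
#' maze search paradigm: per participant, a generating model and its
#' parameters are drawn, every maze is searched by a softmax agent over
#' that model's costs, and decision times are linear in the generating
#' parameters with additive Gaussian noise (initial times fall with the
#' temperature `tau` and rise with the planning horizon `gamma`;
#' subsequent times show the opposite signs, mirroring the reported
#' regression structure), floored at 100 ms.
#'
#' @param n_participants cohort size.
#' @param mazes named list of `grid_maze` objects.
#' @param model_mix named numeric vector of mixture proportions over
#'   generating models (must sum to 1).
#' @param param_ranges named list of `c(min, max)` ranges from which each
#'   parameter is drawn uniformly per participant.
#' @param time_initial,time_subsequent coefficients
#'   `c(intercept, tau, gamma)` of the decision-time model, in ms.
#' @param time_sd decision-time noise SD in ms.
#' @param seed master seed; all randomness derives from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_participants, mazes,
                          model_mix = c(DU = 1),
                          param_ranges = list(tau = c(0.2, 1.5),
                                              gamma = c(0.2, 0.9),
                                              beta = c(0.35, 1.5),
                                              B = c(0.5, 10),
                                              k_weight = c(0, 1)),
                          time_initial = c(2880, -163, 530),
                          time_subsequent = c(1069, 55, -134),
                          time_sd = 400, seed = 1L) {
  if (abs(sum(model_mix) - 1) > 1e-9)
    stop("model_mix proportions must sum to 1", call. = FALSE)
  if (time_sd < 0) stop("time_sd must be >= 0", call. = FALSE)
  if (is.null(names(mazes)))
    names(mazes) <- vapply(mazes, `[[`, "", "maze_id")
  structure(list(n_participants = as.integer(n_participants), mazes = mazes,
                 model_mix = model_mix, param_ranges = param_ranges,
                 time_initial = time_initial,
                 time_subsequent = time_subsequent,
                 time_sd = time_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort of decision logs
#'
#' @param config a [cohort_config()].
#' @param trees optional prebuilt trees (named by maze id); built once
#'   otherwise.
#' @return list with `decisions` (decision log data.frame including
#'   `decision_time_ms`), `participants` (generating model and parameters
#'   per participant), and `trees`.
#' @export
generate_cohort <- function(config, trees = NULL) {
  mazes <- config$mazes
  if (is.null(trees))
    trees <- lapply(mazes, build_tree)
  if (config$n_participants == 0L)
    return(list(decisions = empty_decision_log(),
                participants = data.frame(), trees = trees))

  # shared cost cache across participants: costs depend on the generating
  # parameters, which repeat across the cohort
  cache <- new.env(parent = emptyenv())
  all_rec <- list(); parts <- list()
  for (i in seq_len(config$n_participants)) {
    set.seed(derive_seed(config$seed, paste0("participant", i)))
    model <- sample(names(config$model_mix), 1L, prob = config$model_mix)
    pr <- config$param_ranges
    draw <- function(nm) runif(1, pr[[nm]][1], pr[[nm]][2])
    pars <- model_params(model, tau = draw("tau"), gamma = draw("gamma"),
                         beta = draw("beta"), B = draw("B"),
                         k_weight = draw("k_weight"))
    pid <- sprintf("p%03d", i)
    for (mid in names(mazes)) {
      costs <- if (model == "Sampling") NULL else
        cached_costs(trees[[mid]], model,
                     params_to_cost_row(pars), cache)
      sim <- simulate_agent(mazes[[mid]], pars, tree = trees[[mid]],
                            costs = costs)
      rec <- sim$records
      if (nrow(rec)) {
        mu <- ifelse(rec$is_initial,
                     config$time_initial[1] + config$time_initial[2] * pars$tau +
                       config$time_initial[3] * pars$gamma,
                     config$time_subsequent[1] + config$time_subsequent[2] * pars$tau +
                       config$time_subsequent[3] * pars$gamma)
        rec$decision_time_ms <- pmax(100, rnorm(nrow(rec), mu, config$time_sd))
        rec$participant_id <- pid
        all_rec[[length(all_rec) + 1L]] <- rec
      }
    }
    parts[[i]] <- data.frame(participant_id = pid, model_id = model,
                             tau = pars$tau, gamma = pars$gamma,
                             beta = pars$beta, B = pars$B,
                             k_weight = pars$k_weight)
  }
  decisions <- if (length(all_rec)) do.call(rbind, all_rec) else
    empty_decision_log()
  rownames(decisions) <- NULL
  list(decisions = decisions, participants = do.call(rbind, parts),
       trees = trees)
}

params_to_cost_row <- function(pars) {
  ps <- model_cost_params(pars$model_id)
  if (!length(ps)) return(data.frame(.d = 0)[, 0, drop = FALSE])
  as.data.frame(pars[ps])
}

empty_decision_log <- function() {
  data.frame(maze_id = character(0), node_id = integer(0),
             option_ids = character(0), chosen_id = integer(0),
             n_options = integer(0), is_initial = logical(0),
             decision_time_ms = numeric(0), participant_id = character(0))
}

#' Write/read a decision log as tab-separated text
#' @param decisions decision log data.frame.
#' @param path file path.
#' @export
write_decision_log <- function(decisions, path) {
  utils::write.table(decisions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_decision_log
#' @export
read_decision_log <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(maze_id = "character",
                                   participant_id = "character"))
}

#' Derive a labeled child seed from a master seed
#'
#' Lets one master seed fan out to reproducible, independent component
#' seeds (maze generation, cohort, folds, bootstrap, MCTS).
#' @param master integer master seed.
#' @param label character label.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * (31^(seq_along(utf8ToInt(label)) %% 7)))
  as.integer((as.numeric(master) * 2654435L + h) %% 2147483647L)
}
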