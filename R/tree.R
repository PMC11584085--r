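#' Observation-order decision trees
#'
#' Planning in the Maze Search Task is planning the order in which the
#' maze's rooms are observed. Each tree node is one observation event: a
#' vantage tile from which one or more new rooms become (fully) visible,
#' together with the history of rooms observed so far. Per-node statistics:
#' `s` steps from the parent vantage, `e` mean steps from the vantage to a
#' newly revealed tile (the expected exit distance if the exit is found
#' here), `p` probability that the exit is among the newly revealed tiles
#' (newly revealed tiles over all tiles still unobserved), and `cells`,
#' the number of newly revealed tiles.
#'
#' Vantage enumeration: candidate observation points for a room are tiles
#' from which the room is fully visible, restricted to first-visibility
#' tiles (tiles reachable along a shortest path that does not first bring
#' any unrevealed room into sight), deduplicated by (steps, set of rooms
#' co-revealed), ties broken by row-major tile order. A room observable
#' from two such locations yields two sibling nodes.
#'
#' @name decision_tree
NULL

# absorbing BFS: step distances from `from`, where tiles in `absorbing`
# receive a distance but are not expanded through
absorbing_bfs <- function(maze, from, absorbing) {
  n <- maze$width * maze$height
  d <- rep(Inf, n)
  d[from] <- 0
  stop_here <- logical(n); stop_here[absorbing] <- TRUE
  stop_here[from] <- FALSE
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (t in frontier) {
      for (nb in tile_neighbours(maze, t)) {
        if (maze$kind[nb] != "wall" && !is.finite(d[nb])) {
          d[nb] <- d[t] + 1
          if (!stop_here[nb]) nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# all candidate child observations from a vantage given revealed rooms:
# data.frame(vantage, steps, key) plus list column of co-revealed rooms
candidate_observations <- function(maze, from, revealed) {
  rv <- room_visibility(maze)
  nr <- length(maze$rooms)
  unrev <- setdiff(seq_len(nr), revealed)
  if (!length(unrev)) return(NULL)
  sees_any_unrev <- rv$sees_any[, unrev, drop = FALSE]
  u_tiles <- rv$open[rowSums(sees_any_unrev) > 0L]
  d_abs <- absorbing_bfs(maze, from, u_tiles)
  d_full <- maze_distances(maze)[from, ]

  cand_v <- integer(0); cand_s <- integer(0); cand_rooms <- list()
  for (r in unrev) {
    vset <- rv$open[rv$sees_all[, r]]
    vset <- vset[is.finite(d_abs[vset]) & d_abs[vset] == d_full[vset]]
    for (v in vset) {
      co <- unrev[rv$sees_any[match(v, rv$open), unrev]]
      cand_v <- c(cand_v, v); cand_s <- c(cand_s, as.integer(d_full[v]))
      cand_rooms <- c(cand_rooms, list(sort(co)))
    }
  }
  if (!length(cand_v)) return(NULL)
  key <- paste(cand_s, vapply(cand_rooms, paste, "", collapse = ","))
  ord <- order(key, cand_v)  # representative vantage: lowest row-major tile
  keep <- ord[!duplicated(key[ord])]
  keep <- keep[order(cand_s[keep], cand_v[keep])]
  list(vantage = cand_v[keep], steps = cand_s[keep],
       rooms = cand_rooms[keep])
}

#' Enumerate candidate vantage points for observing a room
#'
#' @param maze a `grid_maze`.
#' @param from tile index or `c(x, y)` of the current vantage.
#' @param revealed integer vector of already-revealed room ids.
#' @param room target room id (must be unrevealed).
#' @return data.frame with columns `vantage` (tile index), `steps`, and a
#'   list column `co_revealed`.
#' @export
enumerate_vantages <- function(maze, from, revealed, room) {
  from <- as_tile(maze, from)
  if (room %in% revealed) stop("room is already revealed", call. = FALSE)
  cand <- candidate_observations(maze, from, revealed)
  hit <- which(vapply(cand$rooms, function(rr) room %in% rr, TRUE) &
                 vapply(seq_along(cand$vantage), function(i) {
                   rv <- room_visibility(maze)
                   rv$sees_all[match(cand$vantage[i], rv$open), room]
                 }, TRUE))
  if (!length(hit))
    stop(sprintf("unobservable room %s: no reachable full-visibility vantage",
                 room), call. = FALSE)
  data.frame(vantage = cand$vantage[hit], steps = cand$steps[hit],
             co_revealed = I(cand$rooms[hit]))
}

#' Build the full observation-order decision tree of a maze
#'
#' Depth-first expansion until every root-to-leaf path covers all rooms.
#' The root is a degenerate node at the start tile whose observed set is
#' the rooms visible from the start (with `s = e = 0` and `p` the share of
#' room tiles initially visible).
#'
#' @param maze a validated `grid_maze`.
#' @param node_cap maximum number of nodes before an explicit error
#'   (guards against combinatorial blowup).
#' @return an object of class `mst_tree`: a flat list of nodes with
#'   parent/children indices.
#' @export
build_tree <- function(maze, node_cap = 50000L) {
  total <- length(room_tiles(maze))
  nr <- length(maze$rooms)
  room_sizes <- vapply(maze$rooms, length, 1L)
  d <- maze_distances(maze)

  init_rooms <- as.integer(start_visible_rooms(maze))
  init_cells <- sum(room_sizes[init_rooms])

  nodes <- list()
  n_nodes <- 0L
  add_node <- function(node) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > node_cap)
      stop(sprintf("decision tree exceeds node cap (%d)", node_cap),
           call. = FALSE)
    node$id <- n_nodes
    nodes[[n_nodes]] <<- node
    n_nodes
  }

  root <- list(parent = 0L, depth = 0L, vantage = maze$start,
               s = 0L, e = 0, p = if (total > 0) init_cells / total else 0,
               cells = init_cells, remaining = total,
               new_rooms = init_rooms, observed = init_rooms,
               tile_dists = numeric(0), children = integer(0))
  root_id <- add_node(root)

  # candidate sets depend only on (vantage, observed); heavily shared
  # between subtrees, so memoize
  cand_memo <- new.env(parent = emptyenv())
  memo_candidates <- function(vantage, observed) {
    key <- paste(vantage, paste(observed, collapse = ","), sep = "|")
    if (is.null(cand_memo[[key]]))
      cand_memo[[key]] <- list(candidate_observations(maze, vantage, observed))
    cand_memo[[key]][[1L]]
  }

  expand <- function(id) {
    node <- nodes[[id]]
    if (length(node$observed) == nr) return(invisible(NULL))
    cand <- memo_candidates(node$vantage, node$observed)
    if (is.null(cand))
      stop("unobservable room: remaining rooms cannot be brought into sight",
           call. = FALSE)
    remaining <- node$remaining - node$cells
    kids <- integer(0)
    for (i in seq_along(cand$vantage)) {
      new_rooms <- cand$rooms[[i]]
      tiles <- unlist(maze$rooms[new_rooms], use.names = FALSE)
      cells <- length(tiles)
      child <- list(parent = id, depth = node$depth + 1L,
                    vantage = cand$vantage[i],
                    s = cand$steps[i],
                    e = mean(d[cand$vantage[i], tiles]),
                    p = cells / remaining,
                    cells = cells, remaining = remaining,
                    new_rooms = as.integer(new_rooms),
                    observed = sort(c(node$observed, as.integer(new_rooms))),
                    tile_dists = as.numeric(d[cand$vantage[i], tiles]),
                    children = integer(0))
      kids <- c(kids, add_node(child))
    }
    nodes[[id]]$children <<- kids
    for (k in kids) expand(k)
    invisible(NULL)
  }
  expand(root_id)

  tree <- structure(list(maze_id = maze$maze_id, n_rooms = nr,
                         total_tiles = total,
                         nodes = nodes[seq_len(n_nodes)]),
                    class = "mst_tree")
  tree
}

#' @export
print.mst_tree <- function(x, ...) {
  cat(sprintf("<mst_tree '%s': %d nodes, %d rooms, %d leaves>\n",
              x$maze_id, length(x$nodes), x$n_rooms,
              sum(vapply(x$nodes, function(n) length(n$children) == 0L, TRUE))))
  invisible(x)
}

#' Per-node statistics of a decision-tree node
#'
#' Convenience accessor returning the `(s, e, p, cells)` tuple of one node.
#' @param tree an `mst_tree`.
#' @param node_id node index.
#' @return named numeric vector.
#' @export
node_statistics <- function(tree, node_id) {
  n <- tree$nodes[[node_id]]
  c(s = n$s, e = n$e, p = n$p, cells = n$cells)
}

#' Flatten a decision tree to a table
#'
#' @param tree an `mst_tree`.
#' @return data.frame with one row per node (`node_id`, `parent`, `depth`,
#'   `vantage_x`, `vantage_y`, `s`, `e`, `p`, `cells`, `new_rooms`).
#' @export
tree_table <- function(tree) {
  data.frame(
    node_id = vapply(tree$nodes, `[[`, 1L, "id"),
    parent = vapply(tree$nodes, `[[`, 1L, "parent"),
    depth = vapply(tree$nodes, `[[`, 1L, "depth"),
    vantage = vapply(tree$nodes, `[[`, 1L, "vantage"),
    s = vapply(tree$nodes, function(n) as.numeric(n$s), 1),
    e = vapply(tree$nodes, function(n) as.numeric(n$e), 1),
    p = vapply(tree$nodes, function(n) as.numeric(n$p), 1),
    cells = vapply(tree$nodes, function(n) as.numeric(n$cells), 1),
    new_rooms = vapply(tree$nodes, function(n)
      paste(n$new_rooms, collapse = ","), "")
  )
}

#' Export a decision tree as delimited text
#' @param tree an `mst_tree`.
#' @param path output path (tab-separated, with header).
#' @export
write_tree <- function(tree, path) {
  utils::write.table(tree_table(tree), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# unconditional find probability of each node: p_i * prod(1 - p_j) over
# strict ancestors
unconditional_find_prob <- function(tree) {
  out <- numeric(length(tree$nodes))
  walk <- function(id, carry) {
    n <- tree$nodes[[id]]
    out[id] <<- n$p * carry
    for (k in n$children) walk(k, carry * (1 - n$p))
  }
  walk(1L, 1)
  out
}

# ids of leaves
tree_leaves <- function(tree) {
  which(vapply(tree$nodes, function(n) length(n$children) == 0L, TRUE))
}

# root-to-node path of ids
tree_path <- function(tree, id) {
  path <- id
  while (tree$nodes[[id]]$parent != 0L) {
    id <- tree$nodes[[id]]$parent
    path <- c(id, path)
  }
  path
}
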