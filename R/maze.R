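#' Grid mazes for the Maze Search Task
#'
#' A `grid_maze` describes the static geometry of one maze: walls,
#' corridors, and *rooms* (clusters of initially hidden tiles that are
#' revealed all at once when any of their tiles enters the agent's line of
#' sight), plus a start tile and an exit tile hidden inside one room.
#'
#' Coordinates are 0-based `(col, row)` with the origin at the top-left;
#' movement is 4-connected; tiles are unit squares and walls are whole
#' tiles. Internally tiles are indexed `1 + x + y * width`.
#'
#' @param width,height tile counts.
#' @param kind character vector of length `width * height` in
#'   `c("wall", "corridor", "room")`, row-major (row 0 first).
#' @param room_id integer vector, same length: room membership (`NA` for
#'   non-room tiles).
#' @param start,exit tile indices (1-based) of the start (a corridor tile)
#'   and the exit (a room tile).
#' @param maze_id optional identifier string.
#' @return an object of class `grid_maze`.
#' @export
grid_maze <- function(width, height, kind, room_id, start, exit,
                      maze_id = "maze") {
  stopifnot(length(kind) == width * height,
            length(room_id) == width * height)
  rid <- sort(unique(room_id[!is.na(room_id)]))
  rooms <- lapply(rid, function(r) which(!is.na(room_id) & room_id == r))
  names(rooms) <- as.character(rid)
  mz <- structure(list(
    width = as.integer(width), height = as.integer(height),
    kind = kind, room_id = as.integer(room_id),
    rooms = rooms, start = as.integer(start), exit = as.integer(exit),
    maze_id = as.character(maze_id),
    cache = new.env(parent = emptyenv())
  ), class = "grid_maze")
  mz
}

#' @export
print.grid_maze <- function(x, ...) {
  cat(sprintf("<grid_maze '%s' %dx%d, %d rooms, %d room tiles>\n",
              x$maze_id, x$width, x$height, length(x$rooms),
              sum(x$kind == "room")))
  cat(maze_ascii(x), sep = "\n")
  invisible(x)
}

# ---- coordinate helpers ----------------------------------------------------

tile_index <- function(maze, x, y) 1L + as.integer(x) + as.integer(y) * maze$width
tile_x <- function(maze, idx) (idx - 1L) %% maze$width
tile_y <- function(maze, idx) (idx - 1L) %/% maze$width

in_bounds <- function(maze, idx) idx >= 1L & idx <= maze$width * maze$height

wall_tiles <- function(maze) which(maze$kind == "wall")
open_tiles <- function(maze) which(maze$kind != "wall")
room_tiles <- function(maze) which(maze$kind == "room")

assert_open_tile <- function(maze, idx, what = "tile") {
  if (length(idx) != 1L || is.na(idx) || !in_bounds(maze, idx))
    stop(sprintf("invalid %s: out of bounds", what), call. = FALSE)
  if (maze$kind[idx] == "wall")
    stop(sprintf("invalid %s: on a wall", what), call. = FALSE)
  invisible(idx)
}

# 4-neighbours of a tile index (within bounds, any kind)
tile_neighbours <- function(maze, idx) {
  x <- tile_x(maze, idx); y <- tile_y(maze, idx)
  nb <- integer(0)
  if (x > 0L) nb <- c(nb, idx - 1L)
  if (x < maze$width - 1L) nb <- c(nb, idx + 1L)
  if (y > 0L) nb <- c(nb, idx - maze$width)
  if (y < maze$height - 1L) nb <- c(nb, idx + maze$width)
  nb
}

# ---- movement graph and distances ------------------------------------------

#' All-pairs step distances over non-wall tiles
#'
#' Distances are cached on the maze; the movement graph treats every
#' non-wall tile (corridor or room) as walkable.
#' @param maze a `grid_maze`.
#' @return numeric matrix indexed by tile index (walls are `Inf` rows).
#' @keywords internal
maze_distances <- function(maze) {
  if (!is.null(maze$cache$dist)) return(maze$cache$dist)
  n <- maze$width * maze$height
  open <- open_tiles(maze)
  ed <- integer(0)
  for (i in open) {
    x <- tile_x(maze, i); y <- tile_y(maze, i)
    if (x < maze$width - 1L && maze$kind[i + 1L] != "wall") ed <- c(ed, i, i + 1L)
    if (y < maze$height - 1L && maze$kind[i + maze$width] != "wall")
      ed <- c(ed, i, i + maze$width)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ed)) g <- igraph::add_edges(g, ed)
  d <- igraph::distances(g)
  maze$cache$dist <- d
  d
}

#' Shortest-path step count between two tiles
#'
#' Length of the shortest 4-connected path over non-wall tiles.
#'
#' @param maze a `grid_maze`.
#' @param a,b tile indices (1-based) or `c(x, y)` coordinate pairs.
#' @return nonnegative integer step count.
#' @export
shortest_path_steps <- function(maze, a, b) {
  a <- as_tile(maze, a); b <- as_tile(maze, b)
  assert_open_tile(maze, a, "tile a"); assert_open_tile(maze, b, "tile b")
  d <- maze_distances(maze)[a, b]
  if (!is.finite(d)) stop("no path between tiles (maze invariant violation)",
                          call. = FALSE)
  as.integer(d)
}

# accept either a tile index or an (x, y) pair
as_tile <- function(maze, t) {
  if (length(t) == 2L) tile_index(maze, t[1L], t[2L]) else as.integer(t)
}

# ---- isovist ---------------------------------------------------------------

#' Compute the isovist (set of fully visible tiles) of an observer tile
#'
#' A target tile is visible when its entire area can be seen from somewhere
#' within the observer's tile, discretized to a corner rule: each of the
#' target's 4 corners must be connected by a wall-free segment to at least
#' one of the observer's 4 corners. Segments grazing exactly along a wall
#' edge count as blocked, so a tile diagonally across a wall corner is not
#' visible.
#'
#' @param maze a `grid_maze`.
#' @param observer tile index or `c(x, y)`; must be non-wall.
#' @return integer vector of visible non-wall tile indices (includes the
#'   observer's own tile).
#' @export
compute_isovist <- function(maze, observer) {
  observer <- as_tile(maze, observer)
  assert_open_tile(maze, observer, "observer location")
  vm <- vis_open_matrix(maze)
  open <- open_tiles(maze)
  open[vm[match(observer, open), ]]
}

# visibility matrix among all open tiles (cached)
vis_open_matrix <- function(maze) {
  if (!is.null(maze$cache$vis)) return(maze$cache$vis)
  open <- open_tiles(maze)
  w <- wall_tiles(maze)
  vm <- .vis_matrix_cpp(tile_x(maze, open), tile_y(maze, open),
                        tile_x(maze, open), tile_y(maze, open),
                        tile_x(maze, w), tile_y(maze, w))
  maze$cache$vis <- vm
  vm
}

# per-room visibility summaries over open tiles:
#  sees_any[t, r]: tile t sees >= 1 tile of room r
#  sees_all[t, r]: tile t sees every tile of room r
room_visibility <- function(maze) {
  if (!is.null(maze$cache$roomvis)) return(maze$cache$roomvis)
  open <- open_tiles(maze)
  vm <- vis_open_matrix(maze)
  nr <- length(maze$rooms)
  sees_any <- matrix(FALSE, length(open), nr)
  sees_all <- matrix(FALSE, length(open), nr)
  for (r in seq_len(nr)) {
    cols <- match(maze$rooms[[r]], open)
    sub <- vm[, cols, drop = FALSE]
    sees_any[, r] <- rowSums(sub) > 0L
    sees_all[, r] <- rowSums(sub) == length(cols)
  }
  rv <- list(open = open, sees_any = sees_any, sees_all = sees_all)
  maze$cache$roomvis <- rv
  rv
}

# ---- belief state and revelation -------------------------------------------

#' Create a belief state
#'
#' Tracks the agent's position, which rooms have been revealed, and whether
#' the exit has been seen.
#' @param maze a `grid_maze`.
#' @param agent tile index or `c(x, y)` (default: maze start).
#' @param revealed_rooms integer vector of revealed room ids.
#' @return object of class `belief_state`.
#' @export
belief_state <- function(maze, agent = maze$start, revealed_rooms = integer(0)) {
  agent <- as_tile(maze, agent)
  assert_open_tile(maze, agent, "agent location")
  exit_room <- maze$room_id[maze$exit]
  structure(list(agent = agent,
                 revealed_rooms = sort(unique(as.integer(revealed_rooms))),
                 exit_seen = exit_room %in% revealed_rooms),
            class = "belief_state")
}

#' Move the agent and reveal rooms entering its line of sight
#'
#' Any room with at least one tile in the isovist from the new position is
#' revealed in full (all-at-once revelation); `exit_seen` is set when the
#' exit's room is revealed. Revelation is monotone and idempotent.
#'
#' @param maze a `grid_maze`.
#' @param state a `belief_state`.
#' @param new_position tile index or `c(x, y)`; must equal the agent's tile
#'   or be 4-adjacent to it, and must not be a wall.
#' @return updated `belief_state`.
#' @export
reveal <- function(maze, state, new_position) {
  new_position <- as_tile(maze, new_position)
  if (!in_bounds(maze, new_position) || maze$kind[new_position] == "wall")
    stop("invalid move: wall or out of bounds", call. = FALSE)
  if (!(new_position == state$agent ||
        new_position %in% tile_neighbours(maze, state$agent)))
    stop("invalid move: not adjacent to agent", call. = FALSE)
  rv <- room_visibility(maze)
  row <- match(new_position, rv$open)
  seen <- which(rv$sees_any[row, ])
  belief_state(maze, new_position,
               union(state$revealed_rooms, as.integer(seen)))
}

# ---- validation ------------------------------------------------------------

#' Validate a grid maze
#'
#' Checks the structural invariants: the exit lies in exactly one room;
#' rooms are disjoint, nonempty, 4-connected, and cover all room tiles; all
#' non-wall tiles form one 4-connected component containing the start; the
#' start is a corridor tile. Additionally warns about partial-visibility
#' hazards: rooms that are not fully visible from the first tile at which
#' any of their tiles becomes visible along some approach path (such
#' geometries would reveal tiles not actually in view under the
#' all-at-once revelation convention).
#'
#' @param maze a `grid_maze`.
#' @return list with `ok` (logical), `failures` (character), and
#'   `warnings` (character).
#' @export
validate_maze <- function(maze) {
  fail <- character(0); warn <- character(0)

  if (maze$kind[maze$start] != "corridor")
    fail <- c(fail, "start is not a corridor tile")
  if (maze$kind[maze$exit] != "room" || is.na(maze$room_id[maze$exit]))
    fail <- c(fail, "exit does not lie on a room tile")

  rt <- room_tiles(maze)
  covered <- sort(unlist(maze$rooms, use.names = FALSE))
  if (length(covered) != length(unique(covered)))
    fail <- c(fail, "rooms are not pairwise disjoint")
  if (!identical(sort(covered), sort(rt)))
    fail <- c(fail, "rooms do not cover all room tiles exactly")
  if (any(vapply(maze$rooms, length, 1L) == 0L))
    fail <- c(fail, "empty room")

  # 4-connectivity of each room (walks restricted to the room's own tiles)
  for (r in names(maze$rooms)) {
    tiles <- maze$rooms[[r]]
    if (length(tiles) <= 1L) next
    seen <- tiles[1L]; frontier <- tiles[1L]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(lapply(frontier, tile_neighbours,
                                             maze = maze)), tiles), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) != length(tiles))
      fail <- c(fail, sprintf("room %s is not 4-connected", r))
  }

  # global connectivity of open tiles from start
  if (maze$kind[maze$start] != "wall") {
    d <- maze_distances(maze)[maze$start, open_tiles(maze)]
    if (any(!is.finite(d)))
      fail <- c(fail, "non-wall tiles are not one connected component")
  }

  # partial-visibility hazard: for each room, every tile that could be the
  # first to see any part of it along an approach path must see it in full.
  if (!length(fail)) {
    rv <- room_visibility(maze)
    for (r in seq_along(maze$rooms)) {
      first <- first_sight_tiles(maze, r)
      bad <- first[!rv$sees_all[match(first, rv$open), r]]
      if (length(bad))
        warn <- c(warn, sprintf(
          "room %s only partially visible from first-sight tile(s) %s",
          names(maze$rooms)[r],
          paste(sprintf("(%d,%d)", tile_x(maze, bad), tile_y(maze, bad)),
                collapse = " ")))
    }
    if (length(start_visible_rooms(maze)))
      warn <- c(warn, "room(s) visible from the start tile")
  }

  list(ok = length(fail) == 0L, failures = fail, warnings = warn)
}

# tiles that can be the first tile seeing any part of room r along some
# path from the start that does not previously sight room r
first_sight_tiles <- function(maze, r) {
  rv <- room_visibility(maze)
  sees <- rv$open[rv$sees_any[, r]]
  blocked <- setdiff(sees, maze$start)
  keep <- logical(length(sees))
  for (i in seq_along(sees)) {
    v <- sees[i]
    keep[i] <- restricted_reachable(maze, maze$start, v, setdiff(blocked, v))
  }
  sees[keep]
}

# is `to` reachable from `from` over open tiles avoiding `avoid` (except at
# the endpoints)?
restricted_reachable <- function(maze, from, to, avoid) {
  if (from == to) return(TRUE)
  ok <- maze$kind != "wall"
  ok[avoid] <- FALSE
  ok[from] <- TRUE; ok[to] <- TRUE
  seen <- from; frontier <- from
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier, tile_neighbours, maze = maze)))
    nb <- nb[ok[nb]]
    nxt <- setdiff(nb, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt); frontier <- nxt
  }
  FALSE
}

# rooms with any tile visible from the start tile
start_visible_rooms <- function(maze) {
  rv <- room_visibility(maze)
  which(rv$sees_any[match(maze$start, rv$open), ])
}
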