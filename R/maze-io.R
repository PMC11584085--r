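#' Render a maze as ASCII rows
#'
#' `#` wall, `.` corridor, lowercase letter = tile of that room (letters
#' assigned in room-id order), `S` start, uppercase letter = the exit tile
#' (uppercase of its room's letter).
#' @param maze a `grid_maze`.
#' @return character vector, one string per row.
#' @export
maze_ascii <- function(maze) {
  ch <- rep("#", maze$width * maze$height)
  ch[maze$kind == "corridor"] <- "."
  for (r in seq_along(maze$rooms))
    ch[maze$rooms[[r]]] <- letters[r]
  ch[maze$exit] <- toupper(ch[maze$exit])
  ch[maze$start] <- "S"
  apply(matrix(ch, nrow = maze$height, byrow = TRUE), 1, paste, collapse = "")
}

#' Build a maze from ASCII rows
#'
#' Accepts the format written by [maze_ascii()]. An exit marked `!` is
#' resolved through the `exit` argument (or a sidecar when reading from
#' disk).
#'
#' @param rows character vector of equal-length strings.
#' @param exit optional `c(x, y)` overriding/locating the exit.
#' @param maze_id identifier.
#' @return a `grid_maze`.
#' @export
maze_from_ascii <- function(rows, exit = NULL, maze_id = "maze") {
  rows <- rows[nzchar(rows)]
  width <- unique(nchar(rows))
  if (length(width) != 1L) stop("ragged ASCII maze rows", call. = FALSE)
  height <- length(rows)
  ch <- unlist(strsplit(rows, ""))  # row-major
  kind <- rep("wall", width * height)
  room_id <- rep(NA_integer_, width * height)
  kind[ch == "."] <- "corridor"
  kind[ch == "S"] <- "corridor"
  is_room <- grepl("[a-z]", ch)
  is_exit_room <- grepl("[A-Z]", ch) & ch != "S"
  kind[is_room | is_exit_room] <- "room"
  room_id[is_room] <- match(ch[is_room], letters)
  room_id[is_exit_room] <- match(tolower(ch[is_exit_room]), letters)
  start <- which(ch == "S")
  if (length(start) != 1L) stop("maze must have exactly one start tile 'S'",
                                call. = FALSE)
  exit_idx <- which(is_exit_room | ch == "!")
  if (!is.null(exit)) exit_idx <- 1L + exit[1L] + exit[2L] * width
  if (length(exit_idx) != 1L)
    stop("maze must have exactly one exit tile", call. = FALSE)
  if (any(ch == "!") && is.na(room_id[exit_idx])) {
    # room of a '!' tile inferred from an adjacent lettered room tile
    mztmp <- list(width = width, height = height)
    nb <- c(exit_idx - 1L, exit_idx + 1L, exit_idx - width, exit_idx + width)
    nb <- nb[nb >= 1 & nb <= width * height]
    rid <- unique(room_id[nb])
    rid <- rid[!is.na(rid)]
    if (length(rid) != 1L)
      stop("cannot infer the exit's room; provide a sidecar", call. = FALSE)
    kind[exit_idx] <- "room"
    room_id[exit_idx] <- rid
  }
  grid_maze(width, height, kind, room_id, start, exit_idx, maze_id)
}

#' Write a maze as ASCII plus a key-value sidecar
#'
#' @param maze a `grid_maze`.
#' @param path path of the ASCII file; the sidecar is written next to it
#'   with extension `.sidecar`.
#' @return invisibly, the two paths.
#' @export
write_maze_ascii <- function(maze, path) {
  writeLines(maze_ascii(maze), path)
  sidecar <- paste0(path, ".sidecar")
  lines <- c(
    sprintf("maze_id = %s", maze$maze_id),
    sprintf("width = %d", maze$width),
    sprintf("height = %d", maze$height),
    sprintf("exit = %d,%d", tile_x(maze, maze$exit), tile_y(maze, maze$exit)),
    vapply(seq_along(maze$rooms), function(r)
      sprintf("room.%s = %s", letters[r], names(maze$rooms)[r]), "")
  )
  writeLines(lines, sidecar)
  invisible(c(path, sidecar))
}

#' Read a maze from ASCII plus sidecar
#'
#' @param path path of the ASCII file (sidecar expected at
#'   `paste0(path, ".sidecar")`).
#' @param randomize_exit if `TRUE`, re-randomize the exit uniformly over
#'   room tiles (requires `rng`).
#' @param rng optional seed for exit re-randomization.
#' @return a `grid_maze`.
#' @export
read_maze_ascii <- function(path, randomize_exit = FALSE, rng = NULL) {
  rows <- readLines(path)
  sc <- read_kv(paste0(path, ".sidecar"))
  exit <- as.integer(strsplit(sc[["exit"]], ",")[[1]])
  mz <- maze_from_ascii(rows, exit = exit,
                        maze_id = sc[["maze_id"]] %||% "maze")
  if (randomize_exit) {
    if (!is.null(rng)) set.seed(rng)
    mz$exit <- sample(room_tiles(mz), 1L)
  }
  mz
}

#' Write a maze as a single hierarchical structured file (JSON)
#'
#' Explicit tile lists: corridors, and per-room tile coordinates; walls are
#' implicit. Round-trips bit-exactly with [read_maze_json()].
#' @param maze a `grid_maze`.
#' @param path output path.
#' @export
write_maze_json <- function(maze, path) {
  xy <- function(idx) lapply(idx, function(i)
    c(tile_x(maze, i), tile_y(maze, i)))
  obj <- list(
    maze_id = maze$maze_id,
    width = maze$width, height = maze$height,
    start = c(tile_x(maze, maze$start), tile_y(maze, maze$start)),
    exit = c(tile_x(maze, maze$exit), tile_y(maze, maze$exit)),
    corridors = xy(which(maze$kind == "corridor")),
    rooms = lapply(maze$rooms, xy)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a maze written by [write_maze_json()]
#' @param path input path.
#' @return a `grid_maze`.
#' @export
read_maze_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  width <- obj$width; height <- obj$height
  kind <- rep("wall", width * height)
  room_id <- rep(NA_integer_, width * height)
  at <- function(m) 1L + m[, 1] + m[, 2] * width
  kind[at(as.matrix(obj$corridors))] <- "corridor"
  for (r in names(obj$rooms)) {
    idx <- at(as.matrix(obj$rooms[[r]]))
    kind[idx] <- "room"
    room_id[idx] <- as.integer(r)
  }
  grid_maze(width, height, kind, room_id,
            start = 1L + obj$start[1] + obj$start[2] * width,
            exit = 1L + obj$exit[1] + obj$exit[2] * width,
            maze_id = obj$maze_id)
}

# minimal key-value reader: "key = value" lines, '#' comments
read_kv <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed key-value line: ", lines[bad][1], call. = FALSE)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  names(vals) <- trimws(vapply(kv, `[`, "", 2L))
  as.list(vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
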