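test_that("isovist covers open corridors and is blocked by walls", {
  # 1x5 open corridor: all five tiles mutually visible
  mz <- grid_maze(7, 3, c(rep("wall", 7),
                          "wall", rep("corridor", 5), "wall",
                          rep("wall", 7)),
                  rep(NA_integer_, 21), start = 9L, exit = 9L)
  iso <- compute_isovist(mz, c(1, 1))
  expect_setequal(iso, 9:13)

  # target separated by one wall tile on the same row: not visible
  mz2 <- grid_maze(5, 3, c(rep("wall", 5),
                           "wall", "corridor", "wall", "corridor", "wall",
                           rep("wall", 5)),
                   rep(NA_integer_, 15), start = 7L, exit = 7L)
  expect_false(mazeplan:::tile_index(mz2, 3, 1) %in% compute_isovist(mz2, c(1, 1)))
})

test_that("diagonal tile across a wall corner is not visible", {
  mz <- maze_from_ascii(c("####",
                          "#S##",
                          "#.a#",
                          "####"), exit = c(2, 2), maze_id = "n2")
  # observer (1,1); wall at (2,1); diagonal (2,2): its far corner cannot be
  # seen from anywhere inside the observer tile
  iso <- compute_isovist(mz, c(1, 1))
  expect_false(mazeplan:::tile_index(mz, 2, 2) %in% iso)
  expect_true(mazeplan:::tile_index(mz, 1, 2) %in% iso)
  # observer's own tile always included
  expect_true(mazeplan:::tile_index(mz, 1, 1) %in% iso)
})

test_that("corner rule agrees with a continuous sampling oracle", {
  set.seed(4)
  cases <- list(generate_maze(4, seed = 11), get_fixtures()$long_compact)
  # plus an irregular wall soup
  w <- 10; h <- 10
  kind <- ifelse(runif(w * h) < 0.28, "wall", "corridor")
  kind[12] <- "corridor"
  cases[[3]] <- grid_maze(w, h, kind, rep(NA_integer_, w * h),
                          start = 12L, exit = 12L)
  for (mz in cases) {
    open <- which(mz$kind != "wall")
    obs <- sample(open, min(4L, length(open)))
    targets <- sample(open, min(12L, length(open)))
    for (o in obs) {
      iso <- compute_isovist(mz, o)
      for (t in targets) {
        expect_identical(t %in% iso, oracle_visible(mz, o, t),
                         label = sprintf("maze %s o=%d t=%d", mz$maze_id,
                                         o, t))
      }
    }
  }
})

test_that("isovist is symmetric and errors on invalid observers", {
  mz <- generate_maze(3, seed = 2)
  vm <- mazeplan:::vis_open_matrix(mz)
  expect_identical(vm, t(vm))
  expect_error(compute_isovist(mz, c(0, 0)), "wall")
  expect_error(compute_isovist(mz, c(-1, 5)), "bounds|wall")
})

test_that("shortest_path_steps matches hand enumeration and is a metric", {
  # wall at (1,0) forces the unique 4-step detour through row 1
  mz <- grid_maze(3, 2, c("corridor", "wall", "corridor",
                          "corridor", "corridor", "corridor"),
                  rep(NA_integer_, 6), start = 1L, exit = 1L)
  expect_identical(shortest_path_steps(mz, c(0, 0), c(2, 0)), 4L)
  expect_identical(shortest_path_steps(mz, c(0, 0), c(0, 0)), 0L)
  expect_identical(shortest_path_steps(mz, c(0, 0), c(0, 1)), 1L)
  # symmetry and triangle inequality on random triples
  gz <- generate_maze(4, seed = 8)
  open <- which(gz$kind != "wall")
  set.seed(1)
  for (k in 1:25) {
    abc <- sample(open, 3)
    dab <- shortest_path_steps(gz, abc[1], abc[2])
    dba <- shortest_path_steps(gz, abc[2], abc[1])
    dbc <- shortest_path_steps(gz, abc[2], abc[3])
    dac <- shortest_path_steps(gz, abc[1], abc[3])
    expect_identical(dab, dba)
    expect_lte(dac, dab + dbc)
  }
})

test_that("reveal is monotone, idempotent, and all-at-once", {
  mz <- get_fixtures()$eu_tie
  st <- belief_state(mz)
  expect_length(st$revealed_rooms, 0)
  # walk toward the small room's vantage
  st1 <- reveal(mz, st, c(4, 1))
  expect_length(st1$revealed_rooms, 0) # corridor only
  st2 <- reveal(mz, belief_state(mz, c(4, 1)), c(3, 1))
  expect_length(st2$revealed_rooms, 1) # one tile in sight reveals in full
  room <- st2$revealed_rooms
  expect_setequal(room, mz$room_id[mz$rooms[[room]][1]])
  # idempotent and monotone
  st3 <- reveal(mz, st2, c(3, 1))
  expect_identical(st2$revealed_rooms, st3$revealed_rooms)
  expect_true(all(st2$revealed_rooms %in% st3$revealed_rooms))
  # exit_seen flags the exit's room
  exit_room <- mz$room_id[mz$exit]
  expect_identical(st2$exit_seen, exit_room %in% st2$revealed_rooms)
  expect_error(reveal(mz, st, c(0, 0)), "wall")
  expect_error(reveal(mz, st, c(9, 1)), "adjacent")
})

test_that("validate_maze reports invariant violations", {
  for (mz in get_fixtures()) {
    v <- validate_maze(mz)
    expect_true(v$ok)
    expect_length(v$warnings, 0)
  }
  # exit on a corridor tile
  bad <- get_fixtures()$eu_tie
  bad$exit <- bad$start
  expect_false(validate_maze(bad)$ok)
  expect_match(validate_maze(bad)$failures, "exit", all = FALSE)
  # room split by a wall
  split <- maze_from_ascii(c("#####",
                             "#S..#",
                             "#a#a#",
                             "#####"), exit = c(1, 2), maze_id = "split")
  v <- validate_maze(split)
  expect_false(v$ok)
  expect_match(v$failures, "connected", all = FALSE)
})

test_that("maze files round-trip bit-exactly (ASCII and structured)", {
  mz <- generate_maze(4, seed = 19)
  tmp <- tempfile(fileext = ".maze")
  write_maze_ascii(mz, tmp)
  back <- read_maze_ascii(tmp)
  expect_identical(maze_ascii(back), maze_ascii(mz))
  expect_identical(back$start, mz$start)
  expect_identical(back$exit, mz$exit)
  expect_identical(back$rooms, mz$rooms)

  tmp2 <- tempfile(fileext = ".json")
  write_maze_json(mz, tmp2)
  back2 <- read_maze_json(tmp2)
  expect_identical(maze_ascii(back2), maze_ascii(mz))
  expect_identical(back2$exit, mz$exit)

  # exit re-randomization stays on room tiles
  rr <- read_maze_ascii(tmp, randomize_exit = TRUE, rng = 42)
  expect_true(rr$exit %in% unlist(rr$rooms))
})
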