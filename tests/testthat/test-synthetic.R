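test_that("generated mazes validate and are reproducible", {
  for (s in 1:4) {
    mz <- generate_maze(n_rooms = 3, seed = s)
    v <- validate_maze(mz)
    expect_true(v$ok)
    expect_length(v$warnings, 0)
    expect_true(mz$exit %in% unlist(mz$rooms))
  }
  m1 <- generate_maze(4, seed = 42)
  m2 <- generate_maze(4, seed = 42)
  expect_identical(maze_ascii(m1), maze_ascii(m2))
  expect_identical(m1$exit, m2$exit)
  expect_error(generate_maze(4, size = c(5, 5), seed = 1), "failed")
})

test_that("large-room-count mazes stay under the node cap", {
  mz <- generate_maze(n_rooms = 10, seed = 7, size = c(90, 12))
  tree <- build_tree(mz)
  expect_lte(length(tree$nodes), 50000L)
  expect_identical(max(vapply(tree$nodes, `[[`, 1L, "depth")) >= 5L, TRUE)
  # every leaf covers all ten rooms
  leaves <- mazeplan:::tree_leaves(tree)
  expect_true(all(vapply(leaves, function(l)
    length(tree$nodes[[l]]$observed) == 10L, TRUE)))
})

test_that("fixture mazes satisfy their captioned properties at load", {
  fx <- get_fixtures()
  expect_named(fx, c("heuristic_tie", "eu_tie", "long_compact",
                     "four_rooms", "looped"))
  # property violations are errors: corrupt a fixture and re-check
  broken <- fx
  broken$eu_tie <- maze_from_ascii(c("######",
                                     "#S.a##",
                                     "#..aA#",
                                     "######"), maze_id = "eu_tie")
  expect_error(mazeplan:::check_fixture_properties(broken))
})

test_that("cohort generation is deterministic and internally consistent", {
  mazes <- lapply(1:4, function(i)
    generate_maze(3, seed = derive_seed(500, paste0("m", i)),
                  maze_id = sprintf("c%02d", i)))
  cc <- cohort_config(5, mazes, model_mix = c(EU = 0.5, Steps = 0.5),
                      seed = 77)
  r1 <- generate_cohort(cc)
  r2 <- generate_cohort(cc)
  expect_identical(r1$decisions, r2$decisions)
  expect_identical(r1$participants, r2$participants)

  # chosen option always among listed options; statistics re-derivable
  dd <- r1$decisions
  expect_true(all(mapply(function(opts, chosen)
    chosen %in% as.integer(strsplit(opts, ",")[[1]]),
    dd$option_ids, dd$chosen_id)))
  expect_true(all(dd$decision_time_ms >= 100))
  for (i in sample(nrow(dd), 10)) {
    tree <- r1$trees[[dd$maze_id[i]]]
    opts <- as.integer(strsplit(dd$option_ids[i], ",")[[1]])
    expect_identical(opts, tree$nodes[[dd$node_id[i]]]$children)
  }

  # empty cohort
  r0 <- generate_cohort(cohort_config(0, mazes, seed = 1))
  expect_identical(nrow(r0$decisions), 0L)

  # mixture validation
  expect_error(cohort_config(5, mazes, model_mix = c(EU = 0.4)), "sum to 1")
  expect_error(cohort_config(5, mazes, time_sd = -1), "time_sd")
})

test_that("decision logs round-trip through delimited text", {
  mazes <- list(generate_maze(3, seed = 600, maze_id = "rt1"))
  res <- generate_cohort(cohort_config(3, mazes, seed = 601))
  tmp <- tempfile(fileext = ".tsv")
  write_decision_log(res$decisions, tmp)
  back <- read_decision_log(tmp)
  expect_identical(back$chosen_id, res$decisions$chosen_id)
  expect_identical(back$option_ids, res$decisions$option_ids)
  expect_equal(back$decision_time_ms, res$decisions$decision_time_ms)
  expect_identical(back$is_initial, res$decisions$is_initial)
})

test_that("cohorts generated from a model are best fit by that model", {
  mazes <- lapply(1:10, function(i)
    generate_maze(4, seed = derive_seed(520, paste0("m", i)),
                  maze_id = sprintf("id%02d", i)))
  cc <- cohort_config(12, mazes, model_mix = c(Steps = 1),
                      param_ranges = list(tau = c(0.3, 0.8),
                                          gamma = c(0.5, 0.5),
                                          beta = c(1, 1), B = c(10, 10),
                                          k_weight = c(0.5, 0.5)),
                      seed = 521)
  res <- generate_cohort(cc)
  fits <- fit_cohort(res$decisions, res$trees, c("DU", "Steps", "Cells"),
                     coarse_grids(), seed = 9)
  cmpr <- compare_models(fits$table)
  expect_identical(cmpr$ranking$model_id[1], "Steps")
})
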