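test_that("Random-model likelihood equals its closed form", {
  res <- get_fit_cohort()
  dd <- res$decisions[res$decisions$participant_id == "p001", ]
  fr <- fit_individual(dd, res$trees, "Random", coarse_grids(), seed = 4)
  expect_equal(fr$total_test_ll, sum(log(1 / dd$n_options)),
               tolerance = 1e-12)
  expect_equal(fr$total_test_ll, random_model_ll(dd), tolerance = 1e-12)
  expect_length(fr$best_params, 0)
})

test_that("fits respect nesting, priors, and input validation", {
  res <- get_fit_cohort()
  dd <- res$decisions[res$decisions$participant_id == "p002", ]
  g <- coarse_grids()
  cache <- new.env()
  fe <- fit_individual(dd, res$trees, "EU", g, seed = 7, cache = cache)
  fd <- fit_individual(dd, res$trees, "DU", g, seed = 7, cache = cache)
  # EU sits inside DU's grid (gamma = 1), so DU's train fit dominates
  expect_gte(fd$train_ll, fe$train_ll - 1e-9)
  expect_lte(fd$total_test_ll, 0)
  expect_identical(length(fd$fold_test_ll), 5L)
  expect_equal(sum(fd$fold_test_ll), fd$total_test_ll)

  expect_error(fit_individual(dd[1:3, ], res$trees, "EU", g),
               "insufficient")
  expect_error(fit_individual(dd, res$trees, "EU",
                              list(tau = numeric(0))), "empty tau grid")
  # likelihood is invariant to decision order
  perm <- sample(nrow(dd))
  f2 <- fit_individual(dd[perm, ], res$trees, "EU", g, seed = 7)
  expect_equal(colSums(mazeplan:::decision_logp(dd, res$trees, "EU", g)),
               colSums(mazeplan:::decision_logp(dd[perm, ], res$trees,
                                                "EU", g)))
  expect_equal(f2$train_ll, fe$train_ll)
})

test_that("softmax flattens toward the Random model at large tau", {
  res <- get_fit_cohort()
  dd <- res$decisions[res$decisions$participant_id == "p003", ]
  taus <- c(1, 10, 100, 1000, 10000)
  lp <- mazeplan:::decision_logp(dd, res$trees, "EU",
                                 list(tau = taus))
  gap <- abs(colSums(lp) - random_model_ll(dd))
  expect_false(is.unsorted(rev(gap))) # monotone approach
  expect_lt(gap[length(taus)], 0.02)
})

test_that("generating parameters are recovered from simulated agents", {
  res <- get_fit_cohort()
  fits <- fit_cohort(res$decisions, res$trees, "DU", coarse_grids(),
                     seed = 11)
  m <- merge(res$participants, fits$table, by = "participant_id")
  expect_gt(cor(m$gamma.x, m$gamma.y), 0.5)
  expect_lt(mean(abs(m$gamma.x - m$gamma.y)), 0.2)
})

test_that("model comparison ranks models and labels families", {
  res <- get_fit_cohort()
  fits <- fit_cohort(res$decisions, res$trees,
                     c("EU", "DU", "Steps", "Random"), coarse_grids(),
                     seed = 11)
  cmpr <- compare_models(fits$table)
  expect_identical(cmpr$ranking$delta_ll[1], 0)
  expect_true(all(diff(cmpr$ranking$total_test_ll) <= 0))
  # DU-generated cohort: planners beat heuristics for most individuals
  expect_gt(mean(cmpr$individuals$family == "planner"), 0.5)
  # identical fits give delta LL 0
  dup <- fits$table[fits$table$model_id %in% c("EU", "DU"), ]
  dup$total_test_ll <- 1 * dup$total_test_ll
  dup$total_test_ll[dup$model_id == "DU"] <-
    dup$total_test_ll[dup$model_id == "EU"]
  expect_equal(compare_models(dup)$ranking$delta_ll, c(0, 0))
  # mismatched decision sets are rejected
  bad <- fits$table
  bad$n_decisions[1] <- bad$n_decisions[1] + 1L
  expect_error(compare_models(bad), "mismatched")
})

test_that("first-choice aggregation matches hand counts", {
  log <- data.frame(
    participant_id = rep(c("a", "b", "c", "d"), each = 1),
    maze_id = "m1", node_id = 1L, option_ids = "2,3",
    chosen_id = c(2L, 2L, 3L, 2L), n_options = 2L, is_initial = TRUE,
    decision_time_ms = 1000)
  agg <- aggregate_first_choices(log)
  expect_equal(agg$prob[agg$option_id == 2], 0.75)
  expect_equal(agg$prob[agg$option_id == 3], 0.25)
  expect_equal(sum(agg$n), 8) # 4 participants x 2 options
  # all choosing one option
  log$chosen_id <- 2L
  expect_equal(aggregate_first_choices(log)$prob, c(1, 0))
  # 50/50
  log$chosen_id <- rep(c(2L, 3L), 2)
  expect_equal(aggregate_first_choices(log)$prob, c(0.5, 0.5))
})

test_that("visitation threshold filters rare nodes in all-decisions mode", {
  log <- data.frame(
    participant_id = rep(sprintf("p%d", 1:10), each = 1),
    maze_id = "m1", node_id = c(rep(1L, 9), 7L), option_ids = "2,3",
    chosen_id = 2L, n_options = 2L,
    is_initial = c(rep(TRUE, 9), FALSE), decision_time_ms = 1000)
  agg <- aggregate_first_choices(log, initial_only = FALSE, min_visit = 0.2)
  expect_false(7L %in% agg$node_id) # visited by 10% < 20% threshold
  expect_true(1L %in% agg$node_id)
})

test_that("bootstrap correlation recovers generative agreement", {
  res <- get_fit_cohort()
  emp <- aggregate_first_choices(res$decisions)
  # perfect and inverted predictions
  pred1 <- emp[, c("maze_id", "node_id", "option_id", "prob")]
  bc <- bootstrap_model_correlation(res$decisions, pred1, n_boot = 50,
                                    seed = 3)
  expect_equal(bc$r, 1)
  pred0 <- pred1
  pred0$prob <- 1 - pred0$prob
  bc0 <- bootstrap_model_correlation(res$decisions, pred0, n_boot = 20,
                                     seed = 3)
  expect_equal(bc0$r, -1)
  # the generating model correlates better than a mismatched heuristic
  mean_tau <- mean(res$participants$tau)
  mean_gamma <- mean(res$participants$gamma)
  pr_du <- predict_choice_probs(res$trees,
                                model_params("DU", tau = mean_tau,
                                             gamma = mean_gamma))
  pr_cells <- predict_choice_probs(res$trees,
                                   model_params("Cells", tau = mean_tau))
  bc2 <- bootstrap_model_correlation(res$decisions, pr_du,
                                     predicted2 = pr_cells, n_boot = 100,
                                     seed = 5)
  expect_gt(bc2$r, bc2$r2)
  # zero-variance rejection
  flat <- pred1
  flat$prob <- 0.5
  expect_error(bootstrap_model_correlation(res$decisions, flat,
                                           n_boot = 5, seed = 1),
               "zero-variance")
})
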