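#' Split a decision log into initial and subsequent decisions
#'
#' Initial decisions are made at the root of a maze's decision tree (the
#' first move of a trial, when the maze representation is formed and a
#' plan, if any, is laid); subsequent decisions occur at inner nodes.
#'
#' @param decisions decision log with an `is_initial` column.
#' @return list with `initial`, `subsequent`, and `counts`.
#' @export
split_decision_times <- function(decisions) {
  ini <- decisions[decisions$is_initial, , drop = FALSE]
  sub <- decisions[!decisions$is_initial, , drop = FALSE]
  list(initial = ini, subsequent = sub,
       counts = c(initial = nrow(ini), subsequent = nrow(sub)))
}

#' Distance of the probability-weighting exponent from optimality
#'
#' `b = |beta - 1|`: probabilities are perceived veridically at
#' `beta = 1`, and `b` maps `beta` in `[0, 2]` onto `[0, 1]` so that
#' larger values mean less exact probability perception in either
#' direction.
#' @param beta weighting exponent(s).
#' @return nonnegative distance(s).
#' @export
beta_distance <- function(beta) abs(beta - 1)

#' Regress decision times on fitted model parameters
#'
#' Ordinary least squares at the level of individual decisions (each
#' observation is one decision; its predictors are the deciding
#' participant's fitted parameters). The predictor set follows the model:
#' `EU` uses `tau`; `DU` adds `gamma`; `DU-Num` adds `B`; `PW-DU` adds
#' `b = |beta - 1|`.
#'
#' @param decisions one side of [split_decision_times()] (must carry
#'   `participant_id` and `decision_time_ms`).
#' @param params data.frame of per-participant fitted parameters
#'   (`participant_id`, `tau`, and as needed `gamma`, `B`, `beta`).
#' @param model_id one of `"EU"`, `"DU"`, `"DU-Num"`, `"PW-DU"`.
#' @return list with `coefficients` (estimate, p-value per term),
#'   `f_statistic` (`F`, `df1`, `df2`, `p`), `n`, and the underlying
#'   `lm` fit.
#' @export
regress_times <- function(decisions, params, model_id = c("EU", "DU",
                                                          "DU-Num", "PW-DU")) {
  model_id <- match.arg(model_id)
  preds <- switch(model_id,
                  "EU" = "tau",
                  "DU" = c("tau", "gamma"),
                  "DU-Num" = c("tau", "gamma", "B"),
                  "PW-DU" = c("tau", "gamma", "b"))
  if (model_id == "PW-DU" && !"b" %in% names(params))
    params$b <- beta_distance(params$beta)
  missing_p <- setdiff(preds, names(params))
  if (length(missing_p))
    stop("missing fitted parameter column(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  df <- merge(decisions[, c("participant_id", "decision_time_ms")],
              params[, c("participant_id", preds)], by = "participant_id")
  if (any(!stats::complete.cases(df)))
    stop("missing parameter values for some participants", call. = FALSE)
  X <- as.matrix(df[, preds, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("rank-deficient design", call. = FALSE)
  fit <- lm(stats::reformulate(preds, response = "decision_time_ms"),
            data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(coefficients = data.frame(
         term = rownames(sm$coefficients),
         estimate = sm$coefficients[, 1],
         p_value = sm$coefficients[, 4], row.names = NULL),
       f_statistic = c(F = unname(fstat[1]), df1 = unname(fstat[2]),
                       df2 = unname(fstat[3]),
                       p = unname(pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE))),
       n = nrow(df), fit = fit)
}

#' Export a pair of decision-time regressions as a delimited table
#'
#' One row per (times type, term), mirroring the standard layout
#' (intercept and slope estimates with p-values, F statistics with
#' degrees of freedom).
#' @param initial,subsequent results of [regress_times()].
#' @param path output path (tab-separated).
#' @export
write_regression_table <- function(initial, subsequent, path) {
  fmt <- function(res, label) {
    data.frame(times = label,
               term = res$coefficients$term,
               estimate = res$coefficients$estimate,
               p_value = res$coefficients$p_value,
               F = unname(res$f_statistic["F"]),
               df1 = unname(res$f_statistic["df1"]),
               df2 = unname(res$f_statistic["df2"]),
               model_p = unname(res$f_statistic["p"]))
  }
  tab <- rbind(fmt(initial, "initial"), fmt(subsequent, "subsequent"))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tab)
}
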