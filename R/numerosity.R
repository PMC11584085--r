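#' Bit-limited numerosity perception channel
#'
#' Models approximate number perception as a lossy channel with a capacity
#' of `B` bits. True counts `n` in 1..80 are drawn from a Zipf-like prior
#' `P(n) proportional to 1/n^2`; the channel `Q(k | n)` minimizes the
#' expected relative squared error `d(n, k) = ((n - k) / n)^2` subject to
#' the mutual information between `n` and the estimate `k` not exceeding
#' `B` bits. The expected subjective estimate is `q(n) = sum_k k Q(k|n)`.
#' Large `B` gives exact counting (`q(n) = n`); as `B` approaches 0 every
#' count is perceived as the prior mean.
#'
#' The constrained problem is solved by alternating minimization at a
#' fixed information price `lambda` (`Q(k|n) proportional to
#' m(k) exp(-lambda d(n,k))` with marginal updates), with an outer
#' bisection on `lambda` to meet the information constraint.
#'
#' @param B bit threshold, in `[0.1, 10]`.
#' @param n_max domain upper bound for counts (default 80).
#' @param tol convergence tolerance on the alternating iteration (change in
#'   expected distortion).
#' @param info_tol how closely the mutual information must match `B` in the
#'   bisection (bits).
#' @param max_iter iteration cap for the inner loop; exceeding it is an
#'   error.
#' @return an object of class `numerosity_channel` with elements `B`,
#'   `domain`, `prior`, `Q` (rows = true count, columns = estimate), `q`
#'   (expected estimate per count), and `mutual_information` (bits).
#' @export
build_channel <- function(B, n_max = 80L, tol = 1e-8, info_tol = 1e-3,
                          max_iter = 20000L) {
  if (!is.numeric(B) || length(B) != 1L || B < 0.1 || B > 10)
    stop("B must be a single number in [0.1, 10]", call. = FALSE)
  n <- seq_len(n_max)
  prior <- (1 / n^2) / sum(1 / n^2)
  dist <- outer(n, n, function(nn, kk) ((nn - kk) / nn)^2)
  h_prior <- -sum(prior * log2(prior))

  solve_at <- function(lambda) {
    m <- prior # initial output marginal
    last_d <- Inf
    for (it in seq_len(max_iter)) {
      logq <- log(pmax(m, 1e-300))[col(dist)] - lambda * dist
      logq <- logq - apply(logq, 1, max)
      Q <- exp(logq)
      Q <- Q / rowSums(Q)
      m <- colSums(prior * Q)
      d_now <- sum(prior * rowSums(Q * dist))
      if (abs(last_d - d_now) < tol) break
      last_d <- d_now
      if (it == max_iter)
        stop("numerosity channel failed to converge", call. = FALSE)
    }
    mi <- sum(prior * rowSums(Q * (log2(pmax(Q, 1e-300)) -
                                     log2(pmax(m, 1e-300))[col(Q)])))
    list(Q = Q, m = m, mi = mi)
  }

  # mutual information grows with lambda; bisect to hit B (or saturate)
  lo <- 0; hi <- 4
  sol_hi <- solve_at(hi)
  while (sol_hi$mi < B && hi < 2^16) {
    hi <- hi * 4
    sol_hi <- solve_at(hi)
  }
  if (sol_hi$mi <= B + info_tol) {
    sol <- sol_hi # constraint slack (B >= achievable information)
  } else {
    for (i in seq_len(200L)) {
      mid <- (lo + hi) / 2
      sol <- solve_at(mid)
      if (abs(sol$mi - B) < info_tol) break
      if (sol$mi > B) hi <- mid else lo <- mid
    }
    if (sol$mi > B + info_tol) sol <- solve_at(lo)
  }

  q <- as.numeric(sol$Q %*% n)
  # the discrete reproduction alphabet can leave small non-monotone
  # wiggles in low-prior regions; pool them so q is nondecreasing
  q <- stats::isoreg(n, q)$yf
  structure(list(B = B, domain = n, prior = prior, Q = sol$Q, q = q,
                 mutual_information = sol$mi, entropy_prior = h_prior),
            class = "numerosity_channel")
}

#' @export
print.numerosity_channel <- function(x, ...) {
  cat(sprintf(
    "<numerosity_channel B=%.3g bits (I=%.3f), domain 1..%d, q(1)=%.2f q(%d)=%.2f>\n",
    x$B, x$mutual_information, max(x$domain), x$q[1], max(x$domain),
    x$q[length(x$q)]))
  invisible(x)
}

#' Expected subjective estimate of a count
#'
#' Looks up `q(n)` in the channel table. Counts above the domain maximum
#' clamp to the maximum with a warning; `n < 1` is an error.
#'
#' @param channel a `numerosity_channel`.
#' @param n true count(s); real values are linearly interpolated between
#'   the integer table entries.
#' @return real-valued estimate(s).
#' @export
subjective_quantity <- function(channel, n) {
  if (any(n < 1)) stop("count below domain minimum (1)", call. = FALSE)
  n_max <- max(channel$domain)
  if (any(n > n_max)) {
    warning(sprintf("count above %d clamped to %d", n_max, n_max))
    n <- pmin(n, n_max)
  }
  stats::approx(channel$domain, channel$q, xout = n, rule = 2)$y
}

# distortion helper used inside cost models: q() extended by distort(0) = 0
distort_count <- function(channel, n) {
  out <- numeric(length(n))
  pos <- n >= 1
  out[pos] <- subjective_quantity(channel, n[pos])
  out[!pos] <- 0
  out
}

#' Export a channel table as delimited text
#'
#' Columns `B`, `n`, `q`; tab-separated with a header.
#' @param channel a `numerosity_channel`.
#' @param path output path.
#' @export
write_channel_table <- function(channel, path) {
  utils::write.table(
    data.frame(B = channel$B, n = channel$domain, q = channel$q),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# channel cache on a fixed grid of B values used in fitting
channel_cache <- new.env(parent = emptyenv())

get_channel <- function(B) {
  key <- sprintf("%.6g", B)
  if (is.null(channel_cache[[key]]))
    channel_cache[[key]] <- build_channel(B)
  channel_cache[[key]]
}
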