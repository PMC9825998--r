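# No-U-Turn sampler (multinomial variant) with dual-averaging step-size
# adaptation and diagonal metric estimation during warmup. The interface is
# generic: `logpost(q)` must return list(lp = scalar, grad = vector).

logsumexp2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

nuts_velocity <- function(p, inv_metric) {
  if (is.list(inv_metric)) drop(inv_metric$Sigma %*% p) else inv_metric * p
}

nuts_momentum <- function(d, inv_metric) {
  z <- stats::rnorm(d)
  if (is.list(inv_metric)) backsolve(inv_metric$R, z) else z / sqrt(inv_metric)
}

nuts_leapfrog <- function(q, p, eps, grad, logpost, inv_metric) {
  p <- p + 0.5 * eps * grad
  q <- q + eps * nuts_velocity(p, inv_metric)
  lg <- logpost(q)
  p <- p + 0.5 * eps * lg$grad
  list(q = q, p = p, lp = lg$lp, grad = lg$grad)
}

nuts_hamiltonian <- function(lp, p, inv_metric)
  -lp + 0.5 * sum(p * nuts_velocity(p, inv_metric))

# Recursive balanced-tree doubling. A node carries both edge states (with
# gradients, for further extension), a multinomially-sampled proposal, the
# log total weight, accept-statistic accumulators and status flags.
nuts_build_tree <- function(state, depth, dir, eps, H0, logpost, inv_metric) {
  if (depth == 0L) {
    s <- nuts_leapfrog(state$q, state$p, dir * eps, state$grad, logpost,
                       inv_metric)
    H <- if (is.finite(s$lp)) nuts_hamiltonian(s$lp, s$p, inv_metric) else Inf
    diverged <- !is.finite(H) || (H - H0) > 1000
    logw <- if (diverged) -Inf else H0 - H
    alpha <- if (diverged) 0 else min(1, exp(H0 - H))
    return(list(minus = s, plus = s, prop = s$q, logw = logw,
                sum_alpha = alpha, n_alpha = 1L, diverged = diverged,
                turning = FALSE, n_leapfrog = 1L))
  }
  inner <- nuts_build_tree(state, depth - 1L, dir, eps, H0, logpost,
                           inv_metric)
  if (inner$diverged || inner$turning) return(inner)
  edge <- if (dir == 1L) inner$plus else inner$minus
  outer <- nuts_build_tree(edge, depth - 1L, dir, eps, H0, logpost,
                           inv_metric)
  out <- list(
    minus = if (dir == 1L) inner$minus else outer$minus,
    plus  = if (dir == 1L) outer$plus else inner$plus,
    logw = logsumexp2(inner$logw, outer$logw),
    sum_alpha = inner$sum_alpha + outer$sum_alpha,
    n_alpha = inner$n_alpha + outer$n_alpha,
    diverged = outer$diverged,
    n_leapfrog = inner$n_leapfrog + outer$n_leapfrog)
  out$prop <- if (is.finite(out$logw) &&
                  log(stats::runif(1)) < outer$logw - out$logw)
    outer$prop else inner$prop
  # generalized U-turn: the span dotted with the end momenta (equivalent to
  # Stan's rho-based criterion for a constant metric)
  span <- out$plus$q - out$minus$q
  out$turning <- outer$turning ||
    sum(span * out$minus$p) < 0 || sum(span * out$plus$p) < 0
  out
}

nuts_transition <- function(q, lg, eps, max_treedepth, logpost, inv_metric) {
  d <- length(q)
  p0 <- nuts_momentum(d, inv_metric)
  H0 <- nuts_hamiltonian(lg$lp, p0, inv_metric)
  minus <- plus <- list(q = q, p = p0, lp = lg$lp, grad = lg$grad)
  prop <- q; prop_lg <- lg
  logw <- 0
  sum_alpha <- 0; n_alpha <- 0L
  depth <- 0L; diverged <- FALSE
  while (depth < max_treedepth) {
    dir <- if (stats::runif(1) < 0.5) -1L else 1L
    sub <- nuts_build_tree(if (dir == 1L) plus else minus, depth, dir, eps,
                           H0, logpost, inv_metric)
    sum_alpha <- sum_alpha + sub$sum_alpha
    n_alpha <- n_alpha + sub$n_alpha
    if (sub$diverged) { diverged <- TRUE; break }
    if (sub$turning) break
    # biased progressive sampling across doublings
    if (log(stats::runif(1)) < sub$logw - logw) {
      prop <- sub$prop
      prop_lg <- NULL
    }
    logw <- logsumexp2(logw, sub$logw)
    if (dir == 1L) plus <- sub$plus else minus <- sub$minus
    span <- plus$q - minus$q
    if (sum(span * minus$p) < 0 || sum(span * plus$p) < 0) break
    depth <- depth + 1L
  }
  if (is.null(prop_lg)) prop_lg <- logpost(prop)
  list(q = prop, lg = prop_lg,
       accept_stat = if (n_alpha > 0) sum_alpha / n_alpha else 0,
       diverged = diverged, treedepth = depth)
}

nuts_find_epsilon <- function(q, lg, logpost, inv_metric) {
  eps <- 1
  d <- length(q)
  p0 <- nuts_momentum(d, inv_metric)
  H0 <- nuts_hamiltonian(lg$lp, p0, inv_metric)
  ratio_at <- function(eps) {
    s <- tryCatch(nuts_leapfrog(q, p0, eps, lg$grad, logpost, inv_metric),
                  error = function(e) NULL)
    if (is.null(s) || !is.finite(s$lp) || any(!is.finite(s$p))) return(0)
    r <- exp(H0 - nuts_hamiltonian(s$lp, s$p, inv_metric))
    if (is.nan(r)) 0 else r
  }
  a0 <- ratio_at(eps)
  dir <- if (a0 > 0.5) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^dir
    a <- ratio_at(eps)
    if ((dir == 1 && a <= 0.5) || (dir == -1 && a >= 0.5)) break
  }
  eps
}

# Stan-style warmup schedule: step-size-only buffers flank doubling
# variance-estimation windows.
nuts_windows <- function(warmup, init_buffer = 75L, term_buffer = 50L,
                         base_window = 25L) {
  if (warmup < init_buffer + term_buffer + base_window) {
    frac <- warmup / (init_buffer + term_buffer + base_window)
    init_buffer <- max(1L, as.integer(frac * init_buffer))
    term_buffer <- max(1L, as.integer(frac * term_buffer))
    base_window <- max(1L, warmup - init_buffer - term_buffer)
  }
  ends <- integer(0)
  pos <- init_buffer
  w <- base_window
  while (pos + w < warmup - term_buffer) {
    # final window absorbs the remainder if doubling again would overflow
    if (pos + w + 2L * w >= warmup - term_buffer) w <- warmup - term_buffer - pos
    pos <- pos + w
    ends <- c(ends, pos)
    w <- 2L * w
  }
  if (!length(ends) && warmup - term_buffer > init_buffer)
    ends <- warmup - term_buffer
  list(init_buffer = init_buffer, term_buffer = term_buffer,
       window_ends = ends)
}

#' Sample from a log posterior with the No-U-Turn sampler
#'
#' Multinomial NUTS with dual-averaging adaptation of the step size (target
#' acceptance statistic \code{target_accept}) and windowed estimation of a
#' diagonal metric during burn-in, after which both are frozen. Chains are
#' run sequentially with per-chain seeds derived from \code{seed}, so results
#' are fully reproducible.
#'
#' @param logpost function of the parameter vector returning
#'   \code{list(lp = , grad = )} (log posterior density up to a constant and
#'   its gradient).
#' @param init matrix (chains x parameters) of initial values, or a function
#'   of the chain index returning an initial vector.
#' @param n_params number of parameters.
#' @param chains,iterations,burn_in chain protocol; \code{iterations} includes
#'   the \code{burn_in} warmup, so \code{chains * (iterations - burn_in)}
#'   draws are retained.
#' @param seed integer seed.
#' @param max_treedepth maximum tree doubling depth (default 10).
#' @param target_accept dual-averaging target (default 0.8).
#' @param metric \code{"diag"} (default) or \code{"dense"}: estimate a
#'   diagonal or full covariance metric during warmup.
#' @return list with \code{draws} (array \code{[kept, chains, n_params]}),
#'   \code{n_divergent}, \code{step_sizes}.
#' @keywords internal
nuts_sample <- function(logpost, init, n_params, chains = 4,
                        iterations = 4000, burn_in = 2000, seed = 1,
                        max_treedepth = 10L, target_accept = 0.8,
                        metric = c("diag", "dense")) {
  metric <- match.arg(metric)
  stopifnot(iterations > burn_in, chains >= 1)
  kept <- iterations - burn_in
  draws <- array(NA_real_, c(kept, chains, n_params))
  n_div <- integer(chains)
  step_sizes <- numeric(chains)
  metrics <- matrix(NA_real_, chains, n_params)
  depth_sum <- numeric(chains)
  sched <- nuts_windows(burn_in)
  for (ch in seq_len(chains)) {
    q <- if (is.function(init)) init(ch) else init[ch, ]
    set.seed(seed + 7451L * ch)
    lg <- logpost(q)
    if (!is.finite(lg$lp)) stop("initial value has non-finite log posterior")
    inv_metric <- rep(1, n_params)
    eps <- nuts_find_epsilon(q, lg, logpost, inv_metric)
    # dual averaging state
    mu <- log(10 * eps); log_ebar <- 0; hbar <- 0; m_adapt <- 0L
    gamma <- 0.05; t0 <- 10; kappa <- 0.75
    # Welford accumulators for the metric
    w_n <- 0L; w_mean <- rep(0, n_params)
    w_m2 <- rep(0, n_params)
    w_cov <- matrix(0, n_params, n_params)
    first_update <- if (length(sched$window_ends)) sched$window_ends[1] else 0L
    for (it in seq_len(iterations)) {
      # before the first metric update the identity metric can force very
      # deep trees on sharply scaled posteriors; cap the depth there, it only
      # affects adaptation speed, never retained draws
      td <- if (it <= first_update) min(6L, max_treedepth) else max_treedepth
      # state-independent +/-10% step-size jitter breaks resonances between
      # the step size and the posterior's oscillation periods
      tr <- nuts_transition(q, lg, eps * stats::runif(1, 0.9, 1.1), td,
                            logpost, inv_metric)
      q <- tr$q; lg <- tr$lg
      if (it <= burn_in) {
        m_adapt <- m_adapt + 1L
        hbar <- (1 - 1 / (m_adapt + t0)) * hbar +
          (target_accept - tr$accept_stat) / (m_adapt + t0)
        log_eps <- mu - sqrt(m_adapt) / gamma * hbar
        eta <- m_adapt^(-kappa)
        log_ebar <- eta * log_eps + (1 - eta) * log_ebar
        eps <- exp(log_eps)
        in_window <- it > sched$init_buffer &&
          it <= (burn_in - sched$term_buffer)
        if (in_window) {
          w_n <- w_n + 1L
          delta <- q - w_mean
          w_mean <- w_mean + delta / w_n
          w_m2 <- w_m2 + delta * (q - w_mean)
          if (metric == "dense")
            w_cov <- w_cov + tcrossprod(delta, q - w_mean)
        }
        if (it %in% sched$window_ends && w_n > 2L) {
          shrink <- w_n / (w_n + 5)
          if (metric == "dense") {
            S <- w_cov / (w_n - 1L) * shrink
            diag(S) <- diag(S) + 1e-3 * (1 - shrink)
            inv_metric <- list(Sigma = S, R = chol(S))
          } else {
            v <- w_m2 / (w_n - 1L)
            inv_metric <- v * shrink + 1e-3 * (1 - shrink)
          }
          w_n <- 0L; w_mean[] <- 0; w_m2[] <- 0; w_cov[] <- 0
          eps <- nuts_find_epsilon(q, lg, logpost, inv_metric)
          mu <- log(10 * eps); log_ebar <- 0; hbar <- 0; m_adapt <- 0L
        }
        if (it == burn_in) eps <- exp(log_ebar)
      } else {
        if (tr$diverged) n_div[ch] <- n_div[ch] + 1L
        draws[it - burn_in, ch, ] <- q
        depth_sum[ch] <- depth_sum[ch] + tr$treedepth
      }
    }
    step_sizes[ch] <- eps
    metrics[ch, ] <- if (is.list(inv_metric)) diag(inv_metric$Sigma) else inv_metric
  }
  list(draws = draws, n_divergent = n_div, step_sizes = step_sizes,
       inv_metric = metrics, mean_treedepth = depth_sum / kept)
}
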