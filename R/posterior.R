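# split-chain potential scale reduction (classic Rhat) for one parameter;
# `x` is an [iterations x chains] matrix
split_rhat <- function(x) {
  n <- nrow(x)
  half <- n %/% 2L
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(1)
  var_plus <- (nn - 1) / nn * W + B / nn
  sqrt(var_plus / W)
}

# autocorrelation-based effective sample size (Geyer initial monotone
# sequence, combined across chains as in Stan)
ess_param <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) stop("ESS requires at least 4 draws per chain")
  vars <- apply(x, 2, stats::var)
  if (all(vars == 0)) return(NA_real_)
  acov <- apply(x, 2, function(ch) {
    a <- stats::acf(ch, lag.max = n - 1L, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  W <- mean(vars)
  var_plus <- W * (n - 1) / n
  if (m > 1) var_plus <- var_plus + stats::var(colMeans(x))
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer: sum of adjacent pairs, truncated at first negative, made monotone
  max_pairs <- (n - 1L) %/% 2L
  tau <- 0; prev <- Inf
  for (k in 0:max_pairs) {
    p <- rho[2 * k + 1] + if (2 * k + 2 <= length(rho)) rho[2 * k + 2] else 0
    if (k > 0 && p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + p
  }
  tau <- max(2 * tau - 1, 1 / log10(n * m))
  n * m / tau
}

#' MCMC convergence diagnostics
#'
#' Split-chain potential scale reduction statistic (classic Rhat) and
#' autocorrelation-based effective sample size for every parameter of a draw
#' array.
#'
#' @param draws array \code{[iterations, chains, parameters]} (with parameter
#'   dimnames), or a \code{\link{fit_hill_hierarchical}} /
#'   \code{\link{fit_mwc_joint}} result.
#' @return data.frame with columns \code{param}, \code{rhat}, \code{ess}.
#' @export
mcmc_diagnostics <- function(draws) {
  if (inherits(draws, "posterior_set")) draws <- draws$draws
  stopifnot(length(dim(draws)) == 3L)
  if (dim(draws)[2] < 2L) stop("diagnostics require at least 2 chains")
  if (dim(draws)[1] < 4L) stop("diagnostics require at least 4 draws per chain")
  pn <- dimnames(draws)[[3]]
  if (is.null(pn)) pn <- paste0("p", seq_len(dim(draws)[3]))
  data.frame(
    param = pn,
    rhat = vapply(seq_len(dim(draws)[3]),
                  function(k) split_rhat(draws[, , k]), numeric(1)),
    ess = vapply(seq_len(dim(draws)[3]),
                 function(k) ess_param(draws[, , k]), numeric(1)))
}

new_posterior_set <- function(draws, meta) {
  diag <- mcmc_diagnostics(draws)
  flagged <- any(diag$rhat > 1.05, na.rm = TRUE)
  structure(list(draws = draws, diagnostics = diag, meta = meta,
                 converged = !flagged),
            class = "posterior_set")
}

#' @export
print.posterior_set <- function(x, ...) {
  d <- dim(x$draws)
  cat("<posterior_set> ", d[1], " draws x ", d[2], " chains (",
      d[1] * d[2], " total), ", d[3], " parameters\n", sep = "")
  cat("  model: ", x$meta$model, "; seed ", x$meta$seed, "\n", sep = "")
  cat(sprintf("  max Rhat %.3f, min ESS %.0f%s\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE),
              if (!x$converged) "  ** NOT CONVERGED (Rhat > 1.05)" else ""))
  invisible(x)
}

#' Posterior medians and central quantile intervals
#'
#' @param posterior a \code{posterior_set} (or a named list/matrix of draws).
#' @param intervals central interval widths in percent (default 50, 80, 95).
#' @return data.frame with the median and \code{lo<w>}/\code{hi<w>} columns
#'   per parameter.
#' @export
summarize_posterior <- function(posterior, intervals = c(50, 80, 95)) {
  draws <- if (inherits(posterior, "posterior_set")) posterior$draws else posterior
  stopifnot(length(dim(draws)) == 3L)
  pn <- dimnames(draws)[[3]]
  out <- data.frame(param = pn, median = NA_real_)
  for (w in intervals) {
    out[[paste0("lo", w)]] <- NA_real_
    out[[paste0("hi", w)]] <- NA_real_
  }
  for (k in seq_along(pn)) {
    v <- as.vector(draws[, , k])
    out$median[k] <- stats::median(v)
    for (w in intervals) {
      qs <- stats::quantile(v, c((1 - w / 100) / 2, 1 - (1 - w / 100) / 2),
                            names = FALSE)
      out[[paste0("lo", w)]][k] <- qs[1]
      out[[paste0("hi", w)]][k] <- qs[2]
    }
  }
  out
}

#' @export
summary.posterior_set <- function(object, ...) summarize_posterior(object, ...)

# pooled draws of one named parameter
posterior_param_draws <- function(posterior, parameter) {
  draws <- if (inherits(posterior, "posterior_set")) posterior$draws else posterior
  pn <- dimnames(draws)[[3]]
  if (!parameter %in% pn)
    stop("parameter '", parameter, "' not found in posterior (has: ",
         paste(pn, collapse = ", "), ")")
  as.vector(draws[, , match(parameter, pn)])
}

#' Posterior fold-change contrast between two constructs
#'
#' Elementwise \code{10^(log10 IC50[mutant] - log10 IC50[control])} over
#' paired posterior draws: the full control posterior is subtracted from the
#' mutant posterior on the log10 scale, and the difference is expressed as a
#' fold-change in IC50. Draws are paired in order after truncation to the
#' common length.
#'
#' @param posterior_mutant,posterior_control \code{posterior_set} objects (or
#'   draw arrays) containing \code{parameter}.
#' @param parameter contrasted parameter (default \code{"log10_IC50"}).
#' @param intervals central interval widths for the summary.
#' @return object of class \code{"fold_change"}: list with \code{draws}
#'   (fold-change samples) and \code{summary} (median + intervals).
#' @export
contrast_fold_change <- function(posterior_mutant, posterior_control,
                                 parameter = "log10_IC50",
                                 intervals = c(50, 80, 95)) {
  a <- posterior_param_draws(posterior_mutant, parameter)
  b <- posterior_param_draws(posterior_control, parameter)
  n <- min(length(a), length(b))
  fc <- 10^(a[seq_len(n)] - b[seq_len(n)])
  med <- stats::median(fc)
  summ <- data.frame(median = med)
  for (w in intervals) {
    qs <- stats::quantile(fc, c((1 - w / 100) / 2, 1 - (1 - w / 100) / 2),
                          names = FALSE)
    summ[[paste0("lo", w)]] <- qs[1]
    summ[[paste0("hi", w)]] <- qs[2]
  }
  structure(list(draws = fc, summary = summ), class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  s <- x$summary
  cat(sprintf("IC50 fold-change: median %.3g (95%%: %.3g - %.3g)\n",
              s$median, s$lo95, s$hi95))
  invisible(x)
}
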