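#' Prior specification for the hierarchical Hill model
#'
#' Defaults follow the fitting protocol for nucleotide inhibition:
#' \code{h ~ Normal(1, 0.3)}, \code{Imax ~ Uniform(0, 1)},
#' \code{log10 IC50 ~ Normal(-4, 1)} (i.e. centred on 100 uM). The "0.3" and
#' "1" scales are standard deviations, not variances. The between-patch
#' scatter of log10 IC50 and the observation-noise SD are given weakly
#' informative half-Normal(0, 0.1) priors on their observed scales.
#'
#' @param ic50_mean,ic50_sd Normal prior on the population log10 IC50.
#' @param h_mean,h_sd Normal prior on the Hill slope.
#' @param imax_lo,imax_hi Uniform prior bounds on Imax.
#' @param sigma_patch_scale half-Normal scale of the between-patch log10 IC50
#'   SD.
#' @param sigma_obs_scale half-Normal scale of the observation noise SD
#'   (fractional current units).
#' @return named list of class \code{"hill_priors"}.
#' @export
hill_priors <- function(ic50_mean = -4, ic50_sd = 1, h_mean = 1, h_sd = 0.3,
                        imax_lo = 0, imax_hi = 1, sigma_patch_scale = 0.1,
                        sigma_obs_scale = 0.1) {
  stopifnot(ic50_sd > 0, h_sd > 0, imax_lo < imax_hi,
            sigma_patch_scale > 0, sigma_obs_scale > 0)
  structure(list(ic50_mean = ic50_mean, ic50_sd = ic50_sd, h_mean = h_mean,
                 h_sd = h_sd, imax_lo = imax_lo, imax_hi = imax_hi,
                 sigma_patch_scale = sigma_patch_scale,
                 sigma_obs_scale = sigma_obs_scale),
            class = "hill_priors")
}

#' Prior specification for the MWC model
#'
#' Defaults: \code{log10 L ~ Normal(0, 0.7)},
#' \code{log10 KA ~ Uniform(2, 6)} (KA in 100 to 1e6 per molar),
#' \code{D ~ Uniform(0, 1)}; half-Normal(0, 0.1) on both observation-noise
#' SDs (current and quenching).
#'
#' @param log10L_mean,log10L_sd Normal prior on log10 L.
#' @param log10KA_lo,log10KA_hi Uniform prior bounds on log10 KA.
#' @param D_lo,D_hi Uniform prior bounds on D.
#' @param sigma_obs_scale half-Normal scale of both observation-noise SDs.
#' @return named list of class \code{"mwc_priors"}.
#' @export
mwc_priors <- function(log10L_mean = 0, log10L_sd = 0.7, log10KA_lo = 2,
                       log10KA_hi = 6, D_lo = 0, D_hi = 1,
                       sigma_obs_scale = 0.1) {
  stopifnot(log10L_sd > 0, log10KA_lo < log10KA_hi, D_lo < D_hi,
            D_lo >= 0, D_hi <= 1, sigma_obs_scale > 0)
  structure(list(log10L_mean = log10L_mean, log10L_sd = log10L_sd,
                 log10KA_lo = log10KA_lo, log10KA_hi = log10KA_hi,
                 D_lo = D_lo, D_hi = D_hi,
                 sigma_obs_scale = sigma_obs_scale),
            class = "mwc_priors")
}

plogis_ <- function(x) 1 / (1 + exp(-x))

# log posterior + gradient for the hierarchical Hill model, centred
# parameterization. Parameter vector: (mu, h, li, lsp, lso, theta_1..theta_J)
# with Imax = lo + (hi-lo) plogis(li), sigma_patch = exp(lsp),
# sigma_obs = floor + exp(lso), theta_j the patch-level log10 IC50 with prior
# Normal(mu, sigma_patch). The centred form is used because each patch's
# dose-response determines its own IC50 well, which is the regime where the
# centred parameterization mixes efficiently.
make_hill_logpost_centered <- function(y, log10c, patch, priors, sigma_floor) {
  J <- if (length(patch)) max(patch) else 0L
  n <- length(y)
  pos <- is.finite(log10c)
  ln10 <- log(10)
  lo <- priors$imax_lo; hi <- priors$imax_hi
  ssp <- priors$sigma_patch_scale; sso <- priors$sigma_obs_scale
  function(q) {
    mu <- q[1]; h <- q[2]; li <- q[3]; lsp <- q[4]; lso <- q[5]
    theta_p <- if (J > 0) q[5L + seq_len(J)] else numeric(0)
    pI <- plogis_(li); imax <- lo + (hi - lo) * pI
    sp <- exp(lsp); sof <- exp(lso); so <- sigma_floor + sof
    f <- rep(1, n)
    grad <- numeric(5L + J)
    gI_lik <- 0; gh <- 0
    if (n > 0) {
      theta <- if (J > 0) theta_p[patch] else rep(mu, n)
      w <- 1 / (1 + 10^(h * (log10c[pos] - theta[pos])))
      f[pos] <- 1 - imax + imax * w
      rp <- ((y - f) / so^2)[pos]
      df_dg <- -imax * w * (1 - w) * ln10       # = -imax u/(1+u)^2 ln10
      common <- rp * df_dg
      gh <- sum(common * (log10c[pos] - theta[pos]))
      t_r <- -h * common
      if (J > 0) {
        gz <- rep(0, J)
        agg <- tapply(t_r, patch[pos], sum)
        gz[as.integer(names(agg))] <- as.numeric(agg)
        grad[5L + seq_len(J)] <- gz
      } else {
        grad[1] <- sum(t_r)
      }
      gI_lik <- sum(rp * (w - 1))
      lp_lik <- -n * log(so) - 0.5 * sum((y - f)^2) / so^2
      dlp_dso <- -n / so + sum((y - f)^2) / so^3
    } else {
      lp_lik <- 0
      dlp_dso <- 0
    }
    dev <- theta_p - mu
    lp <- lp_lik -
      0.5 * (mu - priors$ic50_mean)^2 / priors$ic50_sd^2 -
      0.5 * (h - priors$h_mean)^2 / priors$h_sd^2 +
      log(pI * (1 - pI)) -
      0.5 * sp^2 / ssp^2 + lsp -
      0.5 * sof^2 / sso^2 + lso -
      J * log(sp) - 0.5 * sum(dev^2) / sp^2
    grad[1] <- grad[1] + sum(dev) / sp^2 -
      (mu - priors$ic50_mean) / priors$ic50_sd^2
    grad[2] <- gh - (h - priors$h_mean) / priors$h_sd^2
    grad[3] <- gI_lik * (hi - lo) * pI * (1 - pI) + (1 - 2 * pI)
    grad[4] <- (-J / sp + sum(dev^2) / sp^3) * sp - sp^2 / ssp^2 + 1
    grad[5] <- dlp_dso * sof - sof^2 / sso^2 + 1
    if (J > 0) grad[5L + seq_len(J)] <- grad[5L + seq_len(J)] - dev / sp^2
    list(lp = lp, grad = grad)
  }
}

# non-centred variant: (mu, h, li, lsp, lso, z_1..z_J) with patch log10 IC50
# = mu + sigma_patch z_j; better when patch-level data are weak.
make_hill_logpost <- function(y, log10c, patch, priors, sigma_floor) {
  J <- if (length(patch)) max(patch) else 0L
  n <- length(y)
  pos <- is.finite(log10c)
  ln10 <- log(10)
  lo <- priors$imax_lo; hi <- priors$imax_hi
  ssp <- priors$sigma_patch_scale; sso <- priors$sigma_obs_scale
  function(q) {
    mu <- q[1]; h <- q[2]; li <- q[3]; lsp <- q[4]; lso <- q[5]
    z <- if (J > 0) q[5L + seq_len(J)] else numeric(0)
    pI <- plogis_(li); imax <- lo + (hi - lo) * pI
    sp <- exp(lsp); sof <- exp(lso); so <- sigma_floor + sof
    f <- rep(1, n)
    grad <- numeric(5L + J)
    gI_lik <- 0; gh <- 0; gmu <- 0; gsp <- 0
    if (n > 0) {
      theta <- mu + if (J > 0) sp * z[patch] else 0
      w <- 1 / (1 + 10^(h * (log10c[pos] - theta[pos])))
      f[pos] <- 1 - imax + imax * w
      rp <- ((y - f) / so^2)[pos]
      df_dg <- -imax * w * (1 - w) * ln10    # = -imax u/(1+u)^2 ln10
      common <- rp * df_dg
      gh <- sum(common * (log10c[pos] - theta[pos]))
      t_r <- -h * common                     # d loglik / d theta, per row
      gmu <- sum(t_r)
      if (J > 0) {
        gz <- rep(0, J)
        agg <- tapply(t_r, patch[pos], sum)
        gz[as.integer(names(agg))] <- as.numeric(agg)
        gsp <- sum(t_r * z[patch[pos]])
        grad[5L + seq_len(J)] <- sp * gz
      }
      gI_lik <- sum(rp * (w - 1))
      lp_lik <- -n * log(so) - 0.5 * sum((y - f)^2) / so^2
      dlp_dso <- -n / so + sum((y - f)^2) / so^3
    } else {
      lp_lik <- 0
      dlp_dso <- 0
    }
    lp <- lp_lik -
      0.5 * (mu - priors$ic50_mean)^2 / priors$ic50_sd^2 -
      0.5 * (h - priors$h_mean)^2 / priors$h_sd^2 +
      log(pI * (1 - pI)) -                       # uniform Imax + Jacobian
      0.5 * sp^2 / ssp^2 + lsp -                 # half-normal + Jacobian
      0.5 * sof^2 / sso^2 + lso -
      0.5 * sum(z^2)
    grad[1] <- gmu - (mu - priors$ic50_mean) / priors$ic50_sd^2
    grad[2] <- gh - (h - priors$h_mean) / priors$h_sd^2
    grad[3] <- gI_lik * (hi - lo) * pI * (1 - pI) + (1 - 2 * pI)
    grad[4] <- (gsp - sp / ssp^2) * sp + 1
    grad[5] <- dlp_dso * sof - sof^2 / sso^2 + 1
    if (J > 0) grad[5L + seq_len(J)] <- grad[5L + seq_len(J)] - z
    list(lp = lp, grad = grad)
  }
}

# Gauss-Hermite rule adapted to N(0,1) (Golub-Welsch on the Jacobi matrix):
# nodes z and log weights summing to 1
gauss_hermite_normal <- function(K) {
  off <- sqrt(seq_len(K - 1) / 2)
  J <- matrix(0, K, K)
  J[cbind(seq_len(K - 1), 2:K)] <- off
  J[cbind(2:K, seq_len(K - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(z = sqrt(2) * e$values[ord],
       logw = log(e$vectors[1, ord]^2))
}

# log posterior + gradient for the hierarchical Hill model with the patch
# random effects integrated out by Gauss-Hermite quadrature. Sampling only
# the five population-level parameters (mu, h, li, lsp, lso) removes the
# hierarchical funnel, so NUTS explores the posterior with near-iid
# efficiency; patch-level draws are recovered afterwards by exact conditional
# sampling (hill_patch_conditional_draws).
make_hill_logpost_marginal <- function(y, log10c, patch, priors, sigma_floor,
                                       K = 48L) {
  J <- if (length(patch)) max(patch) else 0L
  n <- length(y)
  pos <- is.finite(log10c)
  n_p <- sum(pos)
  ln10 <- log(10)
  lo <- priors$imax_lo; hi <- priors$imax_hi
  ssp <- priors$sigma_patch_scale; sso <- priors$sigma_obs_scale
  gh <- gauss_hermite_normal(K)
  zk <- gh$z; lwk <- gh$logw
  lc <- log10c[pos]; yp <- y[pos]
  r0 <- y[!pos] - 1                 # zero-concentration residuals
  # patch indicator matrix for segmented row sums
  P <- if (n_p > 0)
    outer(patch[pos], seq_len(J), `==`) * 1 else matrix(0, 0, J)
  function(q) {
    mu <- q[1]; h <- q[2]; li <- q[3]; lsp <- q[4]; lso <- q[5]
    pI <- plogis_(li); imax <- lo + (hi - lo) * pI
    sp <- exp(lsp); sof <- exp(lso); so <- sigma_floor + sof
    lp_prior <- -0.5 * (mu - priors$ic50_mean)^2 / priors$ic50_sd^2 -
      0.5 * (h - priors$h_mean)^2 / priors$h_sd^2 +
      log(pI * (1 - pI)) -
      0.5 * sp^2 / ssp^2 + lsp -
      0.5 * sof^2 / sso^2 + lso
    g_prior <- c(-(mu - priors$ic50_mean) / priors$ic50_sd^2,
                 -(h - priors$h_mean) / priors$h_sd^2,
                 (1 - 2 * pI), -sp^2 / ssp^2 + 1, -sof^2 / sso^2 + 1)
    if (n_p == 0) {
      lp <- lp_prior - n * log(so) -
        (if (length(r0)) 0.5 * sum(r0^2) / so^2 else 0)
      g_prior[5] <- g_prior[5] +
        (-n / so + (if (length(r0)) sum(r0^2) / so^3 else 0)) * sof
      return(list(lp = lp, grad = g_prior))
    }
    theta <- mu + sp * zk                       # K patch-effect nodes
    G <- h * outer(-theta, lc, `+`)             # K x n_p: h (lc - theta)
    W <- 1 / (1 + 10^G)
    f <- 1 - imax + imax * W
    R <- sweep(-f, 2, yp, `+`)                  # residuals y - f
    Q <- (R * R) %*% P                          # K x J within-patch SSR
    A <- lwk - 0.5 * Q / so^2                   # K x J log mixture terms
    amax <- apply(A, 2, max)
    logL <- amax + log(colSums(exp(sweep(A, 2, amax))))
    pw <- exp(sweep(A, 2, logL))                # K x J posterior node weights
    Wt <- pw[, patch[pos], drop = FALSE]
    # row-matched node weights: Wt[k, i] = pw[k, patch(i)]
    df_dg <- -imax * W * (1 - W) * ln10
    df_dth <- -h * df_dg
    WR <- Wt * R / so^2
    g_mu <- sum(WR * df_dth)
    g_h <- sum(WR * df_dg * sweep(-matrix(theta, length(zk), n_p), 2, lc, `+`))
    g_imax <- sum(WR * (W - 1))
    g_sp <- sum((WR * df_dth) * zk)
    ssr0 <- if (length(r0)) sum(r0^2) else 0
    g_so <- -n / so + (sum(Wt * R * R) + ssr0) / so^3
    lp <- lp_prior - n * log(so) - 0.5 * ssr0 / so^2 + sum(logL)
    grad <- g_prior + c(
      g_mu, g_h, g_imax * (hi - lo) * pI * (1 - pI), g_sp * sp, g_so * sof)
    list(lp = lp, grad = grad)
  }
}

# Exact conditional draws of the patch-level log10 IC50 given each retained
# posterior draw of the population parameters: the 1-d conditional density of
# the standardised patch effect is tabulated on a fine grid and sampled by
# inverse CDF with within-cell jitter.
hill_patch_conditional_draws <- function(raw, y, log10c, patch, priors,
                                         sigma_floor, n_grid = 201L,
                                         z_range = 6) {
  J <- max(patch)
  pos <- is.finite(log10c)
  lc <- log10c[pos]; yp <- y[pos]
  P <- outer(patch[pos], seq_len(J), `==`) * 1
  zg <- seq(-z_range, z_range, length.out = n_grid)
  dz <- zg[2] - zg[1]
  lprior <- -0.5 * zg^2
  kept <- dim(raw)[1]; chains <- dim(raw)[2]
  lo <- priors$imax_lo; hi <- priors$imax_hi
  out <- array(NA_real_, c(kept, chains, J))
  for (ch in seq_len(chains)) {
    for (t in seq_len(kept)) {
      mu <- raw[t, ch, 1]; h <- raw[t, ch, 2]
      imax <- lo + (hi - lo) * plogis_(raw[t, ch, 3])
      sp <- exp(raw[t, ch, 4]); so <- sigma_floor + exp(raw[t, ch, 5])
      theta <- mu + sp * zg
      W <- 1 / (1 + 10^(h * outer(-theta, lc, `+`)))
      f <- 1 - imax + imax * W
      R <- sweep(-f, 2, yp, `+`)
      A <- lprior - 0.5 * ((R * R) %*% P) / so^2
      u <- stats::runif(J)
      for (j in seq_len(J)) {
        w <- exp(A[, j] - max(A[, j]))
        cw <- cumsum(w) / sum(w)
        k <- findInterval(u[j], cw) + 1L
        z <- zg[k] + dz * (stats::runif(1) - 0.5)
        out[t, ch, j] <- mu + sp * z
      }
    }
  }
  out
}

#' Fit the hierarchical Bayesian Hill model
#'
#' Mixed-effects dose-response fit: fractional current follows the Hill model
#' of \code{\link{hill_fraction}} with a Gaussian observation model, the
#' population log10 IC50, Hill slope and Imax shared across patches, and the
#' log10 IC50 allowed to vary between individual excised patches
#' (non-centred Normal random effect with an estimated scatter scale).
#' Sampling uses the built-in No-U-Turn sampler
#' (4 chains x 4000 iterations with 2000 burn-in by default, retaining 8000
#' draws). Convergence is checked with split-chain Rhat; a fit with any
#' Rhat > 1.05 is returned flagged (with a warning), never silently.
#'
#' An empty table is accepted and yields a prior-only posterior.
#'
#' @param table data.frame with columns \code{patch}, \code{conc} (molar) and
#'   \code{frac_current}; one construct per call.
#' @param priors a \code{\link{hill_priors}} object.
#' @param chains,iterations,burn_in chain protocol.
#' @param seed integer seed (reproducible draws).
#' @param sigma_floor small additive floor on the observation-noise SD that
#'   keeps zero-noise datasets proper (default 1e-4).
#' @param method \code{"marginal"} (default) integrates the patch effects out
#'   by Gauss-Hermite quadrature and samples the five population parameters
#'   with NUTS, reconstructing patch-level draws by exact conditional
#'   sampling; \code{"joint"} samples the non-centred joint posterior
#'   (population parameters plus standardised patch effects) directly. Both
#'   target the same posterior; marginal mixes with near-iid efficiency.
#' @return A \code{posterior_set} with parameters \code{log10_IC50}, \code{h},
#'   \code{Imax}, \code{sigma_patch}, \code{sigma_obs} and per-patch
#'   \code{log10_IC50[<patch>]}.
#' @export
fit_hill_hierarchical <- function(table, priors = hill_priors(), chains = 4,
                                  iterations = 4000, burn_in = 2000, seed = 1,
                                  sigma_floor = 1e-4,
                                  method = c("marginal", "joint")) {
  stopifnot(inherits(priors, "hill_priors"))
  method <- match.arg(method)
  if (nrow(table) > 0) {
    need <- c("patch", "conc", "frac_current")
    if (!all(need %in% names(table)))
      stop("table must have columns: ", paste(need, collapse = ", "))
    if ("construct" %in% names(table) &&
        length(unique(table$construct)) > 1)
      stop("fit one construct per call; split the table by construct")
    if (anyNA(table$patch)) stop("every row must be assigned a patch")
    if (length(unique(table$conc[table$conc > 0])) < 2)
      stop("non-identifiable input: at least 2 distinct non-zero ",
           "concentrations are required")
    patch_f <- factor(table$patch)
    patch <- as.integer(patch_f)
    patch_ids <- levels(patch_f)
    y <- table$frac_current
    log10c <- ifelse(table$conc > 0, log10(table$conc), -Inf)
  } else {
    patch <- integer(0); patch_ids <- character(0)
    y <- numeric(0); log10c <- numeric(0)
  }
  J <- length(patch_ids)
  marginal <- method == "marginal"
  logpost <- if (marginal)
    make_hill_logpost_marginal(y, log10c, patch, priors, sigma_floor)
  else
    make_hill_logpost(y, log10c, patch, priors, sigma_floor)
  n_par <- if (marginal) 5L else 5L + J
  init <- function(ch) {
    set.seed(seed + 7919L * ch)
    c(priors$ic50_mean + stats::rnorm(1, 0, 0.3),
      priors$h_mean + stats::rnorm(1, 0, 0.1),
      stats::rnorm(1, 1, 0.5), log(0.05) + stats::rnorm(1, 0, 0.2),
      log(0.05) + stats::rnorm(1, 0, 0.2),
      if (!marginal) stats::rnorm(J, 0, 0.2))
  }
  fit <- nuts_sample(logpost, init, n_par, chains, iterations, burn_in,
                     seed, metric = if (marginal) "dense" else "diag")
  raw <- fit$draws
  pn <- c("log10_IC50", "h", "Imax", "sigma_patch", "sigma_obs",
          if (J > 0) paste0("log10_IC50[", patch_ids, "]"))
  out <- array(NA_real_, c(dim(raw)[1], dim(raw)[2], 5L + J),
               dimnames = list(NULL, NULL, pn))
  out[, , 1] <- raw[, , 1]
  out[, , 2] <- raw[, , 2]
  out[, , 3] <- priors$imax_lo +
    (priors$imax_hi - priors$imax_lo) * plogis_(raw[, , 3])
  out[, , 4] <- exp(raw[, , 4])
  out[, , 5] <- sigma_floor + exp(raw[, , 5])
  if (J > 0) {
    if (marginal) {
      set.seed(seed + 104729L)
      out[, , 5L + seq_len(J)] <- hill_patch_conditional_draws(
        raw, y, log10c, patch, priors, sigma_floor)
    } else {
      for (j in seq_len(J))
        out[, , 5L + j] <- raw[, , 1] + exp(raw[, , 4]) * raw[, , 5L + j]
    }
  }
  post <- new_posterior_set(out, meta = list(
    model = "hierarchical_hill", chains = chains, iterations = iterations,
    burn_in = burn_in, seed = seed, n_obs = length(y), n_patches = J,
    n_divergent = sum(fit$n_divergent), priors = priors))
  if (!post$converged)
    warning("fit flagged: split-chain Rhat > 1.05 for at least one parameter")
  post
}

# symbolic gradients of the MWC observables wrt (a = log10 L, k = log10 KA, D)
mwc_occ_deriv <- stats::deriv(
  ~ ((10^(k + lgT)) * (1 + 10^(k + lgT))^3 +
       (10^a) * D * (10^(k + lgT)) * (1 + D * 10^(k + lgT))^3) /
    ((1 + 10^(k + lgT))^4 + (10^a) * (1 + D * 10^(k + lgT))^4),
  c("a", "k", "D"), function.arg = c("a", "k", "D", "lgT"))

mwc_cur_deriv <- stats::deriv(
  ~ ((10^a) * (1 + D * 10^(k + lgT))^4 /
       ((1 + 10^(k + lgT))^4 + (10^a) * (1 + D * 10^(k + lgT))^4)) *
    (1 + 10^a) / (10^a),
  c("a", "k", "D"), function.arg = c("a", "k", "D", "lgT"))

# log posterior + gradient for the joint MWC fit. Parameters:
# (a = log10 L, qk, qd, lsc, lsq) with log10 KA = lo + (hi-lo) plogis(qk),
# D = D_lo + (D_hi-D_lo) plogis(qd), noise SDs = floor + exp(ls*).
make_mwc_logpost <- function(conc, y_cur, y_q, priors, sigma_floor) {
  pos <- conc > 0
  lgT <- log10(conc[pos])
  n <- length(conc)
  klo <- priors$log10KA_lo; khi <- priors$log10KA_hi
  dlo <- priors$D_lo; dhi <- priors$D_hi
  sso <- priors$sigma_obs_scale
  function(q) {
    a <- q[1]
    pk <- plogis_(q[2]); k <- klo + (khi - klo) * pk
    pd <- plogis_(q[3]); D <- dlo + (dhi - dlo) * pd
    scf <- exp(q[4]); sc <- sigma_floor + scf
    sqf <- exp(q[5]); sq <- sigma_floor + sqf
    f_cur <- rep(1, n); f_occ <- rep(0, n)
    g_cur <- g_occ <- matrix(0, n, 3)
    if (any(pos)) {
      oc <- mwc_occ_deriv(a, k, D, lgT)
      cu <- mwc_cur_deriv(a, k, D, lgT)
      f_occ[pos] <- as.numeric(oc)
      f_cur[pos] <- as.numeric(cu)
      g_occ[pos, ] <- attr(oc, "gradient")
      g_cur[pos, ] <- attr(cu, "gradient")
    }
    rc <- (y_cur - f_cur) / sc^2
    rq <- (y_q - f_occ) / sq^2
    # d loglik / d (a, k, D)
    gakd <- colSums(rc * g_cur) + colSums(rq * g_occ)
    lp <- -n * log(sc) - 0.5 * sum((y_cur - f_cur)^2) / sc^2 -
      n * log(sq) - 0.5 * sum((y_q - f_occ)^2) / sq^2 -
      0.5 * (a - priors$log10L_mean)^2 / priors$log10L_sd^2 +
      log(pk * (1 - pk)) + log(pd * (1 - pd)) -
      0.5 * scf^2 / sso^2 + q[4] -
      0.5 * sqf^2 / sso^2 + q[5]
    grad <- c(
      gakd[1] - (a - priors$log10L_mean) / priors$log10L_sd^2,
      gakd[2] * (khi - klo) * pk * (1 - pk) + (1 - 2 * pk),
      gakd[3] * (dhi - dlo) * pd * (1 - pd) + (1 - 2 * pd),
      (-n / sc + sum((y_cur - f_cur)^2) / sc^3) * scf - scf^2 / sso^2 + 1,
      (-n / sq + sum((y_q - f_occ)^2) / sq^3) * sqf - sqf^2 / sso^2 + 1)
    list(lp = lp, grad = grad)
  }
}

#' Jointly fit current inhibition and fluorescence quenching to the MWC model
#'
#' The three equilibrium parameters (L, KA, D) are shared between the two
#' observables: fractional current follows \code{\link{mwc_current}} and
#' fractional quenching follows \code{\link{mwc_occupancy}}, each with its own
#' Gaussian observation-noise SD. Sampling, diagnostics and convergence
#' flagging are as in \code{\link{fit_hill_hierarchical}}.
#'
#' @param table data.frame with columns \code{conc} (molar),
#'   \code{frac_current} and \code{frac_quench}.
#' @inheritParams fit_hill_hierarchical
#' @param priors a \code{\link{mwc_priors}} object.
#' @return A \code{posterior_set} with parameters \code{log10_L},
#'   \code{log10_KA}, \code{D}, \code{sigma_current}, \code{sigma_quench}.
#' @export
fit_mwc_joint <- function(table, priors = mwc_priors(), chains = 4,
                          iterations = 4000, burn_in = 2000, seed = 1,
                          sigma_floor = 1e-4) {
  stopifnot(inherits(priors, "mwc_priors"))
  if (nrow(table) > 0) {
    if (!"frac_quench" %in% names(table) || all(is.na(table$frac_quench)))
      stop("no quenching data: fit current-only data with ",
           "fit_hill_hierarchical()")
    need <- c("conc", "frac_current", "frac_quench")
    if (!all(need %in% names(table)))
      stop("table must have columns: ", paste(need, collapse = ", "))
    ok <- stats::complete.cases(table[, need])
    table <- table[ok, , drop = FALSE]
    if (length(unique(table$conc[table$conc > 0])) < 3)
      stop("joint MWC fit requires both observables at >= 3 concentrations")
    conc <- table$conc; y_cur <- table$frac_current; y_q <- table$frac_quench
  } else {
    conc <- numeric(0); y_cur <- numeric(0); y_q <- numeric(0)
  }
  logpost <- make_mwc_logpost(conc, y_cur, y_q, priors, sigma_floor)
  init <- function(ch) {
    set.seed(seed + 7919L * ch)
    c(priors$log10L_mean + stats::rnorm(1, 0, 0.2),
      stats::rnorm(1, 0, 0.5), stats::rnorm(1, 0, 0.5),
      log(0.05) + stats::rnorm(1, 0, 0.2),
      log(0.05) + stats::rnorm(1, 0, 0.2))
  }
  fit <- nuts_sample(logpost, init, 5L, chains, iterations, burn_in, seed,
                     metric = "dense")
  raw <- fit$draws
  pn <- c("log10_L", "log10_KA", "D", "sigma_current", "sigma_quench")
  out <- array(NA_real_, c(dim(raw)[1], dim(raw)[2], 5L),
               dimnames = list(NULL, NULL, pn))
  out[, , 1] <- raw[, , 1]
  out[, , 2] <- priors$log10KA_lo +
    (priors$log10KA_hi - priors$log10KA_lo) * plogis_(raw[, , 2])
  out[, , 3] <- priors$D_lo + (priors$D_hi - priors$D_lo) * plogis_(raw[, , 3])
  out[, , 4] <- sigma_floor + exp(raw[, , 4])
  out[, , 5] <- sigma_floor + exp(raw[, , 5])
  post <- new_posterior_set(out, meta = list(
    model = "mwc_joint", chains = chains, iterations = iterations,
    burn_in = burn_in, seed = seed, n_obs = length(conc),
    n_divergent = sum(fit$n_divergent), priors = priors))
  if (!post$converged)
    warning("fit flagged: split-chain Rhat > 1.05 for at least one parameter")
  post
}
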