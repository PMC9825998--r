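# Reduced chain protocols keep these fits quick; the full 4 x 4000 protocol
# is exercised in the acceptance tests.

test_that("diagnostics are calibrated on iid draws and detect a shifted chain", {
  set.seed(1)
  draws <- array(rnorm(4 * 1000 * 2), c(1000, 4, 2),
                 dimnames = list(NULL, NULL, c("a", "b")))
  d <- mcmc_diagnostics(draws)
  expect_true(all(abs(d$rhat - 1) < 0.01))
  expect_true(all(d$ess > 0.8 * 4000))
  bad <- draws
  bad[, 2, 1] <- bad[, 2, 1] + 5
  db <- mcmc_diagnostics(bad)
  expect_gt(db$rhat[1], 1.5)
  expect_lt(db$rhat[2], 1.01)
})

test_that("diagnostics reject single chains and tolerate anticorrelation", {
  draws1 <- array(rnorm(100), c(100, 1, 1))
  expect_error(mcmc_diagnostics(draws1), "2 chains")
  # perfectly alternating chain: super-efficient, must not error
  alt <- array(rep(c(-1, 1), 500), c(500, 2, 1),
               dimnames = list(NULL, NULL, "a"))
  d <- mcmc_diagnostics(alt)
  expect_true(is.finite(d$ess))
  expect_gt(d$ess, 1000)
})

test_that("summaries give correct central intervals and nesting", {
  set.seed(2)
  draws <- array(rnorm(8000), c(2000, 4, 1),
                 dimnames = list(NULL, NULL, "x"))
  s <- summarize_posterior(draws)
  expect_equal(s$median, 0, tolerance = 0.05)
  expect_equal(s$lo95, -1.96, tolerance = 0.08)
  expect_equal(s$hi95, 1.96, tolerance = 0.08)
  expect_true(s$lo95 < s$lo80 && s$lo80 < s$lo50)
  expect_true(s$hi50 < s$hi80 && s$hi80 < s$hi95)
})

test_that("fold-change contrasts behave exactly under shifts", {
  set.seed(3)
  draws <- array(rnorm(4000, -4.5, 0.1), c(1000, 4, 1),
                 dimnames = list(NULL, NULL, "log10_IC50"))
  self <- contrast_fold_change(draws, draws)
  expect_equal(self$draws, rep(1, 4000))
  expect_equal(self$summary$median, 1)
  shifted <- draws + 1
  up <- contrast_fold_change(shifted, draws)
  expect_equal(up$draws, rep(10, 4000), tolerance = 1e-12)
  # brute-force paired-subtraction oracle on arbitrary arrays
  a <- array(rnorm(400), c(100, 4, 1), dimnames = list(NULL, NULL, "log10_IC50"))
  b <- array(rnorm(400), c(100, 4, 1), dimnames = list(NULL, NULL, "log10_IC50"))
  fc <- contrast_fold_change(a, b)
  expect_equal(fc$draws, 10^(as.vector(a) - as.vector(b)))
  expect_error(contrast_fold_change(a, b, parameter = "nope"), "not found")
})

test_that("retained draw count is chains * (iterations - burn_in) and seeded", {
  g <- gen_hill_table(-4.5, n_patches = 3, noise_sd = 0.03, seed = 5)
  # such short chains may legitimately trip the Rhat > 1.05 flag
  fit1 <- suppressWarnings(fit_hill_hierarchical(g$table, chains = 2,
                                                 iterations = 300,
                                                 burn_in = 150, seed = 9))
  expect_equal(dim(fit1$draws)[1:2], c(150L, 2L))
  fit2 <- suppressWarnings(fit_hill_hierarchical(g$table, chains = 2,
                                                 iterations = 300,
                                                 burn_in = 150, seed = 9))
  expect_identical(fit1$draws, fit2$draws)
  fit3 <- suppressWarnings(fit_hill_hierarchical(g$table, chains = 2,
                                                 iterations = 300,
                                                 burn_in = 150, seed = 10))
  expect_false(identical(fit1$draws, fit3$draws))
})

test_that("hill fit validates its inputs", {
  g <- gen_hill_table(-4.5, n_patches = 3, concentrations = 1e-5,
                      noise_sd = 0, seed = 1)
  expect_error(fit_hill_hierarchical(g$table), "non-identifiable")
  tab <- gen_hill_table(-4.5, n_patches = 2, seed = 1)$table
  tab$patch[1] <- NA
  expect_error(fit_hill_hierarchical(tab), "patch")
  two <- rbind(transform(tab, construct = "a"),
               transform(tab, construct = "b"))
  two$patch <- rep(c("p1", "p2"), each = nrow(tab))
  expect_error(fit_hill_hierarchical(two), "one construct")
})

test_that("a prior-only hill fit reproduces the priors", {
  empty <- data.frame(patch = character(0), conc = numeric(0),
                      frac_current = numeric(0))
  fit <- fit_hill_hierarchical(empty, chains = 4, iterations = 1500,
                               burn_in = 500, seed = 11)
  s <- summarize_posterior(fit)
  mu <- s[s$param == "log10_IC50", ]
  expect_equal(mu$median, -4, tolerance = 0.1)
  expect_equal(mu$hi95 - mu$lo95, 2 * 1.96, tolerance = 0.25)
  imax <- s[s$param == "Imax", ]
  expect_equal(imax$median, 0.5, tolerance = 0.05)
  expect_equal(imax$lo95, 0.025, tolerance = 0.03)
  expect_equal(imax$hi95, 0.975, tolerance = 0.03)
  h <- s[s$param == "h", ]
  expect_equal(h$median, 1, tolerance = 0.05)
  expect_equal(h$hi95 - h$lo95, 2 * 1.96 * 0.3, tolerance = 0.15)
})

test_that("zero-noise hill data are recovered within 5%", {
  ic50 <- 30e-6
  g <- gen_hill_table(log10(ic50), n_patches = 8, between_patch_sd = 0,
                      noise_sd = 0, seed = 13)
  # zero-noise data: the noise floor is the effective measurement scale
  fit <- fit_hill_hierarchical(g$table, chains = 2, iterations = 800,
                               burn_in = 400, seed = 13, sigma_floor = 0.01)
  s <- summarize_posterior(fit)
  est <- 10^s$median[s$param == "log10_IC50"]
  expect_lt(abs(est - ic50) / ic50, 0.05)
  expect_gt(s$median[s$param == "Imax"], 0.95)
  expect_equal(s$median[s$param == "h"], 1, tolerance = 0.05)
})

test_that("marginalised and joint samplers agree on the same posterior", {
  g <- gen_hill_table(-4.49, n_patches = 6, noise_sd = 0.03, seed = 17)
  fm <- fit_hill_hierarchical(g$table, chains = 4, iterations = 1000,
                              burn_in = 500, seed = 17)
  fj <- fit_hill_hierarchical(g$table, chains = 4, iterations = 1000,
                              burn_in = 500, seed = 17, method = "joint")
  sm <- summarize_posterior(fm); sj <- summarize_posterior(fj)
  for (p in c("log10_IC50", "h", "Imax", "sigma_obs")) {
    expect_equal(sm$median[sm$param == p], sj$median[sj$param == p],
                 tolerance = 0.03)
  }
  # patch-level medians agree too (conditional vs joint sampling)
  pp <- grep("log10_IC50\\[", sm$param)
  expect_equal(sm$median[pp], sj$median[pp], tolerance = 0.03)
})

test_that("per-patch IC50 estimates track the generating patch values", {
  g <- gen_hill_table(-4.5, n_patches = 6, between_patch_sd = 0.15,
                      noise_sd = 0.02, seed = 19)
  fit <- fit_hill_hierarchical(g$table, chains = 2, iterations = 1000,
                               burn_in = 500, seed = 19)
  s <- summarize_posterior(fit)
  est <- s$median[grep("log10_IC50\\[", s$param)]
  expect_gt(cor(est, g$patch_log10_ic50), 0.95)
})

test_that("joint MWC fit recovers zero-noise truth within 10%", {
  truth <- list(L = 1, KA = 1e5, D = 0.1)
  concs <- 10^seq(-7, -3.5, length.out = 8)
  tab <- data.frame(conc = rep(concs, 2))
  tab$frac_current <- mwc_current(tab$conc, truth$L, truth$KA, truth$D)
  tab$frac_quench <- mwc_occupancy(tab$conc, truth$L, truth$KA, truth$D)
  fit <- fit_mwc_joint(tab, chains = 4, iterations = 1000, burn_in = 500,
                       seed = 23, sigma_floor = 0.01)
  s <- summarize_posterior(fit)
  expect_lt(abs(10^s$median[s$param == "log10_L"] - truth$L) / truth$L, 0.10)
  expect_lt(abs(10^s$median[s$param == "log10_KA"] - truth$KA) / truth$KA,
            0.10)
  expect_lt(abs(s$median[s$param == "D"] - truth$D), 0.05)
})

test_that("D = 1 data push the posterior for D to its upper bound", {
  concs <- 10^seq(-7, -4, length.out = 8)
  tab <- data.frame(conc = concs,
                    frac_current = mwc_current(concs, 1, 1e5, 1),
                    frac_quench = mwc_occupancy(concs, 1, 1e5, 1))
  expect_true(all(tab$frac_current == 1))   # current uninformative at D = 1
  fit <- fit_mwc_joint(tab, chains = 2, iterations = 1000, burn_in = 500,
                       seed = 29, sigma_floor = 0.01)
  s <- summarize_posterior(fit)
  expect_gt(s$median[s$param == "D"], 0.9)
})

test_that("a prior-only MWC fit reproduces the uniform prior on D", {
  empty <- data.frame(conc = numeric(0), frac_current = numeric(0),
                      frac_quench = numeric(0))
  fit <- fit_mwc_joint(empty, chains = 4, iterations = 1500, burn_in = 500,
                       seed = 31)
  s <- summarize_posterior(fit)
  d <- s[s$param == "D", ]
  expect_equal(d$median, 0.5, tolerance = 0.05)
  expect_equal(d$lo95, 0.025, tolerance = 0.03)
  expect_equal(d$hi95, 0.975, tolerance = 0.03)
  ka <- s[s$param == "log10_KA", ]
  expect_equal(ka$median, 4, tolerance = 0.15)
})

test_that("MWC fit demands quenching data and enough concentrations", {
  tab <- data.frame(conc = c(1e-6, 1e-5), frac_current = c(0.9, 0.5))
  expect_error(fit_mwc_joint(tab), "fit_hill_hierarchical")
  tab$frac_quench <- c(0.1, 0.5)
  expect_error(fit_mwc_joint(tab), "3 concentrations")
})
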