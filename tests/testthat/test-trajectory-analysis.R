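test_that("min_distance_series returns exact distances and honours windows", {
  tr <- make_toy_traj(list(rbind(c(0, 0, 0), c(3, 0, 0)),
                           rbind(c(0, 0, 0), c(0, 4, 0))))
  d <- min_distance_series(tr, 1, 2)
  expect_equal(d$dist, c(3, 4))
  expect_equal(d$time, c(1, 2))
  expect_error(min_distance_series(tr, 1, 1), "disjoint")
  expect_error(min_distance_series(tr, integer(0), 2), "empty")
})

test_that("min_distance_series equals the brute-force pair scan and skips H", {
  set.seed(4)
  nf <- 6
  coords <- replicate(nf, matrix(rnorm(8 * 3, sd = 5), 8, 3),
                      simplify = FALSE)
  elements <- c("C", "H", "N", "O", "C", "H", "S", "C")
  tr <- make_toy_traj(coords, elements = elements)
  sel_a <- 1:4; sel_b <- 5:8
  d <- min_distance_series(tr, sel_a, sel_b)
  heavy_a <- sel_a[elements[sel_a] != "H"]
  heavy_b <- sel_b[elements[sel_b] != "H"]
  for (f in seq_len(nf))
    expect_equal(d$dist[f],
                 oracle_min_dist(coords[[f]][heavy_a, , drop = FALSE],
                                 coords[[f]][heavy_b, , drop = FALSE]))
})

test_that("running_average block means behave on constants, ramps, identity", {
  t10 <- seq(0.1, 2, by = 0.1)
  expect_equal(running_average(t10, rep(3, 20), window = 1)$value, c(3, 3))
  # linear ramp: block means equal midpoint values
  ramp <- running_average(t10, t10, window = 1)
  expect_equal(ramp$value, c(mean(t10[1:10]), mean(t10[11:20])))
  # single-frame blocks: identity
  ident <- running_average(t10, sin(t10), window = 0.1)
  expect_equal(ident$value, sin(t10))
  expect_error(running_average(t10, t10, window = 0.01), "frame spacing")
})

test_that("sliding running average averages the centred window", {
  t5 <- 1:5
  v <- c(1, 2, 3, 4, 5)
  sl <- running_average(t5, v, window = 2, sliding = TRUE)
  expect_equal(sl$value, c(1.5, 2, 3, 4, 4.5))
})

test_that("analysis window keeps exactly the frames with t > discard", {
  # 380 ns fixture at 1 ns spacing: final-300-ns analysis keeps t = 81..380
  cfg <- switch_config(n_frames = 380, dt = 1, p_stay_site1 = 1,
                       p_stay_site2 = 0.5, noise_sigma = 0, n_subunits = 1,
                       n_repeats = 1, seed = 1)
  tr <- gen_switch_trajectory(cfg, start_state = 1)$trajectories[[1]]
  occ <- contact_occupancy(tr, 39, "ligand_ATP", discard_ns = 80)
  expect_equal(occ$n_frames, 300)
  d <- min_distance_series(tr, list(role = "protein"),
                           list(role = "ligand_ATP"), discard_ns = 80)
  expect_equal(min(d$time), 81)
  expect_equal(nrow(d), 300)
})

test_that("contact boundary is strictly below the cutoff", {
  # mobile atom exactly at 4.0 A from the ligand: not a contact
  atoms <- data.frame(eleno = 1:2, elety = c("NZ", "PG"),
                      element = c("N", "P"), resno = c(39L, 501L),
                      resid = c("LYS", "ATP"), chain = "A",
                      role = c("protein", "ligand_ATP"))
  xyz <- array(0, c(2, 2, 3))
  xyz[1, 1, 1] <- 4.0; xyz[2, 1, 1] <- 3.999999
  tr <- trajectory_ensemble(atoms, xyz, times = 1:2)
  occ <- contact_occupancy(tr, 39, "ligand_ATP", cutoff = 4, discard_ns = 0)
  expect_equal(occ$occupancy, 0.5)
})

test_that("contact occupancy recovers the Markov stationary probability", {
  ps <- c(0.92, 0.85)
  cfg <- switch_config(n_frames = 3000, dt = 0.1, p_stay_site1 = ps[1],
                       p_stay_site2 = ps[2], noise_sigma = 0.4,
                       n_subunits = 4, n_repeats = 3, seed = 21)
  out <- gen_switch_trajectory(cfg)
  prof <- contact_profile(out$trajectories, 39, "ligand_ATP",
                          discard_ns = 0)
  expect_equal(nrow(prof), 12)
  pi1 <- oracle_stationary_p1(ps[1], ps[2])
  se <- oracle_markov_se(ps[1], ps[2],
                         cfg$n_frames * cfg$n_subunits * cfg$n_repeats)
  expect_lt(abs(mean(prof$occupancy) - pi1), 3 * se)
})

test_that("contacting_residues applies a strict 0.4 threshold", {
  prof <- data.frame(resno = rep(c(10L, 11L, 12L), each = 2),
                     occupancy = c(0.41, 0.41, 0.40, 0.40, 0, 0))
  expect_equal(contacting_residues(prof), 10L)
  expect_length(contacting_residues(data.frame(resno = 1:3,
                                               occupancy = c(0, 0, 0))), 0)
  # brute-force filter oracle on a random profile
  set.seed(2)
  rp <- data.frame(resno = rep(1:20, each = 12),
                   occupancy = runif(240))
  means <- tapply(rp$occupancy, rp$resno, mean)
  expect_equal(contacting_residues(rp, 0.5),
               sort(as.integer(names(means)[means > 0.5])))
})

test_that("per_subunit_table yields 12 points per residue and sane CIs", {
  cfg <- switch_config(n_frames = 100, seed = 31)
  out <- gen_switch_trajectory(cfg)
  prof <- contact_profile(out$trajectories, 39, "ligand_ATP", discard_ns = 0)
  tab <- per_subunit_table(prof)
  expect_equal(nrow(tab$points), 12)
  expect_equal(tab$summary$n, 12)
  expect_true(tab$summary$ci_lo <= tab$summary$mean)
  expect_true(tab$summary$ci_hi >= tab$summary$mean)
  # single subunit, single repeat: one row; identical values: zero-width CI
  one <- data.frame(resno = 39L, chain = "A", occupancy = 0.5, n_frames = 10,
                    repeat_id = 1L, ligand = "ligand_ATP")
  t1 <- per_subunit_table(one)
  expect_equal(nrow(t1$points), 1)
  const <- do.call(rbind, replicate(12, one, simplify = FALSE))
  expect_equal(per_subunit_table(const)$summary$ci_lo, 0.5)
  expect_equal(per_subunit_table(const)$summary$ci_hi, 0.5)
  # mismatched residue sets across repeats are reported
  bad <- rbind(one, transform(one, resno = 40L, repeat_id = 2L))
  expect_error(per_subunit_table(bad), "40")
})

test_that("rmsf is zero for static coordinates and errors on one frame", {
  M <- matrix(rnorm(30), 10, 3)
  tr <- make_toy_traj(list(M, M, M))
  out <- rmsf(tr, 1:10)
  expect_equal(out$rmsf, rep(0, 10), tolerance = 1e-12)
  tr1 <- make_toy_traj(list(M))
  expect_error(rmsf(tr1, 1:10), "2 frames")
})

test_that("rmsf of isotropic jitter approaches sigma * sqrt(3)", {
  set.seed(8)
  base <- matrix(rnorm(40 * 3, sd = 10), 40, 3)
  sigma <- 0.7
  frames <- lapply(1:1000, function(i) base + matrix(rnorm(120, 0, sigma),
                                                     40, 3))
  tr <- make_toy_traj(frames, dt = 0.01)
  out <- rmsf(tr, 1:40)
  expect_equal(mean(out$rmsf), sigma * sqrt(3), tolerance = 0.05)
})

test_that("rmsf without fitting matches the direct definition on small arrays", {
  set.seed(12)
  coords <- replicate(5, matrix(rnorm(9), 3, 3), simplify = FALSE)
  tr <- make_toy_traj(coords)
  out <- rmsf(tr, 1:3, fit = FALSE)
  X <- simplify2array(coords)              # 3 atoms x 3 coords x 5 frames
  direct <- sapply(1:3, function(a) {
    M <- t(X[a, , ])                       # frames x coords
    dev <- sweep(M, 2, colMeans(M))
    sqrt(mean(rowSums(dev^2)))
  })
  expect_equal(out$rmsf[order(out$resno)], direct, tolerance = 1e-12)
})

test_that("pairwise_rmsd is zero for identical or rigidly moved frames", {
  set.seed(5)
  M <- matrix(rnorm(60), 20, 3)
  tr <- make_toy_traj(list(M, M, apply_rigid(M)))
  R <- pairwise_rmsd(tr, 1:20)
  expect_equal(max(abs(R)), 0, tolerance = 1e-8)
  expect_equal(R, t(R))
  expect_equal(diag(R), rep(0, 3), ignore_attr = TRUE)
})

test_that("pairwise_rmsd matches the bio3d superposition oracle to 1e-6", {
  set.seed(6)
  M <- matrix(rnorm(45), 15, 3)
  frames <- list(M, M + matrix(rnorm(45, 0, 0.6), 15, 3),
                 apply_rigid(M + matrix(rnorm(45, 0, 0.3), 15, 3)),
                 matrix(rnorm(45), 15, 3))
  tr <- make_toy_traj(frames)
  R <- pairwise_rmsd(tr, 1:15)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(R[i, j], oracle_rmsd_bio3d(frames[[i]], frames[[j]]),
                 tolerance = 1e-6)
  expect_error(pairwise_rmsd(make_toy_traj(frames[1]), 1:15), "2 frames")
})

test_that("compare_groups matches the pooled-variance t-test", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  cmp <- compare_groups(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(cmp$t, unname(ref$statistic))
  expect_equal(cmp$p, ref$p.value)
  expect_equal(cmp$df, unname(ref$parameter))
  expect_equal(cmp$ci, unname(ref$conf.int), ignore_attr = TRUE)
  expect_false(cmp$significant)
  # swapping groups negates t and preserves p
  rev <- compare_groups(b, a)
  expect_equal(rev$t, -cmp$t)
  expect_equal(rev$p, cmp$p)
})

test_that("compare_groups handles degenerate inputs as defined", {
  same <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ident <- compare_groups(c(1, 5, 9), c(1, 5, 9))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("hbond distributions match the oracle and sum to one", {
  set.seed(10)
  counts <- sample(0:3, 60, replace = TRUE)
  out <- gen_hbond_frames(60, list(list(capacity = 3, counts = counts)),
                          seed = 13)
  dist <- hbond_count_distribution(out$trajectory, out$criteria,
                                   donor_type = "lysine")
  expect_equal(sum(dist), 1, tolerance = 1e-12)
  expect_equal(unname(dist), as.numeric(tabulate(counts + 1L, 4) / 60))
  # arginine-like capacity reports k = 0..5
  out5 <- gen_hbond_frames(20, list(list(capacity = 5, counts = 4)),
                           seed = 14)
  d5 <- hbond_count_distribution(out5$trajectory, out5$criteria,
                                 donor_type = "arginine")
  expect_length(d5, 6)
  expect_equal(unname(d5["4"]), 1)
})

test_that("hbond counting errors on missing hydrogens and empty windows", {
  out <- gen_hbond_frames(5, list(list(capacity = 2, counts = 1)), seed = 2)
  bad <- hbond_criterion(donor = out$criteria[[1]]$donor,
                         hydrogen = list(elety = "HX9"),
                         acceptor = out$criteria[[1]]$acceptor)
  expect_error(hbond_count_series(out$trajectory, bad), "hydrogen")
  expect_error(hbond_count_distribution(out$trajectory, out$criteria,
                                        k_max = 0), "capacity")
  expect_error(hbond_criterion(1, 2, 3, dist_cutoff = -1), "positive")
  expect_error(hbond_criterion(1, 2, 3, angle_cutoff = 200), "angle")
})

test_that("trajectories round-trip through multi-model PDB", {
  cfg <- switch_config(n_frames = 4, n_subunits = 2, n_repeats = 1, seed = 3)
  tr <- gen_switch_trajectory(cfg)$trajectories[[1]]
  path <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, path)
  back <- read_trajectory_pdb(path, times = tr$times)
  expect_equal(dim(back$xyz), dim(tr$xyz))
  expect_equal(back$xyz, tr$xyz, tolerance = 1e-3)   # PDB: 3 decimals
  expect_equal(back$atoms$role, tr$atoms$role)
  expect_equal(back$atoms$chain, tr$atoms$chain)
  unlink(path)
})

test_that("select_atoms composes filters conjunctively", {
  cfg <- switch_config(n_frames = 2, n_subunits = 2, n_repeats = 1, seed = 1)
  tr <- gen_switch_trajectory(cfg)$trajectories[[1]]
  expect_length(select_atoms(tr, chain = "A", role = "protein"), 1)
  expect_length(select_atoms(tr, role = c("ligand_ATP", "ligand_PIP2")), 4)
  expect_length(select_atoms(tr, chain = "Z"), 0)
})
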