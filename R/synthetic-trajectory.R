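#' Configuration for the two-site Markov switch fixture
#'
#' Describes a toy trajectory in which one mobile "side-chain" particle per
#' subunit hops between two ligand sites (an ATP-like site and a PIP2-like
#' site) under a two-state Markov chain with isotropic Gaussian positional
#' noise, emulating a lysine side-chain oscillating between coordination with
#' ATP and PIP2. Static ligand pseudo-atoms mark each site centre.
#'
#' @param n_frames frames per repeat (>= 1).
#' @param dt frame spacing in ns (default 0.1).
#' @param p_stay_site1,p_stay_site2 Markov self-transition probabilities in
#'   \code{[0, 1]}.
#' @param site1_center,site2_center 3-vectors (Angstrom); must be distinct.
#'   Site 1 is the ATP site, site 2 the PIP2 site.
#' @param noise_sigma isotropic positional noise SD, Angstrom (>= 0).
#' @param n_subunits subunits (chains) per trajectory (default 4).
#' @param n_repeats independent repeat trajectories (default 3).
#' @param seed integer seed.
#' @return validated config list of class \code{"switch_config"}.
#' @export
switch_config <- function(n_frames, dt = 0.1, p_stay_site1 = 0.9,
                          p_stay_site2 = 0.9,
                          site1_center = c(0, 0, 0),
                          site2_center = c(12, 0, 0),
                          noise_sigma = 0.5, n_subunits = 4, n_repeats = 3,
                          seed = 1) {
  stopifnot(n_frames >= 1, dt > 0, n_subunits >= 1, n_repeats >= 1)
  if (p_stay_site1 < 0 || p_stay_site1 > 1 || p_stay_site2 < 0 ||
      p_stay_site2 > 1)
    stop("self-transition probabilities must lie in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (length(site1_center) != 3 || length(site2_center) != 3)
    stop("site centers must be 3-vectors")
  if (all(site1_center == site2_center)) stop("site centers must be distinct")
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 p_stay_site1 = p_stay_site1, p_stay_site2 = p_stay_site2,
                 site1_center = site1_center, site2_center = site2_center,
                 noise_sigma = noise_sigma, n_subunits = as.integer(n_subunits),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "switch_config")
}

#' Stationary site-1 probability of the two-state switch chain
#'
#' \code{(1 - p22) / ((1 - p11) + (1 - p22))}; undefined (error) when both
#' self-transition probabilities are 1.
#'
#' @param p_stay_site1,p_stay_site2 self-transition probabilities.
#' @return stationary probability of occupying site 1.
#' @export
switch_stationary_p1 <- function(p_stay_site1, p_stay_site2) {
  denom <- (1 - p_stay_site1) + (1 - p_stay_site2)
  if (denom == 0)
    stop("degenerate chain: both self-transition probabilities are 1")
  (1 - p_stay_site2) / denom
}

#' Generate two-site Markov switch trajectories
#'
#' One labelled trajectory ensemble per repeat. Per subunit: a mobile
#' side-chain nitrogen (residue 39) whose position follows the Markov chain
#' over the two site centres plus Gaussian noise, and one static ligand
#' pseudo-atom at each site centre (roles \code{ligand_ATP} for site 1,
#' \code{ligand_PIP2} for site 2). Subunits are spatially separated so that
#' per-chain analyses are independent. Output is deterministic given the
#' config seed.
#'
#' @param cfg a \code{\link{switch_config}}.
#' @param start_state initial state per subunit: 1, 2, or NULL to draw from
#'   the stationary distribution. Required when both self-transition
#'   probabilities are 1 (the chain is degenerate and has no stationary
#'   start).
#' @return list with \code{trajectories} (list of
#'   \code{\link{trajectory_ensemble}}, one per repeat) and \code{states}
#'   (list of \code{[n_frames x n_subunits]} integer matrices of true site
#'   labels, for oracle checks).
#' @export
gen_switch_trajectory <- function(cfg, start_state = NULL) {
  stopifnot(inherits(cfg, "switch_config"))
  degenerate <- cfg$p_stay_site1 == 1 && cfg$p_stay_site2 == 1
  if (degenerate && is.null(start_state))
    stop("degenerate chain (both self-transition probabilities are 1): ",
         "an explicit start_state is required")
  set.seed(cfg$seed)
  chains <- LETTERS[seq_len(cfg$n_subunits)]
  spacing <- 4 * max(sqrt(sum((cfg$site1_center - cfg$site2_center)^2)), 10)
  atoms <- do.call(rbind, lapply(seq_len(cfg$n_subunits), function(s) {
    data.frame(
      eleno = (s - 1L) * 3L + 1:3,
      elety = c("NZ", "PG", "P5"),
      element = c("N", "P", "P"),
      resno = c(39L, 501L, 601L),
      resid = c("LYS", "ATP", "PIP"),
      chain = chains[s],
      role = c("protein", "ligand_ATP", "ligand_PIP2"),
      stringsAsFactors = FALSE)
  }))
  centers <- rbind(cfg$site1_center, cfg$site2_center)
  p_stay <- c(cfg$p_stay_site1, cfg$p_stay_site2)
  trajectories <- vector("list", cfg$n_repeats)
  states <- vector("list", cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    st <- matrix(NA_integer_, cfg$n_frames, cfg$n_subunits)
    xyz <- array(NA_real_, c(cfg$n_frames, nrow(atoms), 3))
    for (s in seq_len(cfg$n_subunits)) {
      off <- c(0, (s - 1) * spacing, 0)
      s0 <- if (!is.null(start_state)) start_state else
        if (stats::runif(1) < switch_stationary_p1(cfg$p_stay_site1,
                                                   cfg$p_stay_site2)) 1L else 2L
      cur <- as.integer(s0)
      for (f in seq_len(cfg$n_frames)) {
        if (f > 1L)
          cur <- if (stats::runif(1) < p_stay[cur]) cur else 3L - cur
        st[f, s] <- cur
        mobile <- centers[cur, ] + off +
          stats::rnorm(3, 0, cfg$noise_sigma)
        base <- (s - 1L) * 3L
        xyz[f, base + 1L, ] <- mobile
        xyz[f, base + 2L, ] <- cfg$site1_center + off
        xyz[f, base + 3L, ] <- cfg$site2_center + off
      }
    }
    trajectories[[r]] <- trajectory_ensemble(atoms, xyz,
                                             times = cfg$dt * seq_len(cfg$n_frames))
    states[[r]] <- st
  }
  list(trajectories = trajectories, states = states)
}

# five donor-H directions with pairwise angles >= 90 degrees, so an active
# acceptor on one axis can never satisfy the 30-degree criterion of another
hbond_directions <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                          c(0, 0, 1))

#' Generate hydrogen-bond geometry fixtures with known per-frame counts
#'
#' Each bond spec describes one donor group (a lysine-like or arginine-like
#' side chain) with a geometric capacity and a target bond count per frame.
#' Donor-hydrogen-acceptor triplets are placed so that exactly the target
#' number satisfy the default detection criterion (donor-acceptor 3.0
#' Angstrom, in-line hydrogen) before jitter; inactive acceptors sit at 5.0
#' Angstrom on the same axis. True counts are returned for oracle checks.
#'
#' @param n_frames number of frames.
#' @param bond_specs list of specs, each a list with \code{capacity} (1-5
#'   hydrogens/acceptor sites) and \code{counts} (scalar or length
#'   \code{n_frames} vector of target bond counts, each <= capacity).
#' @param jitter Gaussian positional noise SD (Angstrom) applied to all
#'   coordinates after placement (default 0).
#' @param seed integer seed.
#' @param dt frame spacing in ns.
#' @return list with \code{trajectory}, \code{true_counts} (matrix
#'   \code{[n_frames x n_specs]}), and \code{criteria} (list of matching
#'   \code{\link{hbond_criterion}} objects, one per spec).
#' @export
gen_hbond_frames <- function(n_frames, bond_specs, jitter = 0, seed = 1,
                             dt = 0.1) {
  stopifnot(n_frames >= 1, length(bond_specs) >= 1, jitter >= 0)
  set.seed(as.integer(seed))
  chains <- LETTERS[seq_along(bond_specs)]
  atoms_list <- list(); eleno <- 0L
  layout <- list()
  for (i in seq_along(bond_specs)) {
    sp <- bond_specs[[i]]
    cap <- as.integer(sp$capacity)
    if (is.na(cap) || cap < 1L || cap > 5L)
      stop("bond spec ", i, ": capacity must be in 1..5")
    counts <- rep_len(as.integer(sp$counts), n_frames)
    if (any(counts < 0) || any(counts > cap))
      stop("infeasible geometry: spec ", i, " requests up to ",
           max(counts), " bonds but the acceptor layout supports ", cap)
    origin <- c(0, 0, (i - 1) * 30)
    don <- eleno + 1L
    hyd <- eleno + 1L + seq_len(cap)
    acc <- eleno + 1L + cap + seq_len(cap)
    atoms_list[[i]] <- data.frame(
      eleno = eleno + seq_len(1L + 2L * cap),
      elety = c("NZ", paste0("HZ", seq_len(cap)), paste0("O", seq_len(cap))),
      element = c("N", rep("H", cap), rep("O", cap)),
      resno = c(rep(39L + i, 1L + cap), rep(601L, cap)),
      resid = c(rep(if (cap > 3) "ARG" else "LYS", 1L + cap),
                rep("PIP", cap)),
      chain = chains[i],
      role = c(rep("protein", 1L + cap), rep("ligand_PIP2", cap)),
      stringsAsFactors = FALSE)
    layout[[i]] <- list(origin = origin, cap = cap, counts = counts,
                        don = don, hyd = hyd, acc = acc)
    eleno <- eleno + 1L + 2L * cap
  }
  atoms <- do.call(rbind, atoms_list)
  n_atoms <- nrow(atoms)
  xyz <- array(NA_real_, c(n_frames, n_atoms, 3))
  true_counts <- matrix(NA_integer_, n_frames,
                        length(bond_specs))
  for (f in seq_len(n_frames)) {
    for (i in seq_along(layout)) {
      lo <- layout[[i]]
      xyz[f, lo$don, ] <- lo$origin
      for (b in seq_len(lo$cap)) {
        u <- hbond_directions[b, ]
        xyz[f, lo$hyd[b], ] <- lo$origin + 1.0 * u
        d <- if (b <= lo$counts[f]) 3.0 else 5.0
        xyz[f, lo$acc[b], ] <- lo$origin + d * u
      }
      true_counts[f, i] <- lo$counts[f]
    }
  }
  if (jitter > 0)
    xyz <- xyz + array(stats::rnorm(length(xyz), 0, jitter), dim(xyz))
  traj <- trajectory_ensemble(atoms, xyz, times = dt * seq_len(n_frames))
  criteria <- lapply(seq_along(layout), function(i) {
    hbond_criterion(donor = layout[[i]]$don, hydrogen = layout[[i]]$hyd,
                    acceptor = layout[[i]]$acc)
  })
  list(trajectory = traj, true_counts = true_counts, criteria = criteria)
}
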