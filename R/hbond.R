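#' Geometric hydrogen-bond criterion
#'
#' A hydrogen bond is detected when the donor-acceptor distance is at most
#' \code{dist_cutoff} and the hydrogen-donor-acceptor angle (vertex at the
#' donor) is at most \code{angle_cutoff}. Defaults (3.5 Angstrom, 30 degrees)
#' follow the common MD-analysis convention; both are configurable.
#'
#' @param donor selection for the single donor heavy atom (indices or a list
#'   of \code{\link{select_atoms}} arguments).
#' @param hydrogen selection for hydrogen(s) bonded to the donor.
#' @param acceptor selection for candidate acceptor heavy atoms.
#' @param dist_cutoff donor-acceptor distance cutoff, Angstrom (> 0).
#' @param angle_cutoff H-donor-acceptor angle cutoff, degrees (0, 180].
#' @return object of class \code{"hbond_criterion"}.
#' @export
hbond_criterion <- function(donor, hydrogen, acceptor, dist_cutoff = 3.5,
                            angle_cutoff = 30) {
  if (dist_cutoff <= 0) stop("dist_cutoff must be positive")
  if (angle_cutoff <= 0 || angle_cutoff > 180)
    stop("angle_cutoff must be in (0, 180] degrees")
  structure(list(donor = donor, hydrogen = hydrogen, acceptor = acceptor,
                 dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criterion")
}

# Count satisfied (hydrogen, acceptor) pairs for one criterion in one frame.
hbond_count_frame <- function(xyz_frame, di, hi, ai, dist_cutoff,
                              angle_cutoff) {
  D <- xyz_frame[di, ]
  count <- 0L
  for (a in ai) {
    A <- xyz_frame[a, ]
    v_da <- A - D
    dda <- sqrt(sum(v_da^2))
    if (dda > dist_cutoff || dda == 0) next
    for (h in hi) {
      v_dh <- xyz_frame[h, ] - D
      cosang <- sum(v_dh * v_da) / (sqrt(sum(v_dh^2)) * dda)
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang <= angle_cutoff) count <- count + 1L
    }
  }
  count
}

#' Per-frame hydrogen-bond counts
#'
#' Total number of satisfied criteria (counting each qualifying
#' hydrogen-acceptor pair) in every analysis-window frame.
#'
#' @param traj A \code{\link{trajectory_ensemble}}.
#' @param criteria a single \code{\link{hbond_criterion}} or a list of them.
#' @param discard_ns,window analysis window (default: all frames).
#' @return data.frame with columns \code{time} and \code{count}.
#' @export
hbond_count_series <- function(traj, criteria, discard_ns = 0, window = NULL) {
  if (inherits(criteria, "hbond_criterion")) criteria <- list(criteria)
  frames <- window_frames(traj, discard_ns, window)
  if (!length(frames)) stop("empty analysis window")
  resolved <- lapply(criteria, function(cr) {
    di <- resolve_selection(traj, cr$donor, "donor")
    if (length(di) != 1L) stop("donor selection must resolve to a single atom")
    hi <- if (is.list(cr$hydrogen)) do.call(select_atoms, c(list(traj), cr$hydrogen)) else as.integer(cr$hydrogen)
    if (!length(hi)) stop("missing hydrogen atom for donor (atom ", di, ")")
    ai <- resolve_selection(traj, cr$acceptor, "acceptor")
    list(di = di, hi = hi, ai = ai, dc = cr$dist_cutoff, ac = cr$angle_cutoff)
  })
  counts <- vapply(frames, function(f) {
    xyz_frame <- traj$xyz[f, , , drop = FALSE]
    dim(xyz_frame) <- dim(traj$xyz)[2:3]
    sum(vapply(resolved, function(r)
      hbond_count_frame(xyz_frame, r$di, r$hi, r$ai, r$dc, r$ac), integer(1)))
  }, integer(1))
  data.frame(time = traj$times[frames], count = counts)
}

#' Hydrogen-bond count distribution
#'
#' Fraction of analysis-window frames in which k hydrogen bonds are formed,
#' for k = 0..k_max. The default capacity reflects side-chain chemistry: a
#' lysine ammonium group can donate at most 3 bonds, an arginine guanidinium
#' up to 5.
#'
#' @inheritParams hbond_count_series
#' @param donor_type \code{"lysine"} (k_max 3) or \code{"arginine"} (k_max 5);
#'   ignored when \code{k_max} is given.
#' @param k_max explicit maximum bond count.
#' @return named numeric vector of fractions for k = 0..k_max, summing to 1.
#' @export
hbond_count_distribution <- function(traj, criteria,
                                     donor_type = c("lysine", "arginine"),
                                     k_max = NULL, discard_ns = 0,
                                     window = NULL) {
  if (is.null(k_max)) {
    donor_type <- match.arg(donor_type)
    k_max <- if (donor_type == "lysine") 3L else 5L
  }
  ser <- hbond_count_series(traj, criteria, discard_ns, window)
  if (any(ser$count > k_max))
    stop("observed H-bond count ", max(ser$count),
         " exceeds donor capacity k_max = ", k_max)
  frac <- tabulate(ser$count + 1L, nbins = k_max + 1L) / nrow(ser)
  names(frac) <- 0:k_max
  frac
}
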