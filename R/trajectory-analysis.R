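#' @noRd
resolve_selection <- function(traj, sel, name = "selection") {
  idx <- if (is.list(sel)) do.call(select_atoms, c(list(traj), sel)) else as.integer(sel)
  if (length(idx) == 0L) stop("empty atom selection: ", name)
  if (any(idx < 1L | idx > nrow(traj$atoms))) stop("atom index out of range in ", name)
  idx
}

# frames retained by the analysis window: t > discard_ns, or an explicit
# [t_min, t_max] range
window_frames <- function(traj, discard_ns = 0, window = NULL) {
  t <- traj$times
  keep <- if (!is.null(window)) t >= window[1] & t <= window[2] else t > discard_ns
  which(keep)
}

#' Per-frame minimum heavy-atom distance between two selections
#'
#' For every frame in the analysis window, the minimum over all A-B heavy-atom
#' pairs of the Euclidean distance. Hydrogens are excluded; the two selections
#' must be disjoint.
#'
#' @param traj A \code{\link{trajectory_ensemble}}.
#' @param sel_a,sel_b atom selections: integer index vectors, or lists of
#'   arguments to \code{\link{select_atoms}}.
#' @param discard_ns drop frames with time <= this many ns (default 0).
#' @param window optional explicit time range \code{c(t_min, t_max)} in ns,
#'   overriding \code{discard_ns}.
#' @return data.frame with columns \code{time} (ns) and \code{dist} (Angstrom).
#' @export
min_distance_series <- function(traj, sel_a, sel_b, discard_ns = 0,
                                window = NULL) {
  ia <- resolve_selection(traj, sel_a, "sel_a")
  ib <- resolve_selection(traj, sel_b, "sel_b")
  ia <- ia[traj$atoms$element[ia] != "H"]
  ib <- ib[traj$atoms$element[ib] != "H"]
  if (!length(ia)) stop("sel_a contains no heavy atoms")
  if (!length(ib)) stop("sel_b contains no heavy atoms")
  if (length(intersect(ia, ib))) stop("sel_a and sel_b must be disjoint")
  frames <- window_frames(traj, discard_ns, window)
  if (!length(frames)) stop("empty analysis window")
  d <- vapply(frames, function(f) {
    A <- traj$xyz[f, ia, , drop = FALSE]; dim(A) <- c(length(ia), 3)
    B <- traj$xyz[f, ib, , drop = FALSE]; dim(B) <- c(length(ib), 3)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  data.frame(time = traj$times[frames], dist = d)
}

#' Block or sliding running average of a time series
#'
#' Default behaviour averages over non-overlapping blocks of \code{window} ns
#' with timestamps at block centres (partial trailing blocks are kept). With
#' \code{sliding = TRUE} a centred moving average of full width \code{window}
#' is returned on the original time base.
#'
#' @param times sample times in ns, strictly increasing.
#' @param values sample values.
#' @param window averaging window in ns (default 1); must be at least the
#'   frame spacing.
#' @param sliding use a centred sliding window instead of block means.
#' @return data.frame with columns \code{time} and \code{value}.
#' @export
running_average <- function(times, values, window = 1, sliding = FALSE) {
  stopifnot(length(times) == length(values), length(times) >= 1)
  if (length(times) > 1 && window < min(diff(times)))
    stop("window (", window, " ns) is shorter than the frame spacing")
  if (sliding) {
    half <- window / 2
    v <- vapply(times, function(t0)
      mean(values[times >= t0 - half & times <= t0 + half]), numeric(1))
    return(data.frame(time = times, value = v))
  }
  t0 <- times[1]
  block <- floor((times - t0) / window + 1e-9)
  agg_v <- tapply(values, block, mean)
  agg_t <- t0 + (as.numeric(names(agg_v)) + 0.5) * window
  data.frame(time = unname(agg_t), value = unname(agg_v))
}

# Assign each ligand residue (role, chain, resno) to a protein subunit chain.
# Ligands sharing a chain id with a protein chain are assigned directly;
# otherwise the ligand goes to the chain whose reference residues it most
# frequently contacts (<cutoff) across the analysed frames.
assign_ligand_chains <- function(traj, ligand_role, ref_resno, frames,
                                 cutoff = 4) {
  a <- traj$atoms
  prot_chains <- unique(a$chain[a$role == "protein"])
  lig <- which(a$role == ligand_role & a$element != "H")
  if (!length(lig)) stop("no atoms with role '", ligand_role, "' present")
  key <- paste(a$chain[lig], a$resno[lig], sep = ":")
  out <- list()
  for (k in unique(key)) {
    idx <- lig[key == k]
    lig_chain <- a$chain[idx[1]]
    if (lig_chain %in% prot_chains) {
      out[[k]] <- list(atoms = idx, chain = lig_chain)
      next
    }
    hits <- vapply(prot_chains, function(ch) {
      res_idx <- select_atoms(traj, chain = ch, resno = ref_resno,
                              role = "protein", heavy = TRUE)
      if (!length(res_idx)) return(0)
      sum(vapply(frames, function(f) {
        A <- traj$xyz[f, res_idx, , drop = FALSE]; dim(A) <- c(length(res_idx), 3)
        B <- traj$xyz[f, idx, , drop = FALSE]; dim(B) <- c(length(idx), 3)
        d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
        min(d2) < cutoff^2
      }, logical(1)))
    }, numeric(1))
    out[[k]] <- list(atoms = idx, chain = prot_chains[which.max(hits)])
  }
  out
}

#' Ligand contact occupancy per residue and subunit
#'
#' Fraction of analysis-window frames in which the minimum heavy-atom distance
#' between a residue and its subunit's ligand is strictly below the cutoff.
#' Computed per subunit (each Kir-like subunit of the tetramer is treated as a
#' separate data point).
#'
#' @param traj A \code{\link{trajectory_ensemble}}.
#' @param resno residue number(s) to profile.
#' @param ligand_role \code{"ligand_ATP"} or \code{"ligand_PIP2"}.
#' @param cutoff contact distance cutoff in Angstrom (default 4; strict \code{<}).
#' @param discard_ns equilibration time to discard (default 80 ns; frames with
#'   \code{t > discard_ns} are analysed).
#' @param window optional explicit \code{c(t_min, t_max)} window.
#' @return data.frame with columns \code{resno}, \code{chain},
#'   \code{occupancy} and \code{n_frames}.
#' @export
contact_occupancy <- function(traj, resno, ligand_role, cutoff = 4,
                              discard_ns = 80, window = NULL) {
  frames <- window_frames(traj, discard_ns, window)
  if (!length(frames)) stop("empty analysis window")
  lig <- assign_ligand_chains(traj, ligand_role, resno, frames, cutoff)
  lig_by_chain <- split(
    unlist(lapply(lig, `[[`, "atoms")),
    rep(vapply(lig, `[[`, "", "chain"), vapply(lig, function(l) length(l$atoms), 0L)))
  rows <- list()
  for (ch in names(lig_by_chain)) {
    lidx <- lig_by_chain[[ch]]
    for (rn in resno) {
      ridx <- select_atoms(traj, chain = ch, resno = rn, role = "protein",
                           heavy = TRUE)
      if (!length(ridx)) next
      inside <- vapply(frames, function(f) {
        A <- traj$xyz[f, ridx, , drop = FALSE]; dim(A) <- c(length(ridx), 3)
        B <- traj$xyz[f, lidx, , drop = FALSE]; dim(B) <- c(length(lidx), 3)
        d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
        min(d2) < cutoff^2
      }, logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        resno = rn, chain = ch, occupancy = mean(inside),
        n_frames = length(frames))
    }
  }
  if (!length(rows)) stop("no matching residue/ligand atoms for occupancy")
  do.call(rbind, rows)
}

#' Contact occupancy profile across repeat simulations
#'
#' Runs \code{\link{contact_occupancy}} on each repeat trajectory and stacks
#' the per-residue, per-subunit occupancies into one long table (the
#' "12 data points" layout for 4 subunits x 3 repeats).
#'
#' @param trajs list of \code{\link{trajectory_ensemble}} objects (repeats).
#' @inheritParams contact_occupancy
#' @return data.frame with columns \code{resno}, \code{chain}, \code{repeat_id},
#'   \code{ligand}, \code{occupancy}, \code{n_frames}.
#' @export
contact_profile <- function(trajs, resno, ligand_role, cutoff = 4,
                            discard_ns = 80, window = NULL) {
  stopifnot(length(trajs) >= 1)
  out <- lapply(seq_along(trajs), function(r) {
    occ <- contact_occupancy(trajs[[r]], resno, ligand_role, cutoff,
                             discard_ns, window)
    occ$repeat_id <- r
    occ$ligand <- ligand_role
    occ
  })
  do.call(rbind, out)
}

#' Contacting residues above an occupancy threshold
#'
#' Residues whose mean occupancy across all (subunit x repeat) data points
#' strictly exceeds the threshold.
#'
#' @param profile a contact profile from \code{\link{contact_profile}} (or any
#'   data.frame with \code{resno} and \code{occupancy} columns).
#' @param threshold occupancy threshold (default 0.4; strict \code{>}).
#' @return sorted vector of retained residue numbers.
#' @export
contacting_residues <- function(profile, threshold = 0.4) {
  stopifnot(nrow(profile) > 0)
  m <- tapply(profile$occupancy, profile$resno, mean)
  sort(as.integer(names(m)[m > threshold]))
}

#' Per-subunit data-point table with residue summaries
#'
#' Long table of one row per (residue, subunit, repeat) occupancy point, plus
#' a per-residue summary (mean and 95\% t-based confidence interval across the
#' points). With 4 subunits and 3 repeats this yields 12 points per residue.
#'
#' @param profile output of \code{\link{contact_profile}}.
#' @return list with elements \code{points} (long table) and \code{summary}
#'   (per-residue mean, \code{ci_lo}, \code{ci_hi}, \code{n}).
#' @export
per_subunit_table <- function(profile) {
  stopifnot(nrow(profile) > 0)
  sets <- tapply(profile$resno, profile$repeat_id, function(r) sort(unique(r)))
  ref <- sets[[1]]
  for (i in seq_along(sets)) {
    if (!identical(sets[[i]], ref)) {
      diffs <- union(setdiff(sets[[i]], ref), setdiff(ref, sets[[i]]))
      stop("residue sets differ across repeats; mismatched residue(s): ",
           paste(diffs, collapse = ", "))
    }
  }
  summ <- do.call(rbind, lapply(split(profile, profile$resno), function(d) {
    n <- nrow(d); m <- mean(d$occupancy)
    hw <- if (n > 1 && stats::sd(d$occupancy) > 0)
      stats::qt(0.975, n - 1) * stats::sd(d$occupancy) / sqrt(n) else 0
    data.frame(resno = d$resno[1], mean = m, ci_lo = m - hw, ci_hi = m + hw,
               n = n)
  }))
  rownames(summ) <- NULL
  list(points = profile, summary = summ)
}

# Optimal rigid-body superposition (Kabsch, SVD). Returns `moving` rotated and
# translated onto `ref`; both n x 3 with matched rows.
kabsch_fit <- function(moving, ref) {
  cm <- colMeans(moving); cr <- colMeans(ref)
  P <- sweep(moving, 2, cm); Q <- sweep(ref, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(P %*% t(R), 2, cr, "+")
}

#' Per-residue root-mean-square fluctuation
#'
#' Each frame in the analysis window is superposed onto the window-mean
#' structure (least-squares fit over the same selection, removing global
#' rigid-body motion), then the RMSF of each selected atom about its mean
#' position is computed and averaged per residue.
#'
#' @param traj A \code{\link{trajectory_ensemble}}.
#' @param sel atom selection (indices or \code{\link{select_atoms}} argument
#'   list); hydrogens are dropped.
#' @param discard_ns,window analysis window (as in
#'   \code{\link{contact_occupancy}}, default no discard).
#' @param fit superpose frames before computing fluctuations (default TRUE).
#' @return data.frame with columns \code{chain}, \code{resno}, \code{rmsf}
#'   (Angstrom).
#' @export
rmsf <- function(traj, sel, discard_ns = 0, window = NULL, fit = TRUE) {
  idx <- resolve_selection(traj, sel, "sel")
  idx <- idx[traj$atoms$element[idx] != "H"]
  frames <- window_frames(traj, discard_ns, window)
  if (length(frames) < 2) stop("RMSF requires at least 2 frames in the window")
  coords <- lapply(frames, function(f) {
    M <- traj$xyz[f, idx, , drop = FALSE]; dim(M) <- c(length(idx), 3); M
  })
  if (fit) {
    ref <- coords[[1]]
    fitted <- lapply(coords, kabsch_fit, ref = ref)
    mref <- Reduce(`+`, fitted) / length(fitted)
    coords <- lapply(coords, kabsch_fit, ref = mref)
  }
  mpos <- Reduce(`+`, coords) / length(coords)
  msd <- Reduce(`+`, lapply(coords, function(M) rowSums((M - mpos)^2))) /
    length(coords)
  atom_rmsf <- sqrt(msd)
  grp <- paste(traj$atoms$chain[idx], traj$atoms$resno[idx], sep = ":")
  agg <- tapply(atom_rmsf, grp, mean)
  parts <- strsplit(names(agg), ":", fixed = TRUE)
  out <- data.frame(chain = vapply(parts, `[`, "", 1),
                    resno = as.integer(vapply(parts, `[`, "", 2)),
                    rmsf = unname(agg))
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Pairwise RMSD matrix with optimal superposition
#'
#' For every pair of (strided) frames, the moving frame is superposed onto the
#' other by least-squares rigid-body fit (Kabsch) over the selection and the
#' RMSD is computed. The result is symmetric with a zero diagonal and is
#' invariant to global rigid motion of any frame.
#'
#' @param traj A \code{\link{trajectory_ensemble}}.
#' @param sel atom selection (typically C-alpha equivalents).
#' @param stride keep every \code{stride}-th frame of the window (default 1).
#' @param discard_ns,window analysis window (default none discarded).
#' @return numeric matrix (Angstrom) with frame times as dimnames.
#' @export
pairwise_rmsd <- function(traj, sel, stride = 1, discard_ns = 0,
                          window = NULL) {
  stopifnot(stride >= 1)
  idx <- resolve_selection(traj, sel, "sel")
  frames <- window_frames(traj, discard_ns, window)
  frames <- frames[seq(1, length(frames), by = stride)]
  if (length(frames) < 2) stop("pairwise RMSD requires at least 2 frames")
  coords <- lapply(frames, function(f) {
    M <- traj$xyz[f, idx, , drop = FALSE]; dim(M) <- c(length(idx), 3); M
  })
  nf <- length(frames)
  out <- matrix(0, nf, nf,
                dimnames = list(traj$times[frames], traj$times[frames]))
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      fitted <- kabsch_fit(coords[[j]], coords[[i]])
      r <- sqrt(mean(rowSums((fitted - coords[[i]])^2)))
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

#' Unpaired two-sample comparison (pooled-variance t test)
#'
#' Classical Student's unpaired t-test (equal variances pooled), two-sided,
#' with the 95\% confidence interval of the mean difference and a significance
#' flag at p < 0.01. The degenerate case of two constant, identical groups is
#' defined as t = 0, p = 1.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return object of class \code{"group_comparison"}: list with
#'   \code{mean_diff}, \code{t}, \code{df}, \code{p}, \code{ci} (95\%),
#'   \code{n} (per group), \code{significant}.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  md <- mean(a) - mean(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    tt <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
    ci <- c(md, md)
  } else {
    tt <- md / se
    p <- 2 * stats::pt(-abs(tt), df)
    ci <- md + c(-1, 1) * stats::qt(0.975, df) * se
  }
  structure(list(mean_diff = md, t = tt, df = df, p = p, ci = ci,
                 n = c(n1, n2), significant = p < 0.01),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Unpaired t-test: diff = %.4g, t(%d) = %.3f, p = %.3g%s\n",
              x$mean_diff, x$df, x$t, x$p,
              if (x$significant) " (**P < 0.01)" else ""))
  cat(sprintf("  95%% CI of difference: [%.4g, %.4g]; n = %d vs %d\n",
              x$ci[1], x$ci[2], x$n[1], x$n[2]))
  invisible(x)
}
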