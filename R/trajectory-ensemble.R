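#' Labelled trajectory ensemble
#'
#' A light-weight container for an ensemble of frames over a fixed set of
#' labelled atoms: an atom table, per-frame coordinates in Angstrom and frame
#' times in nanoseconds. Every atom carries a role distinguishing protein
#' atoms from ATP and PIP2 ligand atoms, which drives the contact and H-bond
#' analyses.
#'
#' @param atoms data.frame with columns \code{eleno} (atom id), \code{elety}
#'   (atom name), \code{element}, \code{resno}, \code{resid} (residue name),
#'   \code{chain} (subunit id) and \code{role} (one of \code{"protein"},
#'   \code{"ligand_ATP"}, \code{"ligand_PIP2"}).
#' @param xyz numeric array \code{[n_frames, n_atoms, 3]}, coordinates in
#'   Angstrom.
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @return An object of class \code{"traj_ensemble"}.
#' @export
trajectory_ensemble <- function(atoms, xyz, times) {
  atoms <- as.data.frame(atoms)
  need <- c("eleno", "elety", "element", "resno", "resid", "chain", "role")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(atoms$role %in% c("protein", "ligand_ATP", "ligand_PIP2")))
    stop("atom roles must be 'protein', 'ligand_ATP' or 'ligand_PIP2'")
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    stop("xyz must be an [n_frames, n_atoms, 3] array")
  if (dim(xyz)[2] != nrow(atoms))
    stop("xyz atom dimension (", dim(xyz)[2], ") does not match atom table (",
         nrow(atoms), ")")
  times <- as.numeric(times)
  if (length(times) != dim(xyz)[1])
    stop("length(times) must equal the number of frames")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(atoms = atoms, xyz = xyz, times = times),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat("<traj_ensemble> ", dim(x$xyz)[1], " frames x ", nrow(x$atoms),
      " atoms, t = ", format(min(x$times)), "..", format(max(x$times)),
      " ns\n", sep = "")
  cat("  chains: ", paste(unique(x$atoms$chain), collapse = " "),
      " | roles: ", paste(names(table(x$atoms$role)), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

n_frames <- function(traj) dim(traj$xyz)[1]

#' Select atoms of a trajectory ensemble
#'
#' Minimal selection grammar: each non-NULL argument restricts the selection
#' (conjunction). Values may be vectors (disjunction within a field).
#'
#' @param traj A \code{\link{trajectory_ensemble}}.
#' @param chain,resno,resid,elety,element,role optional filters on the
#'   corresponding atom-table columns.
#' @param heavy if TRUE, drop hydrogens (element \code{"H"}).
#' @return Integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(traj, chain = NULL, resno = NULL, resid = NULL,
                         elety = NULL, element = NULL, role = NULL,
                         heavy = FALSE) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  if (!is.null(resno))   keep <- keep & a$resno %in% resno
  if (!is.null(resid))   keep <- keep & a$resid %in% resid
  if (!is.null(elety))   keep <- keep & a$elety %in% elety
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(role))    keep <- keep & a$role %in% role
  if (heavy)             keep <- keep & a$element != "H"
  which(keep)
}

#' Write a trajectory ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; chain IDs carry the subunit labels and
#' ligand atoms are written as HETATM records with residue names \code{ATP}
#' and \code{PIP}. Coordinates are in Angstrom. PDB carries no time axis, so
#' frame times are not stored; supply them again on reading.
#'
#' @param traj A \code{\link{trajectory_ensemble}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$atoms
  rec <- ifelse(a$role == "protein", "ATOM  ", "HETATM")
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf("%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, a$eleno, substr(a$elety, 1, 4), substr(a$resid, 1, 3),
                     substr(as.character(a$chain), 1, 1), a$resno,
                     traj$xyz[f, , 1], traj$xyz[f, , 2], traj$xyz[f, , 3],
                     1.00, 0.00, a$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory ensemble
#'
#' Parsing is delegated to \code{bio3d::read.pdb}. Atom roles are assigned
#' from residue names: \code{ATP} -> \code{ligand_ATP}, \code{PIP}/\code{PIP2}
#' -> \code{ligand_PIP2}, all else protein.
#'
#' @param path PDB file with MODEL/ENDMDL records.
#' @param times frame times in ns; if NULL, \code{dt * (0:(n-1))}.
#' @param dt frame spacing in ns (default 1) when \code{times} is NULL.
#' @return A \code{\link{trajectory_ensemble}}.
#' @export
read_trajectory_pdb <- function(path, times = NULL, dt = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  role <- ifelse(at$resid == "ATP", "ligand_ATP",
                 ifelse(at$resid %in% c("PIP", "PIP2"), "ligand_PIP2",
                        "protein"))
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1, 1)
  atoms <- data.frame(eleno = at$eleno, elety = trimws(at$elety),
                      element = trimws(elem), resno = at$resno,
                      resid = trimws(at$resid), chain = at$chain, role = role,
                      stringsAsFactors = FALSE)
  xyz_mat <- pdb$xyz                        # [n_frames, 3 * n_atoms]
  if (is.null(dim(xyz_mat))) xyz_mat <- matrix(xyz_mat, nrow = 1)
  nf <- nrow(xyz_mat); na <- nrow(atoms)
  xyz <- array(NA_real_, c(nf, na, 3))
  for (k in 1:3) xyz[, , k] <- xyz_mat[, seq(k, 3 * na, by = 3), drop = FALSE]
  if (is.null(times)) times <- dt * (seq_len(nf) - 1)
  trajectory_ensemble(atoms, xyz, times)
}
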