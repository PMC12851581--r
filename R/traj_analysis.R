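#' Construct a trajectory object
#'
#' A lightweight in-memory trajectory: a topology table plus a coordinate
#' array. Coordinates are Angstrom; frames are assumed imaged/whole (no
#' periodic reconstruction is performed).
#'
#' @param topology data frame with columns \code{resno}, \code{resname},
#'   \code{name} (atom name), \code{element}, \code{role} (one of
#'   \code{"protein"}, \code{"ligand"}, \code{"water"}, \code{"other"}).
#' @param coords numeric array of dim \code{c(n_atoms, 3, n_frames)}.
#' @param replica replica id (integer).
#' @param state state label.
#' @return an object of class \code{trajectory}.
#' @export
trajectory <- function(topology, coords, replica = 1L, state = "apo") {
  topology <- as.data.frame(topology, stringsAsFactors = FALSE)
  need <- c("resno", "resname", "name", "element", "role")
  stopifnot(all(need %in% names(topology)))
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(topology))
    stop("coords atom count (", dim(coords)[1],
         ") != topology rows (", nrow(topology), ")")
  if (dim(coords)[3] < 1L) stop("trajectory needs >= 1 frame")
  structure(list(topology = topology, coords = coords,
                 replica = as.integer(replica), state = as.character(state)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", dim(x$coords)[1], "atoms x", dim(x$coords)[3],
      "frames; state", x$state, "replica", x$replica, "\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Resolve the four-atom-pair water-site rule against a topology
#'
#' The binding-site criterion is defined by four heavy-atom pairs between
#' the sugar and its coordinating residues; by default (melibiose in the
#' sugar-binding site): (ligand O5, Gln372 NE2), (ligand O5, Thr373 OG1),
#' (ligand O6, Gln372 NE2), (ligand O6, Thr373 OG1). Each selector must
#' match exactly one atom; missing or ambiguous selectors fail loudly.
#'
#' @param topology a trajectory topology data frame (or a
#'   \code{trajectory}).
#' @param pairs list of character pairs; each selector is
#'   \code{"<role>:<atom name>"} for ligand atoms or
#'   \code{"<resno>:<atom name>"} for protein atoms. Default the four-pair
#'   melibiose rule with Gln372/Thr373.
#' @param outer,inner distance cutoffs in Angstrom: both pair distances must
#'   be within \code{outer} (<= 4.0) and at least one below \code{inner}
#'   (< 3.5).
#' @return object of class \code{pair_rule}: list with \code{pairs} (list of
#'   length-2 atom-index vectors), \code{outer}, \code{inner},
#'   \code{labels}.
#' @export
resolve_pairs <- function(topology,
                          pairs = list(c("ligand:O5", "372:NE2"),
                                       c("ligand:O5", "373:OG1"),
                                       c("ligand:O6", "372:NE2"),
                                       c("ligand:O6", "373:OG1")),
                          outer = 4.0, inner = 3.5) {
  if (inherits(topology, "trajectory")) topology <- topology$topology
  if (inner > outer) stop("inner cutoff must be <= outer cutoff")
  find_atom <- function(sel) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("bad selector: ", sel)
    idx <- if (parts[1] == "ligand")
      which(topology$role == "ligand" & topology$name == parts[2])
    else
      which(topology$role == "protein" &
            topology$resno == as.integer(parts[1]) &
            topology$name == parts[2])
    if (length(idx) == 0L) stop("selector matches no atom: ", sel)
    if (length(idx) > 1L) stop("ambiguous selector (", length(idx),
                               " matches): ", sel)
    idx
  }
  resolved <- lapply(pairs, function(p) c(find_atom(p[1]), find_atom(p[2])))
  structure(list(pairs = resolved, outer = outer, inner = inner,
                 labels = vapply(pairs, paste, "", collapse = "--")),
            class = "pair_rule")
}

pair_dist <- function(w, ref, box = NULL) {
  dv <- sweep(w, 2, ref)
  if (!is.null(box))  # minimum image, orthorhombic box
    dv <- dv - sweep(round(sweep(dv, 2, box, "/")), 2, box, "*")
  sqrt(rowSums(dv^2))
}

occupancy_one_frame <- function(xyz, rule, wat_idx, box = NULL) {
  # xyz: n_atoms x 3 for one frame; returns indices of occupying water oxygens
  if (length(wat_idx) == 0L) return(integer(0))
  w <- xyz[wat_idx, , drop = FALSE]
  occ <- rep(FALSE, length(wat_idx))
  for (p in rule$pairs) {
    d1 <- pair_dist(w, xyz[p[1], ], box)
    d2 <- pair_dist(w, xyz[p[2], ], box)
    occ <- occ | (d1 <= rule$outer & d2 <= rule$outer &
                  (d1 < rule$inner | d2 < rule$inner))
  }
  wat_idx[occ]
}

#' Water occupancy of the binding site across trajectories
#'
#' Per frame, a water oxygen occupies the site iff for at least one of the
#' rule's atom pairs both member distances are within the outer cutoff
#' (<= 4.0 A by default) and at least one is below the inner cutoff
#' (< 3.5 A). The occupancy is the fraction of frames with >= 1 occupying
#' water, pooled over all frames of all replicas; per-replica fractions are
#' also reported.
#'
#' @param trajs a \code{trajectory} or list of trajectories (replicas).
#' @param rule a \code{pair_rule} from \code{\link{resolve_pairs}}; if
#'   \code{NULL}, resolved with defaults against the first trajectory.
#' @param stride analyze every \code{stride}-th frame (default 1).
#' @param box optional orthorhombic box lengths (Angstrom, length 3) for
#'   minimum-image distances; \code{NULL} (default) assumes whole, imaged
#'   input.
#' @return list: \code{occupancy} (pooled fraction), \code{per_frame}
#'   (logical vector over pooled frames), \code{per_replica} (named
#'   fractions), \code{occupying_waters} (list of water atom indices per
#'   frame), \code{n_frames}.
#' @export
water_site_occupancy <- function(trajs, rule = NULL, stride = 1L,
                                 box = NULL) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  if (is.null(rule)) rule <- resolve_pairs(trajs[[1]])
  flags <- logical(0); waters <- list(); per_rep <- numeric(0)
  for (tr in trajs) {
    wat_idx <- which(tr$topology$role == "water" &
                     toupper(tr$topology$element) == "O")
    if (length(wat_idx) == 0L)
      warning("trajectory (state ", tr$state, ", replica ", tr$replica,
              ") has no water oxygens; contributes zero occupancy")
    fr <- seq(1L, n_frames(tr), by = stride)
    ff <- logical(length(fr))
    for (k in seq_along(fr)) {
      ids <- occupancy_one_frame(tr$coords[, , fr[k]], rule, wat_idx, box)
      ff[k] <- length(ids) > 0L
      waters[[length(waters) + 1L]] <- ids
    }
    flags <- c(flags, ff)
    per_rep <- c(per_rep, stats::setNames(mean(ff), paste0(tr$state, "_rep",
                                                           tr$replica)))
  }
  list(occupancy = mean(flags), per_frame = flags, per_replica = per_rep,
       occupying_waters = waters, n_frames = length(flags))
}

#' Side-chain heavy-atom RMSF per residue
#'
#' Frames are rigid-body fitted to the time-averaged structure over the fit
#' selection (default Calpha; the mean is refined by one fit-average
#' iteration), then per residue
#' \deqn{RMSF = \sqrt{ mean_{frames, atoms}\, |x - \bar x|^2 }}
#' over side-chain heavy atoms (backbone N, CA, C, O and hydrogens
#' excluded). Glycine has no side-chain heavy atom and is flagged absent.
#'
#' @param traj a \code{trajectory} (>= 2 frames; a single frame yields RMSF 0
#'   with a warning).
#' @param fit_selection atom names used for the fit (default \code{"CA"});
#'   \code{NULL} skips fitting (frames already aligned).
#' @return data frame: \code{resno}, \code{resname}, \code{rmsf} (Angstrom;
#'   NA where no side-chain heavy atoms), \code{n_atoms}, \code{replica},
#'   \code{state}.
#' @export
sidechain_rmsf <- function(traj, fit_selection = "CA") {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  co <- traj$coords
  nf <- dim(co)[3]
  if (nf < 2L) warning("single-frame trajectory; RMSF is 0 by construction")
  if (!is.null(fit_selection)) {
    fi <- which(top$role == "protein" & top$name %in% fit_selection)
    if (length(fi) < 3L) stop("fit selection has < 3 atoms")
    # fit all frames to frame 1 on the selection, then refit to the mean
    for (pass in 1:2) {
      ref <- if (pass == 1) co[fi, , 1, drop = FALSE][, , 1]
             else apply(co[fi, , , drop = FALSE], c(1, 2), mean)
      for (k in seq_len(nf)) {
        f <- kabsch_fit(ref, co[fi, , k])
        co[, , k] <- sweep(co[, , k] %*% t(f$rotation), 2, f$translation, "+")
      }
    }
  }
  backbone <- c("N", "CA", "C", "O", "OXT")
  sc <- top$role == "protein" & !(top$name %in% backbone) &
    !(toupper(top$element) %in% c("H", "D"))
  mean_xyz <- apply(co, c(1, 2), mean)
  dev2 <- sweep(co, c(1, 2), mean_xyz)^2
  msf_atom <- apply(dev2, 1, mean) * 3  # mean over (3, nf) of squared dev, per axis summed
  res <- unique(top[top$role == "protein", c("resno", "resname")])
  rmsf <- vapply(seq_len(nrow(res)), function(i) {
    idx <- which(sc & top$resno == res$resno[i])
    if (length(idx) == 0L) return(NA_real_)
    sqrt(mean(msf_atom[idx]))
  }, numeric(1))
  n_at <- vapply(res$resno, function(r) sum(sc & top$resno == r), integer(1))
  data.frame(resno = res$resno, resname = res$resname, rmsf = rmsf,
             n_atoms = n_at, replica = traj$replica, state = traj$state,
             stringsAsFactors = FALSE)
}

#' Compare per-residue side-chain RMSF between two states across replicas
#'
#' Per residue, an unpaired two-sided Welch t-test on the replica RMSF
#' values of the two states (n = number of replicas per state).
#'
#' @param apo,holo data frames of \code{\link{sidechain_rmsf}} rows pooled
#'   over replicas (>= 2 replicas per state).
#' @return data frame: \code{resno}, \code{mean_apo}, \code{mean_holo},
#'   \code{t_stat}, \code{p_value}.
#' @export
compare_states <- function(apo, holo) {
  shared <- intersect(unique(apo$resno), unique(holo$resno))
  out <- lapply(sort(shared), function(r) {
    xa <- apo$rmsf[apo$resno == r]; xh <- holo$rmsf[holo$resno == r]
    xa <- xa[!is.na(xa)]; xh <- xh[!is.na(xh)]
    if (length(xa) < 2L || length(xh) < 2L)
      return(data.frame(resno = r, mean_apo = mean(xa), mean_holo = mean(xh),
                        t_stat = NA_real_, p_value = NA_real_))
    w <- welch_t_test(xa, xh)
    data.frame(resno = r, mean_apo = mean(xa), mean_holo = mean(xh),
               t_stat = w$t_stat, p_value = w$p_value)
  })
  do.call(rbind, out)
}

#' Write a trajectory as a multi-model PDB
#'
#' Baseline interchange format so toy trajectories can be inspected with
#' standard viewers and re-read with \code{\link{read_trajectory_pdb}}.
#'
#' @param traj a \code{trajectory}.
#' @param file output path.
#' @export
write_trajectory_pdb <- function(traj, file) {
  top <- traj$topology
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   state %s replica %d", traj$state,
                     traj$replica), con)
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- traj$coords[, , k]
    rectype <- ifelse(top$role == "protein", "ATOM  ", "HETATM")
    writeLines(sprintf(
      "%s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rectype, seq_len(nrow(top)),
      substr(top$name, 1, 4), substr(top$resname, 1, 3), "A", top$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, top$element), con)
    writeLines("ENDMDL", con)
  }
  invisible(NULL)
}

#' Read a multi-model PDB as a trajectory
#'
#' @param file multi-model PDB path.
#' @param state,replica labels attached to the result.
#' @return a \code{trajectory}; roles are inferred from residue names
#'   (waters by name, \code{MEL}/\code{NPG}/\code{LIG} and other HETATM
#'   non-water residues as ligand).
#' @export
read_trajectory_pdb <- function(file, state = "apo", replica = 1L) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  a <- pdb$atom
  role <- ifelse(is_water(a$resid), "water",
                 ifelse(a$type == "ATOM", "protein", "ligand"))
  top <- data.frame(resno = a$resno, resname = a$resid, name = a$elety,
                    element = ifelse(is.na(a$elesy) | a$elesy == "",
                                     toupper(substr(a$elety, 1, 1)), a$elesy),
                    role = role, stringsAsFactors = FALSE)
  nf <- nrow(pdb$xyz)
  na <- nrow(a)
  co <- array(0, dim = c(na, 3, nf))
  for (k in seq_len(nf))
    co[, , k] <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
  trajectory(top, co, replica = replica, state = state)
}
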