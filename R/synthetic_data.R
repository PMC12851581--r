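#' Random protein sequence
#'
#' Uniform draw over the 20 canonical amino acids; proline probability can
#' be lowered since prolines remove exchangeable amides.
#'
#' @param n length.
#' @param seed RNG seed.
#' @param identifier sequence name.
#' @return a \code{protein_sequence}.
#' @export
random_protein <- function(n, seed = 1L, identifier = "synthetic") {
  set.seed(seed)
  protein_sequence(identifier, sample(AA1, n, replace = TRUE))
}

#' Generate an overlapping peptide digestion map
#'
#' Emulates a proteolytic peptide map: peptide starts advance by a random
#' step smaller than the typical peptide length, producing overlaps, with
#' lengths drawn around \code{mean_length}. Deterministic per seed.
#'
#' @param protein a \code{protein_sequence}.
#' @param mean_length mean peptide length (>= 2).
#' @param length_sd spread of lengths.
#' @param overlap_depth target mean number of peptides covering a position;
#'   the start step is \code{mean_length / overlap_depth}.
#' @param seed RNG seed.
#' @return data frame \code{start}, \code{end}, \code{sequence}.
#' @export
make_digestion_map <- function(protein, mean_length = 12, length_sd = 3,
                               overlap_depth = 2, seed = 1L) {
  stopifnot(inherits(protein, "protein_sequence"), mean_length >= 2)
  np <- length(protein)
  if (mean_length > np) {
    warning("mean peptide length exceeds protein length; emitting one full-length peptide")
    return(data.frame(start = 1L, end = np, sequence = subseq(protein, 1, np),
                      stringsAsFactors = FALSE))
  }
  set.seed(seed)
  step <- max(1, round(mean_length / overlap_depth))
  starts <- integer(0); ends <- integer(0)
  s <- 1L
  while (s <= np - 1L) {
    len <- max(2L, min(np - s + 1L,
                       round(stats::rnorm(1, mean_length, length_sd))))
    starts <- c(starts, s); ends <- c(ends, s + len - 1L)
    s <- s + max(1L, stats::rpois(1, step))
  }
  # guarantee the C-terminus is reachable by at least one peptide
  if (max(ends) < np) {
    starts <- c(starts, max(2L, np - as.integer(mean_length) + 1L))
    ends <- c(ends, np)
  }
  keep <- !duplicated(paste(starts, ends))
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(start = starts, end = ends,
             sequence = vapply(seq_along(starts),
                               function(i) subseq(protein, starts[i], ends[i]),
                               ""),
             stringsAsFactors = FALSE)
}

#' Define a first-order hydrogen-exchange model
#'
#' Per-residue intrinsic rate and protection factor; a residue's exchange
#' follows \code{uptake(t) = labeling_fraction * (1 - exp(-k_int * t / P))}.
#' No EX1/EX2 distinction is modeled: the statistics downstream see only
#' uptake values.
#'
#' @param protein a \code{protein_sequence}.
#' @param k_int intrinsic exchange rate, 1/s; scalar or per-residue vector.
#' @param protection per-residue protection factors (P >= 1); scalar
#'   recycled.
#' @param labeling_fraction deuterium fraction of the labeling buffer
#'   (default 0.9, a 10-fold dilution into deuterated buffer).
#' @return list of class \code{exchange_model}.
#' @export
exchange_model <- function(protein, k_int = 1, protection = 1000,
                           labeling_fraction = 0.9) {
  stopifnot(inherits(protein, "protein_sequence"))
  np <- length(protein)
  k_int <- rep_len(k_int, np); protection <- rep_len(protection, np)
  stopifnot(all(k_int > 0), all(protection >= 1),
            labeling_fraction > 0, labeling_fraction <= 1)
  structure(list(protein = protein, k_int = k_int, protection = protection,
                 labeling_fraction = labeling_fraction),
            class = "exchange_model")
}

# exchangeable residue positions of a peptide: all but the first residue,
# prolines excluded
exchangeable_positions <- function(protein, start, end) {
  pos <- (start + 1L):end
  if (start + 1L > end) return(integer(0))
  pos[protein$residues[pos] != "P"]
}

#' Noiseless peptide uptake under an exchange model
#'
#' @param model an \code{exchange_model}.
#' @param map digestion map (\code{start}, \code{end} columns).
#' @param timepoint labeling time in seconds (scalar).
#' @return numeric vector of deuterons, one per peptide.
#' @export
noiseless_uptake <- function(model, map, timepoint) {
  vapply(seq_len(nrow(map)), function(i) {
    pos <- exchangeable_positions(model$protein, map$start[i], map$end[i])
    if (length(pos) == 0L) return(0)
    sum(model$labeling_fraction *
          (1 - exp(-model$k_int[pos] * timepoint / model$protection[pos])))
  }, numeric(1))
}

#' Simulate a replicated HDX-MS uptake dataset
#'
#' Peptide uptake is the sum of per-residue first-order exchange over the
#' peptide's exchangeable amides, plus Gaussian replicate noise truncated at
#' 0 and at the saturation bound \code{labeling_fraction * n_exch}.
#'
#' @param model an \code{exchange_model} (or named list of models, one per
#'   state).
#' @param map digestion map from \code{\link{make_digestion_map}}.
#' @param state state label (ignored when \code{model} is a named list).
#' @param timepoints labeling times in seconds (default 30, 300, 3000).
#' @param replicates replicates per cell (default 3).
#' @param noise_sd Gaussian noise SD on peptide uptake, deuterons (default
#'   0.05).
#' @param seed RNG seed.
#' @return an \code{hdx_dataset} covering all states.
#' @export
simulate_uptake <- function(model, map, state = "apo",
                            timepoints = c(30, 300, 3000), replicates = 3L,
                            noise_sd = 0.05, seed = 1L) {
  models <- if (inherits(model, "exchange_model"))
    stats::setNames(list(model), state) else model
  stopifnot(all(vapply(models, inherits, TRUE, "exchange_model")),
            all(timepoints > 0), replicates >= 1L)
  protein <- models[[1]]$protein
  set.seed(seed)
  rows <- list()
  for (st in names(models)) {
    mo <- models[[st]]
    if (!identical(mo$protein$residues, protein$residues))
      stop("all state models must share the same protein")
    for (tp in timepoints) {
      clean <- noiseless_uptake(mo, map, tp)
      cap <- mo$labeling_fraction *
        vapply(seq_len(nrow(map)),
               function(i) length(exchangeable_positions(protein, map$start[i],
                                                         map$end[i])),
               numeric(1))
      for (r in seq_len(replicates)) {
        u <- clean + stats::rnorm(nrow(map), 0, noise_sd)
        u <- pmin(pmax(u, 0), cap)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = map$sequence, start = map$start, end = map$end,
          state = st, timepoint = tp, replicate = r, uptake = u,
          stringsAsFactors = FALSE)
      }
    }
  }
  hdx_dataset(protein, do.call(rbind, rows))
}

#' Ground-truth effect classes per peptide
#'
#' Expected protected/deprotected/none labels from the noiseless uptake
#' difference (holo minus apo) against an effect floor, evaluated at each
#' timepoint; a peptide is labeled by the largest-magnitude noiseless
#' difference across timepoints.
#'
#' @param model_apo,model_holo \code{exchange_model}s over the same protein.
#' @param map digestion map.
#' @param timepoints labeling times, seconds.
#' @param effect_floor minimum |delta| (deuterons) to count as a true effect.
#' @return data frame: peptide identity, \code{max_abs_delta},
#'   \code{expected} in \code{\{"protected", "deprotected", "none"\}}.
#' @export
ground_truth_labels <- function(model_apo, model_holo, map,
                                timepoints = c(30, 300, 3000),
                                effect_floor = 0.1) {
  if (!identical(model_apo$protein$residues, model_holo$protein$residues))
    stop("models must share the same protein")
  deltas <- sapply(timepoints, function(tp)
    noiseless_uptake(model_holo, map, tp) - noiseless_uptake(model_apo, map, tp))
  deltas <- matrix(deltas, nrow = nrow(map))
  pick <- apply(abs(deltas), 1, which.max)
  dmax <- deltas[cbind(seq_len(nrow(map)), pick)]
  expected <- ifelse(abs(dmax) <= effect_floor, "none",
                     ifelse(dmax < 0, "protected", "deprotected"))
  data.frame(sequence = map$sequence, start = map$start, end = map$end,
             max_abs_delta = abs(dmax), expected = expected,
             stringsAsFactors = FALSE)
}

# minimal side-chain template used by the toy trajectory generator
toy_residue_atoms <- function() {
  data.frame(name = c("N", "CA", "C", "O", "CB", "CG"),
             element = c("N", "C", "C", "O", "C", "C"),
             sidechain = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate toy trajectories with known RMSF and water-site occupancy
#'
#' Builds replicas of a minimal system: a chain of residues whose atoms
#' fluctuate isotropically about fixed anchors (side-chain atoms with a
#' per-state, per-residue amplitude \code{sigma}, so the expected RMSF is
#' \code{sqrt(3) * sigma}; backbone atoms with a small fixed jitter), a
#' static ligand/receptor site defining the four-pair rule (ligand O5/O6,
#' Gln372 NE2, Thr373 OG1), and \code{n_waters} waters. Per frame, with
#' probability \code{target_occupancy} one water is placed inside the site
#' (satisfying the rule by construction); all other waters are placed well
#' outside the outer cutoff. The realized per-frame draws are recorded in
#' the \code{realized_occupied} attribute for generator bookkeeping.
#'
#' @param n_residues number of protein residues (numbered from 1; residues
#'   372/373 of the site are added separately).
#' @param sigma per-residue side-chain fluctuation amplitude (Angstrom per
#'   axis); scalar or vector of length \code{n_residues}.
#' @param target_occupancy fraction of frames with an in-site water.
#' @param n_waters number of water molecules (oxygens only).
#' @param frames frames per replica (>= 2).
#' @param replicas number of replicas.
#' @param state state label.
#' @param seed RNG seed.
#' @param backbone_jitter backbone positional noise per axis (Angstrom).
#' @return list of \code{trajectory} objects (one per replica), each with
#'   attributes \code{realized_occupied} (logical per frame) and
#'   \code{sigma}.
#' @export
simulate_trajectory <- function(n_residues = 20, sigma = 0.5,
                                target_occupancy = 0.6, n_waters = 10,
                                frames = 200, replicas = 1, state = "apo",
                                seed = 1L, backbone_jitter = 0.05) {
  stopifnot(frames >= 2, target_occupancy >= 0, target_occupancy <= 1)
  sigma <- rep_len(sigma, n_residues)
  tmpl <- toy_residue_atoms()
  # anchors: residues on a loose helix-like curve, far from the site
  top_rows <- list(); anchors <- list()
  for (r in seq_len(n_residues)) {
    base <- c(30 + 3.5 * r, 10 * cos(r / 2), 10 * sin(r / 2))
    for (j in seq_len(nrow(tmpl))) {
      top_rows[[length(top_rows) + 1L]] <- data.frame(
        resno = r, resname = "ALA", name = tmpl$name[j],
        element = tmpl$element[j], role = "protein",
        stringsAsFactors = FALSE)
      anchors[[length(anchors) + 1L]] <- base + j * c(0.4, 0.7, 0.2)
    }
  }
  # binding site: ligand O5/O6 and the two coordinating side-chain atoms,
  # geometry chosen so a water at the site centroid satisfies the rule
  site <- data.frame(
    resno = c(900, 900, 372, 373),
    resname = c("MEL", "MEL", "GLN", "THR"),
    name = c("O5", "O6", "NE2", "OG1"),
    element = c("O", "O", "N", "O"),
    role = c("ligand", "ligand", "protein", "protein"),
    stringsAsFactors = FALSE)
  site_xyz <- rbind(c(0, 0, 0), c(2.8, 0, 0), c(1.4, 2.6, 0),
                    c(1.4, -2.6, 0))
  site_center <- c(1.4, 0, 1.5)  # ~2.3-3.0 A from all members
  wat <- data.frame(resno = 1000 + seq_len(n_waters), resname = "HOH",
                    name = "O", element = "O", role = "water",
                    stringsAsFactors = FALSE)
  top <- rbind(do.call(rbind, top_rows), site, wat)
  anchor_mat <- do.call(rbind, anchors)
  n_prot <- nrow(anchor_mat)
  set.seed(seed)
  out <- vector("list", replicas)
  for (rep_i in seq_len(replicas)) {
    co <- array(0, dim = c(nrow(top), 3, frames))
    occ_draw <- stats::runif(frames) < target_occupancy
    sc <- rep(tmpl$sidechain, n_residues)
    amp <- rep(sigma, each = nrow(tmpl))
    amp[!sc] <- backbone_jitter
    for (k in seq_len(frames)) {
      co[seq_len(n_prot), , k] <- anchor_mat +
        matrix(stats::rnorm(n_prot * 3, 0, amp), ncol = 3)
      co[n_prot + 1:4, , k] <- site_xyz
      # waters: far shell around the site, > outer cutoff from all members
      shell_dir <- matrix(stats::rnorm(n_waters * 3), ncol = 3)
      shell_dir <- shell_dir / sqrt(rowSums(shell_dir^2))
      co[n_prot + 4 + seq_len(n_waters), , k] <-
        sweep(shell_dir * (15 + stats::runif(n_waters, 0, 5)), 2,
              site_center, "+")
      if (occ_draw[k])
        co[n_prot + 5, , k] <- site_center  # first water into the site
    }
    tr <- trajectory(top, co, replica = rep_i, state = state)
    attr(tr, "realized_occupied") <- occ_draw
    attr(tr, "sigma") <- sigma
    out[[rep_i]] <- tr
  }
  out
}
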