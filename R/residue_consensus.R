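#' Per-residue mean deuteration for one state
#'
#' Collapses peptide-level uptake to residue resolution: per peptide the
#' uptake is averaged first across timepoints, then across replicates; per
#' residue the mean over covering peptides is unweighted. Residues covered by
#' no peptide are flagged uncovered. The first residue of a peptide does not
#' retain label kinetically but is still counted as spatially covered
#' (configurable).
#'
#' @param ds an \code{hdx_dataset}.
#' @param state state label.
#' @param count_first_residue treat peptide position 1 as covered (default
#'   TRUE).
#' @return data frame: \code{position}, \code{mean_deuteration} (deuterons;
#'   NA where uncovered), \code{n_peptides}, \code{covered}.
#' @export
per_residue_deuteration <- function(ds, state, count_first_residue = TRUE) {
  stopifnot(inherits(ds, "hdx_dataset"))
  np <- length(ds$protein)
  out <- data.frame(position = seq_len(np), mean_deuteration = NA_real_,
                    n_peptides = 0L, covered = FALSE)
  rec <- ds$records[ds$records$state == state, ]
  if (nrow(rec) == 0L) return(out)
  # average over timepoints within replicate, then over replicates
  by_rep <- stats::aggregate(uptake ~ sequence + start + end + replicate,
                             data = rec, FUN = mean)
  pep <- stats::aggregate(uptake ~ sequence + start + end, data = by_rep,
                          FUN = mean)
  acc <- numeric(np); cnt <- integer(np)
  for (i in seq_len(nrow(pep))) {
    lo <- if (count_first_residue) pep$start[i] else pep$start[i] + 1L
    if (lo > pep$end[i]) next
    idx <- lo:pep$end[i]
    acc[idx] <- acc[idx] + pep$uptake[i]
    cnt[idx] <- cnt[idx] + 1L
  }
  out$n_peptides <- cnt
  out$covered <- cnt > 0L
  out$mean_deuteration[out$covered] <- acc[cnt > 0L] / cnt[cnt > 0L]
  out
}

#' Per-residue consensus effect classes
#'
#' A peptide is effect-bearing if any of its timepoints passes the hybrid
#' criteria. Each residue is classed by the effect-bearing peptides covering
#' it: \code{protected} or \code{deprotected} when all agree, \code{mixed}
#' when they disagree, \code{not_significant} when covered but no covering
#' peptide bears an effect, \code{uncovered} otherwise. Conflicting overlaps
#' stay visible as \code{mixed} rather than being vote-resolved.
#'
#' @param diffs a classified \code{hdx_differential}
#'   (\code{\link{hybrid_classify}} output).
#' @param ds the \code{hdx_dataset} the differentials came from (defines
#'   protein length and coverage).
#' @param count_first_residue as in \code{\link{per_residue_deuteration}}.
#' @return data frame: \code{position}, \code{effect}, \code{n_covering},
#'   \code{n_protected}, \code{n_deprotected} (effect-bearing peptide counts).
#' @export
consensus_effects <- function(diffs, ds, count_first_residue = TRUE) {
  stopifnot(inherits(diffs, "hdx_differential"), inherits(ds, "hdx_dataset"))
  if (is.null(diffs$significant))
    stop("diffs lack significance calls; run hybrid_classify first")
  np <- length(ds$protein)
  # peptide-level verdict: significant at any timepoint, with direction(s)
  key <- c("sequence", "start", "end")
  peps <- unique(as.data.frame(diffs)[key])
  cov <- integer(np); prot <- integer(np); depr <- integer(np)
  for (i in seq_len(nrow(peps))) {
    sel <- diffs$sequence == peps$sequence[i] & diffs$start == peps$start[i] &
      diffs$end == peps$end[i]
    dirs <- unique(diffs$direction[sel & diffs$significant])
    lo <- if (count_first_residue) peps$start[i] else peps$start[i] + 1L
    if (lo > peps$end[i]) next
    idx <- lo:peps$end[i]
    cov[idx] <- cov[idx] + 1L
    if ("protected" %in% dirs) prot[idx] <- prot[idx] + 1L
    if ("deprotected" %in% dirs) depr[idx] <- depr[idx] + 1L
  }
  effect <- rep("uncovered", np)
  effect[cov > 0L] <- "not_significant"
  effect[prot > 0L & depr == 0L] <- "protected"
  effect[depr > 0L & prot == 0L] <- "deprotected"
  effect[prot > 0L & depr > 0L] <- "mixed"
  data.frame(position = seq_len(np), effect = effect, n_covering = cov,
             n_protected = prot, n_deprotected = depr,
             stringsAsFactors = FALSE)
}

effect_codes <- c(uncovered = -1, not_significant = 0, protected = 1,
                  deprotected = 2, mixed = 3)

#' Write per-residue annotations into a structure's B-factor channel
#'
#' Maps per-residue values (mean deuteration, or numeric codes for consensus
#' effect classes) onto every atom of the matching residue in a structure
#' model and writes an annotated PDB and/or mmCIF. Residues in the structure
#' with no annotation get a sentinel value (default -1, outside the data
#' range of both channels). Structure residues are matched by residue number;
#' an offset reconciles differing numbering. Annotated positions missing from
#' the structure are skipped with a message.
#'
#' @param calls output of \code{\link{consensus_effects}} (annotated with the
#'   numeric class codes: uncovered -1, not_significant 0, protected 1,
#'   deprotected 2, mixed 3) or of \code{\link{per_residue_deuteration}}
#'   (mean deuteration written directly).
#' @param structure a \code{bio3d} \code{pdb} object
#'   (\code{\link{read_structure}}).
#' @param out output path; extension selects the format (\code{.pdb} or
#'   \code{.cif}).
#' @param field which annotation to write: \code{"effect"} or
#'   \code{"deuteration"}; autodetected from \code{calls} columns.
#' @param offset added to annotation positions to obtain structure residue
#'   numbers (default 0).
#' @param sentinel B-factor for unannotated residues (default -1).
#' @return invisibly, the per-atom B-factor vector written.
#' @export
export_structure_map <- function(calls, structure, out,
                                 field = c("auto", "effect", "deuteration"),
                                 offset = 0L, sentinel = -1) {
  field <- match.arg(field)
  if (field == "auto")
    field <- if ("effect" %in% names(calls)) "effect" else "deuteration"
  if (field == "effect") {
    vals <- unname(effect_codes[calls$effect])
    if (anyNA(vals)) stop("unknown effect class in calls")
  } else {
    vals <- calls$mean_deuteration
  }
  pos <- calls$position + as.integer(offset)
  ann <- stats::setNames(vals, pos)
  atom <- structure$atom
  b <- ann[as.character(atom$resno)]
  b[is.na(b)] <- sentinel
  missing_in_struct <- setdiff(pos[!is.na(vals)], unique(atom$resno))
  if (length(missing_in_struct) > 0L)
    message(length(missing_in_struct),
            " annotated position(s) absent from the structure; skipped")
  structure$atom$b <- round(unname(b), 2)
  if (grepl("\\.cif$", out, ignore.case = TRUE))
    write_structure_cif(structure, out)
  else
    bio3d::write.pdb(structure, file = out)
  invisible(unname(b))
}
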