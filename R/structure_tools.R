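#' Read a structure model (PDB or mmCIF)
#'
#' Thin wrapper over bio3d's readers; the format is selected from the file
#' extension (mmCIF preferred where both exist). Alternate conformers keep
#' altloc 'A' (or blank).
#'
#' @param path path to a \code{.pdb} or \code{.cif} file.
#' @return a \code{bio3d} \code{pdb} object.
#' @export
read_structure <- function(path) {
  if (grepl("\\.cif$", path, ignore.case = TRUE))
    s <- withCallingHandlers(
      bio3d::read.cif(path),
      warning = function(w) {
        if (grepl("beta version|helix/sheet", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  else
    s <- bio3d::read.pdb(path)
  keep <- s$atom$alt %in% c(NA, "", "A", ".")
  if (!all(keep)) s <- bio3d::trim.pdb(s, inds = list(atom = which(keep)))
  s
}

#' Minimal mmCIF writer (atom_site loop)
#'
#' Emits the coordinate loop of an mmCIF file from a bio3d pdb object. Only
#' atom_site records are written; this is sufficient for annotation transfer
#' (e.g. B-factor maps) and re-reading by standard parsers.
#'
#' @param pdb a bio3d \code{pdb} object.
#' @param file output path.
#' @export
write_structure_cif <- function(pdb, file) {
  a <- pdb$atom
  n <- nrow(a)
  grp <- ifelse(is.na(a$type) | a$type == "", "ATOM", a$type)
  elem <- ifelse(is.na(a$elesy) | a$elesy == "",
                 toupper(substr(a$elety, 1, 1)), a$elesy)
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  # full wwPDB atom_site column set so standard readers accept the file
  lines <- c(
    "data_annotated",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
            grp, seq_len(n), elem, a$elety, a$resid, chain, a$resno,
            a$x, a$y, a$z,
            ifelse(is.na(a$o), 1, a$o), ifelse(is.na(a$b), 0, a$b),
            a$resno, a$resid, chain, a$elety),
    "#")
  writeLines(lines, file)
  invisible(NULL)
}

is_water <- function(resid) resid %in% c("HOH", "WAT", "DOD", "TIP3", "SOL")
is_hydrogen <- function(atom) {
  el <- atom$elesy
  ifelse(!is.na(el) & el != "", toupper(el) %in% c("H", "D"),
         grepl("^[0-9]*H", atom$elety))
}

#' Residues forming a ligand-binding pocket
#'
#' Protein residues with at least one non-hydrogen atom within \code{cutoff}
#' of any non-hydrogen atom of the ligand. Waters and ions are excluded by
#' default; the ligand itself is always excluded.
#'
#' @param s a bio3d \code{pdb} object.
#' @param ligand residue name of the ligand (e.g. \code{"NPG"},
#'   \code{"MEL"}).
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @param exclude_waters drop waters from the result (default TRUE).
#' @return data frame of pocket residues (\code{chain}, \code{resno},
#'   \code{resid}, \code{min_dist}), sorted by chain then residue number.
#' @export
pocket_residues <- function(s, ligand, cutoff = 5, exclude_waters = TRUE) {
  stopifnot(cutoff > 0)
  a <- s$atom
  lig <- a$resid == ligand & !is_hydrogen(a)
  if (!any(lig)) stop("ligand selector matches nothing: ", ligand)
  env <- a$resid != ligand & !is_hydrogen(a)
  if (exclude_waters) env <- env & !is_water(a$resid)
  if (!any(env)) return(data.frame(chain = character(0), resno = integer(0),
                                   resid = character(0),
                                   min_dist = numeric(0)))
  lx <- as.matrix(a[lig, c("x", "y", "z")])
  ex <- as.matrix(a[env, c("x", "y", "z")])
  # min distance from each environment atom to any ligand atom
  d2 <- outer(rowSums(ex^2), rowSums(lx^2), "+") - 2 * ex %*% t(lx)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  hit <- mind <= cutoff
  res <- data.frame(chain = a$chain[env][hit], resno = a$resno[env][hit],
                    resid = a$resid[env][hit], min_dist = mind[hit],
                    stringsAsFactors = FALSE)
  if (nrow(res) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), min_dist = numeric(0)))
  agg <- stats::aggregate(min_dist ~ chain + resno + resid, data = res,
                          FUN = min)
  agg <- agg[order(agg$chain, agg$resno), ]
  rownames(agg) <- NULL
  agg
}

resolve_selection <- function(s, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  if (inherits(sel, "select")) return(sel$atom)
  if (is.list(sel)) return(do.call(bio3d::atom.select,
                                   c(list(s), sel))$atom)
  if (is.character(sel) && length(sel) == 1L)
    return(bio3d::atom.select(s, string = sel)$atom)
  stop("unsupported selection")
}

#' Polar contacts between two atom selections
#'
#' All nitrogen/oxygen atom pairs across the two selections at distance
#' \code{<= max_dist} (default 3.5 Angstrom), i.e. candidate hydrogen bonds
#' and salt bridges. Each pair is reported once; self pairs are excluded.
#'
#' @param s a bio3d \code{pdb} object.
#' @param selection_a,selection_b selections: integer atom indices, a
#'   \code{bio3d::atom.select} result, a selection-string (e.g.
#'   \code{"ligand"}), or a list of \code{atom.select} arguments (e.g.
#'   \code{list(resno = 59)}).
#' @param max_dist contact cutoff in Angstrom.
#' @return data frame of contacts with both atoms' identities and the
#'   distance, sorted by distance.
#' @export
polar_contacts <- function(s, selection_a, selection_b, max_dist = 3.5) {
  ia <- resolve_selection(s, selection_a)
  ib <- resolve_selection(s, selection_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty selection")
  a <- s$atom
  polar <- function(i) {
    el <- a$elesy[i]
    known <- !is.na(el) & el != ""
    out <- toupper(substr(a$elety[i], 1, 1)) %in% c("N", "O")
    out[known] <- toupper(el[known]) %in% c("N", "O")
    i[out]
  }
  ia <- polar(ia); ib <- polar(ib)
  if (length(ia) == 0L || length(ib) == 0L)
    return(data.frame())
  xa <- as.matrix(a[ia, c("x", "y", "z")])
  xb <- as.matrix(a[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d <- sqrt(pmax(d2, 0))
  hits <- which(d <= max_dist, arr.ind = TRUE)
  if (nrow(hits) > 0L) {
    gi <- ia[hits[, 1]]; gj <- ib[hits[, 2]]
    keep <- gi != gj
    hits <- hits[keep, , drop = FALSE]; gi <- gi[keep]; gj <- gj[keep]
  } else gi <- gj <- integer(0)
  if (length(gi) == 0L) return(data.frame())
  key <- paste(pmin(gi, gj), pmax(gi, gj))
  first <- !duplicated(key)
  out <- data.frame(
    chain_a = a$chain[gi], resno_a = a$resno[gi], resid_a = a$resid[gi],
    atom_a = a$elety[gi],
    chain_b = a$chain[gj], resno_b = a$resno[gj], resid_b = a$resid[gj],
    atom_b = a$elety[gj],
    distance = d[hits], stringsAsFactors = FALSE)[first, ]
  out <- out[order(out$distance), ]
  rownames(out) <- NULL
  out
}

#' Optimal rigid-body superposition of two coordinate sets (Kabsch)
#'
#' Least-squares fit of \code{mobile} onto \code{ref} by SVD of the
#' cross-covariance, with the proper-rotation sign correction.
#'
#' @param ref,mobile n x 3 coordinate matrices with matched rows.
#' @return list: \code{rotation} (3 x 3), \code{translation} (length 3, to be
#'   applied after rotation), \code{rmsd}, and \code{fitted} (mobile after
#'   the transform).
#' @export
kabsch_fit <- function(ref, mobile) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  stopifnot(ncol(ref) == 3, ncol(mobile) == 3, nrow(ref) == nrow(mobile))
  if (nrow(ref) < 3) stop("underdetermined: need >= 3 paired atoms")
  cr <- colMeans(ref); cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm); Q <- sweep(ref, 2, cr)
  s <- svd(t(P) %*% Q)
  dsign <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  fitted <- sweep(P %*% t(R), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - ref)^2)))
  list(rotation = R, translation = cr - as.numeric(R %*% cm), rmsd = rmsd,
       fitted = fitted)
}

#' Superpose two structure models
#'
#' Atoms are paired by identical (chain, residue number, atom name) within
#' the selection (default Calpha), then fit by \code{\link{kabsch_fit}}.
#'
#' @param a,b bio3d \code{pdb} objects (reference and mobile).
#' @param selection atom-name selection, default \code{"CA"}; any atom names
#'   vector, or \code{"all"}.
#' @return list: \code{rmsd} (Angstrom), \code{rotation},
#'   \code{translation}, \code{n_atoms} paired, and \code{selection}
#'   metadata.
#' @export
superpose <- function(a, b, selection = "CA") {
  pick <- function(s) {
    at <- s$atom
    keep <- if (identical(selection, "all")) !is_hydrogen(at)
            else at$elety %in% selection
    at <- at[keep, , drop = FALSE]
    at$key <- paste(at$chain, at$resno, at$elety)
    at
  }
  aa <- pick(a); bb <- pick(b)
  common <- intersect(aa$key, bb$key)
  if (length(common) < 3) {
    unpaired <- union(setdiff(aa$key, bb$key), setdiff(bb$key, aa$key))
    stop("fewer than 3 paired atoms; unpaired: ",
         paste(utils::head(unpaired, 10), collapse = "; "))
  }
  aa <- aa[match(common, aa$key), ]; bb <- bb[match(common, bb$key), ]
  fit <- kabsch_fit(as.matrix(aa[c("x", "y", "z")]),
                    as.matrix(bb[c("x", "y", "z")]))
  list(rmsd = fit$rmsd, rotation = fit$rotation,
       translation = fit$translation, n_atoms = length(common),
       selection = selection, units = "Angstrom")
}
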