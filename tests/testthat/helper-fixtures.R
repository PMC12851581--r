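# Shared fixture builders. All synthetic, generated in code at test time.

# small protein with known sequence (no prolines unless asked)
fixture_protein <- function(n = 30, with_proline = FALSE, seed = 42) {
  set.seed(seed)
  pool <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]]
  aa <- sample(pool, n, replace = TRUE)
  if (with_proline) aa[c(5, 12)] <- "P"
  protein_sequence("fixture", aa)
}

# records data.frame for given peptides x states x timepoints x replicates
fixture_records <- function(protein, peptides, states = "apo",
                            timepoints = c(30, 300, 3000), replicates = 3,
                            uptake_fun = NULL, seed = 7) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(peptides))) {
    sq <- subseq(protein, peptides$start[i], peptides$end[i])
    nex <- max_exchangeable(sq)
    for (st in states) for (tp in timepoints) for (r in seq_len(replicates)) {
      u <- if (is.null(uptake_fun)) stats::runif(1, 0, max(nex * 0.9, 0.01))
           else uptake_fun(i, st, tp, r)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = sq, start = peptides$start[i], end = peptides$end[i],
        state = st, timepoint = tp, replicate = r,
        uptake = min(max(u, 0), nex), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

fixture_dataset <- function(n = 30, n_peptides = 6, states = "apo", ...) {
  prot <- fixture_protein(n)
  starts <- seq(1, n - 6, length.out = n_peptides)
  peps <- data.frame(start = as.integer(round(starts)),
                     end = pmin(as.integer(round(starts)) + 5L, n))
  hdx_dataset(prot, fixture_records(prot, peps, states = states, ...))
}

# write a minimal PDB file from an atom table for structure_tools tests
write_fixture_pdb <- function(atoms, path) {
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(atoms$type == "ATOM", "ATOM", "HETATM"),
    seq_len(nrow(atoms)), substr(atoms$elety, 1, 4), atoms$resid,
    atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z, 1,
    ifelse(is.null(atoms$b), 0, atoms$b), atoms$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# small two-residue protein + ligand structure with controllable distances
fixture_structure <- function(path = tempfile(fileext = ".pdb"),
                              d1 = 4.9, d2 = 5.1) {
  atoms <- data.frame(
    type  = c("HETATM", "ATOM", "ATOM", "ATOM", "ATOM", "HETATM"),
    elety = c("C1", "CA", "CB", "CA", "CB", "O"),
    resid = c("LIG", "ALA", "ALA", "VAL", "VAL", "HOH"),
    chain = "A",
    resno = c(500L, 10L, 10L, 11L, 11L, 900L),
    x = c(0, d1, d1 + 1.5, d2, d2 + 1.5, 2.0),
    y = 0, z = 0,
    elesy = c("C", "C", "C", "C", "C", "O"),
    stringsAsFactors = FALSE)
  write_fixture_pdb(atoms, path)
  read_structure(path)
}

# random coordinate cloud as an n x 3 matrix
random_coords <- function(n, seed = 1, scale = 10) {
  set.seed(seed)
  matrix(stats::rnorm(n * 3, 0, scale), ncol = 3)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent brute-force water-occupancy check (naive double loop)
naive_occupancy <- function(traj, rule) {
  wat <- which(traj$topology$role == "water" &
               toupper(traj$topology$element) == "O")
  nf <- dim(traj$coords)[3]
  flags <- logical(nf)
  for (k in seq_len(nf)) {
    any_w <- FALSE
    for (w in wat) {
      wpos <- traj$coords[w, , k]
      for (p in rule$pairs) {
        d1 <- sqrt(sum((wpos - traj$coords[p[1], , k])^2))
        d2 <- sqrt(sum((wpos - traj$coords[p[2], , k])^2))
        if (d1 <= rule$outer && d2 <= rule$outer &&
            (d1 < rule$inner || d2 < rule$inner)) { any_w <- TRUE; break }
      }
      if (any_w) break
    }
    flags[k] <- any_w
  }
  mean(flags)
}

# minimal hand-built trajectory: topology + explicit coordinates
toy_trajectory <- function(coords, roles, names = NULL, elements = NULL,
                           resnos = NULL, state = "apo", replica = 1L) {
  n <- dim(coords)[1]
  top <- data.frame(
    resno = if (is.null(resnos)) seq_len(n) else resnos,
    resname = ifelse(roles == "water", "HOH",
                     ifelse(roles == "ligand", "MEL", "ALA")),
    name = if (is.null(names)) ifelse(roles == "water", "O", "CB") else names,
    element = if (is.null(elements)) ifelse(roles == "water", "O", "C")
              else elements,
    role = roles, stringsAsFactors = FALSE)
  trajectory(top, coords, replica = replica, state = state)
}
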