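#!/usr/bin/env Rscript
# Step 3: collapse peptide-level calls to per-residue consensus and map
# them onto a structure model's B-factor channel.
#
# Writes the per-residue profile (mean deuteration, coverage, effect class)
# and annotated PDB/mmCIF files for a synthetic Calpha-trace structure with
# matching numbering.

suppressMessages(library(hdxtraj))

prot <- random_protein(200, seed = 2001)
ds <- read_uptake_table("results/uptake_table.csv", prot)
diffs <- read.csv("results/differential_mel_apo.csv")
class(diffs) <- c("hdx_differential", "data.frame")

pr_apo <- per_residue_deuteration(ds, "apo")
cc <- consensus_effects(diffs, ds)
per_res <- merge(pr_apo, cc, by = "position")
write.csv(per_res, "results/per_residue_mel_apo.csv", row.names = FALSE)

tab <- table(cc$effect)
cat("consensus classes:\n"); print(tab)
prot_res <- cc$position[cc$effect == "protected"]
if (length(prot_res)) {
  runs <- split(prot_res, cumsum(c(1, diff(prot_res) != 1)))
  cat("protected segments:",
      paste(vapply(runs, function(r) paste0(min(r), "-", max(r)), ""),
            collapse = ", "), "\n")
}

# synthetic Calpha-trace structure, numbering aligned to the sequence
xyz <- cbind(3.8 * seq_len(200), 10 * cos(seq_len(200) / 3),
             10 * sin(seq_len(200) / 3))
pdb_path <- tempfile(fileext = ".pdb")
writeLines(c(sprintf(
  "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
  seq_len(200), seq_len(200), xyz[, 1], xyz[, 2], xyz[, 3]), "END"),
  pdb_path)
s <- read_structure(pdb_path)
export_structure_map(cc, s, "results/consensus_map.pdb")
export_structure_map(cc, s, "results/consensus_map.cif")
export_structure_map(pr_apo, s, "results/deuteration_map.pdb",
                     field = "deuteration")
cat("wrote per_residue_mel_apo.csv and annotated structures",
    "(B-factor codes: -1 uncovered, 0 not significant, 1 protected,",
    "2 deprotected, 3 mixed)\n")
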