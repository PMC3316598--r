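#!/usr/bin/env Rscript
# Apply the fitted pose to the structure and report the docking geometry:
# signed residue depths relative to the phosphate plane, contact residues
# by chemical class, and the docked-pose PDB.

suppressPackageStartupMessages(library(eprdock))
dir.create("results", showWarnings = FALSE)

s <- read_structure("results/synthetic_structure.pdb")
fit <- utils::read.csv("results/fit_parameters.csv")
t <- docking_transform(fit$estimate[fit$parameter == "theta_x"],
                       fit$estimate[fit$parameter == "theta_z"],
                       fit$estimate[fit$parameter == "y_trans"])

rep <- geometry_report(s, t, contact_cutoff = 3)
write_structure(rep$structure, "results/docked_pose.pdb")
utils::write.csv(rep$ca_depths, "results/residue_depths.csv",
                 row.names = FALSE)

deep <- rep$ca_depths[which.min(rep$ca_depths$depth), ]
cat(sprintf("Deepest backbone CA: residue %d at %.2f A %s the phosphate plane.\n",
            deep$resno, abs(deep$depth),
            if (deep$depth < 0) "below" else "above"))
n_contact <- nrow(rep$contacts$basic) + nrow(rep$contacts$acidic) +
  nrow(rep$contacts$hydrophobic_polar)
cat(n_contact, "residues have side-chain atoms within the headgroup layer",
    "(y < +3 A).\n")
cat("Contact classes: basic", nrow(rep$contacts$basic),
    "| acidic", nrow(rep$contacts$acidic),
    "| hydrophobic/polar", nrow(rep$contacts$hydrophobic_polar), "\n")
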