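#!/usr/bin/env Rscript
# Stage 1: synthetic inputs.
#
# The upstream stages of the real study (MD sampling of the protein, QM/MM
# site energies) are replaced by seeded generators with the statistical
# structure the analysis assumes: an Ornstein-Uhlenbeck process for
# site-energy fluctuations, toy ring geometries for couplings, and jittered
# coordinates for structural statistics. This script writes small
# demonstration files; the later stages regenerate what they need in memory
# at full production scale (20 ps at 0.5 fs) rather than carrying large
# intermediates on disk.

suppressPackageStartupMessages(library(fmoexciton))
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)

# eight-pigment ring geometry with tangential dipoles
ring <- generate_pigment_ring(8, radius = 15, dipole_scheme = "tangential")
write_pigments_pdb(ring, "results/inputs/ring_pigments.pdb")

# short site-energy table (one pigment, three monomers, 0.25 ps)
cfg_demo <- ou_config(n_steps = 500, seed = 11)
demo <- generate_ou_site_energies(cfg_demo, pigment_label = "1")
write_site_energy_table(demo, "results/inputs/site_energies_demo.csv")

# jittered coordinate trajectory of a Mg + 4 N chelation site
base <- rbind(MG_1 = c(0, 0, 0),
              NA_1 = c(2.05, 0, 0), NB_1 = c(0, 2.05, 0),
              NC_1 = c(-2.05, 0, 0), ND_1 = c(0, -2.05, 0))
traj <- generate_jittered_trajectory(base, sigma = 0.04, n_frames = 50,
                                     rigid_motion = TRUE, seed = 13)
write_coordinate_trajectory(traj, "results/inputs/jittered_trajectory.pdb")

cat("Synthetic inputs written under results/inputs/:\n")
cat("  ring_pigments.pdb        8 pigments on a 15 A ring\n")
cat(sprintf("  site_energies_demo.csv   %d samples x %d monomers, OU process\n",
            cfg_demo$n_steps, cfg_demo$n_monomers))
cat("  jittered_trajectory.pdb  50 frames of a jittered Mg-N4 site\n")
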