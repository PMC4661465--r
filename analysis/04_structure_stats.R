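#!/usr/bin/env Rscript
# Stage 4: structural statistics.
#
# On a synthetic jittered trajectory of Mg-N4 chelation sites (crystal-like
# base coordinates plus isotropic Gaussian jitter and random rigid motion),
# computes superposition RMSD per frame and the Mg-N distance distributions
# whose Gaussian widths quantify how tightly the magnesium is held.

suppressPackageStartupMessages(library(fmoexciton))
dir.create("results", showWarnings = FALSE)

# two chelation sites, displaced copies of the same Mg + 4 N motif
site <- rbind(c(0, 0, 0),
              c(2.05, 0, 0), c(0, 2.05, 0), c(-2.05, 0, 0), c(0, -2.05, 0))
base <- rbind(site, sweep(site, 2, c(12, 3, -4), `+`))
rownames(base) <- c("MG_1", "NA_1", "NB_1", "NC_1", "ND_1",
                    "MG_2", "NA_2", "NB_2", "NC_2", "ND_2")

sigma <- 0.04
traj <- generate_jittered_trajectory(base, sigma = sigma, n_frames = 2000,
                                     rigid_motion = TRUE, seed = 17)

rmsd <- vapply(traj$frames, function(f) superpose_rmsd(base, f), numeric(1))
utils::write.csv(data.frame(frame = seq_along(rmsd),
                            rmsd_A = round(rmsd, 4)),
                 "results/rmsd_series.csv", row.names = FALSE)
cat(sprintf("RMSD after superposition: mean %.3f A (jitter sigma %.2f A; expected ~ sigma*sqrt(3) minus the 6 fitted rigid dof)\n",
            mean(rmsd), sigma))

pairs <- list(c("MG_1", "NA_1"), c("MG_1", "NB_1"),
              c("MG_2", "NA_2"), c("MG_2", "NB_2"))
d <- distance_series(traj, pairs)
fwhm_tab <- do.call(rbind, lapply(seq_along(pairs), function(j) {
  r <- histogram_fwhm(d[, j], bin_width = 0.01)
  data.frame(pair = colnames(d)[j], peak_A = r$peak_position,
             fwhm_A = r$fwhm, method = r$method)
}))
utils::write.csv(fwhm_tab, "results/mg_n_distance_fwhm.csv", row.names = FALSE)

cat("Mg-N distance distributions:\n")
for (j in seq_len(nrow(fwhm_tab)))
  cat(sprintf("  %-11s peak %.3f A (construction 2.05), FWHM %.3f A\n",
              fwhm_tab$pair[j], fwhm_tab$peak_A[j], fwhm_tab$fwhm_A[j]))
cat(sprintf("  (both atoms jittered: expected FWHM = 2.3548 * sigma * sqrt(2) = %.3f A)\n",
            2.3548 * sigma * sqrt(2)))
cat("Tables written: rmsd_series.csv, mg_n_distance_fwhm.csv\n")
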