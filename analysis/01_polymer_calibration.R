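#!/usr/bin/env Rscript
# Worm-like-chain calibration of the extension<->bp ruler, plus the
# physiological TRF1 dimer concentration implied by per-cell copy numbers.
# Writes results/polymer_calibration.tsv and results/wlc_curves.tsv.

suppressPackageStartupMessages(library(teltrace))
dir.create("results", showWarnings = FALSE)

forces <- c(0.5, 1, 2, 4, 8, 12, 17, 20, 25)
curves <- data.frame(
  force_pN = forces,
  ds_relative_extension = ds_relative_extension(forces),
  ds_nm_per_bp = ds_nm_per_bp(forces),
  ss_relative_extension = ss_relative_extension(forces),
  ss_nm_per_nt = ss_nm_per_nt(forces))
write_table_tsv(curves, "results/wlc_curves.tsv")

calib <- data.frame(
  quantity = c("ds_nm_per_bp_at_17pN", "ds_nm_per_bp_at_17pN_rounded",
               "ss_nm_per_nt_at_17pN",
               "trf1_dimer_conc_nM", "trf1_dimer_conc_upper_nM",
               "trf1_dimer_conc_lower_nM"),
  value = c(ds_nm_per_bp(17), round(ds_nm_per_bp(17), 2),
            ss_nm_per_nt(17),
            dimer_concentration(40000, 1540),
            dimer_concentration(40000, 760),
            dimer_concentration(40000, 2730)))
write_table_tsv(calib, "results/polymer_calibration.tsv")

cat(sprintf("dsDNA ruler at 17 pN: %.4f nm/bp (rounds to %.2f)\n",
            ds_nm_per_bp(17), round(ds_nm_per_bp(17), 2)))
cat(sprintf("ssDNA release factor at 17 pN: %.3f nm/nt\n", ss_nm_per_nt(17)))
cat(sprintf("physiological TRF1 dimer concentration: %.1f nM (%.1f-%.1f nM)\n",
            dimer_concentration(40000, 1540),
            dimer_concentration(40000, 2730),
            dimer_concentration(40000, 760)))
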