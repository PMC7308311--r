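#!/usr/bin/env Rscript
# Peristaltic pumping in the idealised one-wavelength annular PVS (periodic
# ends, sinusoidal traveling wall wave, production mesh 10 x 100).  Sweeps
# the wall amplitude from physiological (1-4% peak-to-peak of the arterial
# radius) to the grossly non-physiological values needed for appreciable
# pumping, and records the mean-vs-oscillatory decomposition, the
# wall-to-fluid phase at z = lambda/2, and the Reynolds number.
#
# Findings this script prints: at physiological amplitudes the centerline
# mean flow is 2-3 orders of magnitude below the oscillatory velocity,
# the mean grows quadratically with amplitude, and the fluid velocity lags
# the wall velocity by ~270 degrees.

library(pvsflow)

phi0s <- c(0, amp_from_pp_radius_pct(c(0.8, 1, 2, 4, 10, 25, 50)))
sweep <- run_amplitude_sweep(phi0s, m = 2L)

write_run_outputs("results", "amplitude_sweep",
                  tables = list(sweep = sweep),
                  config = attr(sweep, "config"))

phys <- sweep[sweep$pp_radius_pct %in% c(1, 4), ]
cat("Physiological band (1-4% peak-to-peak of radius):\n")
for (i in seq_len(nrow(phys)))
  cat(sprintf(
    "  pp %.0f%%: mean %.3g um/s, oscillatory %.4g um/s, log10(osc/mean) = %.2f, phase = %.1f deg\n",
    phys$pp_radius_pct[i], phys$mean_eulerian[i] * 1e6,
    phys$oscillatory[i] * 1e6, phys$log10_osc_over_mean[i],
    phys$phase_deg[i]))

nz <- sweep[sweep$phi0 > 0, ]
slope <- stats::coef(stats::lm(log(abs(mean_eulerian)) ~ log(phi0),
                               data = nz[nz$phi0 <= 0.02, ]))[2]
cat(sprintf("Small-amplitude scaling: mean flow ~ amplitude^%.2f\n", slope))
cat(sprintf("At 50%% pp the mean/oscillatory ratio reaches %.3g (same order as in-vivo trajectories)\n",
            nz$ratio[nz$pp_radius_pct == 50]))

# field snapshot at the physiological 0.8% pp amplitude
sol <- solve_traveling_wave(wave_spec(amp_from_pp_radius_pct(0.8)), m = 2L)
write_vtk(sol$mesh, "results/peristalsis_fields.vtk",
          point_data = list(uz_lab = sol$uz_lab, ur = sol$ur_lab, p = sol$p),
          title = "one-wavelength peristalsis, lab-frame fields")
cat("Wrote results/amplitude_sweep_sweep.csv and results/peristalsis_fields.vtk\n")
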