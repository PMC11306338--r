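#!/usr/bin/env Rscript
# Exposure-table dosimetry: power budget, fields and SAR for each measured
# waveguide configuration, written to results/dosimetry.csv.
#
# Inputs are the measured characterization values: source powers 15/19/23
# dBm with 0.8 dB cable loss, buffer-filled S-parameters per frequency, a
# 1 mm plate gap on a 50-ohm line, buffer conductivity 0.8 S/m and water
# density. Field at the measurement point assumes a linear field profile
# along the exposure section, evaluated mid-section.

library(turbikin)
dir.create("results", showWarnings = FALSE)

# frequency [GHz], source power [dBm], buffer-filled S21/S11 [dB]
grid <- data.frame(
  frequency_ghz = c(3.5, 20, 20, 20, 29),
  source_dbm = c(23, 15, 19, 23, 23),
  s21 = c(-1.49, -10.73, -10.73, -10.73, -16.48),
  s11 = c(-8.45, -11.88, -11.88, -11.88, -9.30)
)

med <- medium_props(conductivity = 0.8, density = 1000)
rows <- lapply(seq_len(nrow(grid)), function(i) {
  g <- grid[i, ]
  rep <- dosimetry_report(
    exposure_setting(g$frequency_ghz, g$source_dbm, cable_loss_db = 0.8,
                     s11 = g$s11, s21 = g$s21, measurement_position = 0.5),
    med)
  data.frame(frequency_ghz = g$frequency_ghz,
             p_waveguide_mw = round(rep$p_waveguide_mw),
             reflected_mw = round(rep$budget$reflected, 1),
             transmitted_mw = round(rep$budget$transmitted, 1),
             absorbed_mw = round(rep$budget$absorbed, 1),
             e_nominal_kv_m = round(rep$e_nominal_v_m / 1000, 2),
             e_measured_kv_m = round(rep$e_measurement_v_m / 1000, 2),
             sar_w_kg = rep$sar_rounded_w_kg,
             x_whole_body_limit = signif(rep$vs_whole_body_guideline, 2))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/dosimetry.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nwrote results/dosimetry.csv\n")
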