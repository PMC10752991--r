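#!/usr/bin/env Rscript
# Stage 2 of the pipeline: calibrate the serial-elastic tendon parameters
# against a stress-strain reference curve.
#
# The reference is a synthetic surrogate for positional-tendon material
# data: toe region, a linear region with a 2.4 GPa modulus, and necking
# beyond 3.5% strain. The fit minimizes the 0-3% window (where the tendon
# model family can represent the data); the 0-5% window is reported to show
# how the missing necking branch degrades the wide-window agreement. The
# generic default parameter set is scored for comparison.

library(jfisim)

dir.create("results", showWarnings = FALSE)

spec <- default_tendon_spec(linear_modulus = 2.4e9, toe_end_strain = 0.015,
                            linear_end_strain = 0.035,
                            necking_modulus_fraction = 0.15)
ref <- gen_tendon_reference(spec, seed = 20260901)
write_stress_strain(ref, "results/tendon_reference.csv")

Fmax <- 100; csa <- Fmax / 30e6

fit <- fit_see(ref, Fmax, csa, init = see_params())
def <- see_params()
def_curve <- model_stress_strain(def, Fmax, csa, ref$strains)

report <- data.frame(
  parameter_set = c("fitted", "default"),
  dF_see_0_frac = c(fit$see$dF_see_0_frac, def$dF_see_0_frac),
  dU_see_nll = c(fit$see$dU_see_nll, def$dU_see_nll),
  dU_see_l = c(fit$see$dU_see_l, def$dU_see_l),
  nmae3_pct = c(fit$nmae3, windowed_nmae(def_curve, ref, 0.03)),
  nmae5_pct = c(fit$nmae5, windowed_nmae(def_curve, ref, 0.05)),
  E_GPa = c(fit$E, see_young_modulus(def, Fmax, csa)) / 1e9)
write.csv(report, "results/tendon_fit.csv", row.names = FALSE)
write_stress_strain(model_stress_strain(fit$see, Fmax, csa, ref$strains),
                    "results/tendon_model_fitted.csv")

cat("tendon calibration:\n")
print(report, digits = 4)
cat(sprintf("\nfitted set: NMAE3 %.2f%% vs NMAE5 %.2f%% (necking outside the\n",
            fit$nmae3, fit$nmae5))
cat("model family widens the 0-5% window error); default set is far too\n")
cat(sprintf("compliant (E %.2f GPa vs fitted %.2f GPa)\n",
            report$E_GPa[2], report$E_GPa[1]))
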