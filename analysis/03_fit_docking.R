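#!/usr/bin/env Rscript
# Joint hyperbola / rigid-body fit on the simulated dataset: multistart
# nonlinear least squares for the seven unknowns, uncertainty estimates,
# and the replicated parameter-recovery experiment.

suppressPackageStartupMessages(library(eprdock))
dir.create("results", showWarnings = FALSE)

seed <- 1
truth <- default_truth(seed)
dataset <- utils::read.csv("results/synthetic_dataset.csv")

model <- multistart_fit(dataset)
unc <- estimate_uncertainties(model, dataset, "covariance")
fit_tab <- data.frame(
  parameter = c("theta_x", "theta_z", "y_trans", "m", "i", "b", "c"),
  truth = c(truth$transform$theta_x, truth$transform$theta_z,
            truth$transform$y_trans, truth$hyperbola$m, truth$hyperbola$i,
            truth$hyperbola$b, truth$hyperbola$c),
  estimate = c(model$transform$theta_x, model$transform$theta_z,
               model$transform$y_trans, model$hyperbola$m,
               model$hyperbola$i, model$hyperbola$b, model$hyperbola$c),
  se = unname(unc))
utils::write.csv(fit_tab, "results/fit_parameters.csv", row.names = FALSE)
utils::write.csv(data.frame(site = dataset$site, phi = dataset$phi,
                            fitted = model$fitted,
                            residual = model$residuals),
                 "results/fit_residuals.csv", row.names = FALSE)

cat("Joint fit on", nrow(dataset), "rows: R =", round(model$r, 4), "\n")
print(fit_tab, row.names = FALSE, digits = 4)

rec <- recovery_experiment(n_replicates = 100, truth = truth,
                           sigma_phi = 0.05, seed = seed)
utils::write.csv(rec$summary, "results/recovery_summary.csv",
                 row.names = FALSE)
cat("\nRecovery over 100 noisy replicates (sigma_phi = 0.05):\n")
print(rec$summary, row.names = FALSE, digits = 3)
cat(sprintf("Membrane-normal misorientation RMSE: %.2f deg\n",
            rec$normal_rmse_deg))
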