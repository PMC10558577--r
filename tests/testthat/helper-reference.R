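# Printed per-label metrics of the published benchmark (same 180-image test
# set, 20 positives per size code), frozen here as expected values:
# columns follow ACC SE SP F1 PPV NPV AUC (95% CI low-high), all normalised
# to 3 decimals.
reference_printed <- function() {
  dl <- rbind(
    c(1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000),
    c(0.994, 0.950, 1.000, 0.974, 1.000, 0.994, 0.975, 0.926, 1.000),
    c(1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000),
    c(0.994, 1.000, 0.994, 0.976, 0.952, 1.000, 0.997, 0.991, 1.000),
    c(1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000),
    c(0.994, 1.000, 0.994, 0.976, 0.952, 1.000, 0.997, 0.991, 1.000),
    c(0.994, 0.950, 1.000, 0.974, 1.000, 0.994, 0.975, 0.926, 1.000),
    c(1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000),
    c(1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000))
  cl <- rbind(
    c(0.994, 0.950, 1.000, 0.974, 1.000, 0.994, 0.975, 0.926, 1.000),
    c(0.983, 0.900, 0.994, 0.923, 0.947, 0.988, 0.947, 0.879, 1.000),
    c(0.989, 1.000, 0.988, 0.952, 0.909, 1.000, 0.994, 0.985, 1.000),
    c(1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000),
    c(0.989, 1.000, 0.988, 0.952, 0.909, 1.000, 0.994, 0.985, 1.000),
    c(0.989, 0.900, 1.000, 0.947, 1.000, 0.988, 0.950, 0.883, 1.000),
    c(1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000),
    c(1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000),
    c(1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000))
  out <- rbind(dl, cl)
  colnames(out) <- c("accuracy", "sensitivity", "specificity", "f1", "ppv",
                     "npv", "auc", "ci_low", "ci_high")
  data.frame(model = rep(c("deep_learning", "clustering"), each = 9),
             code = rep(size_labels()$code, 2), out,
             stringsAsFactors = FALSE)
}
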