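#!/usr/bin/env Rscript
# Load the packaged peptide bitterness dataset, report the partition
# structure and activity ranges, and screen the responses for outliers.

suppressMessages(library(bitterQSBR))
dir.create("results", showWarnings = FALSE)

d <- load_dataset(bitter_fixture_path())
cat("Loaded", nrow(d), "peptide records\n")

summary_tab <- do.call(rbind, lapply(split(d, d$partition), function(s) {
  data.frame(partition = s$partition[1], n = nrow(s),
             min_obs = min(s$observed), max_obs = max(s$observed))
}))
print(summary_tab, row.names = FALSE)
write.csv(summary_tab, "results/dataset_summary.csv", row.names = FALSE)

flagged <- screen_outliers(d$observed, threshold = 3)
cat("Standard-score outlier screen (|z| >= 3):", length(flagged),
    "flagged\n")

# response-space view used alongside the z-screen: distribution of the
# activities against a PCA of the per-partition prediction columns
pred_cols <- as.matrix(d[, c("pred_mlr", "pred_svm", "pred_ann")])
scores <- pca_scores(cbind(observed = d$observed, pred_cols), 2)
write.csv(data.frame(sequence = d$sequence, partition = d$partition,
                     pc1 = scores[, 1], pc2 = scores[, 2]),
          "results/pca_scores.csv", row.names = FALSE)
cat("PCA score map written to results/pca_scores.csv\n")
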