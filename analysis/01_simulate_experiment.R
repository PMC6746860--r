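#!/usr/bin/env Rscript

# Simulate the study's two inputs at desk scale: a genotype-phenotype
# landscape over N = 10 positions with a planted sparse interaction
# spectrum, and a two-channel FACS-seq barcode-count experiment over an
# N = 8 brightness landscape. Everything downstream (02-06) consumes the
# files written here.

suppressPackageStartupMessages(library(epicube))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 1L

## Sparse landscape: 20 interaction terms over orders 1-5, unimodal order
## profile peaking at 3rd-4th order, plus mild measurement noise.
spec <- synthetic_spec(
  n_positions = 10, n_terms = 20,
  order_weights = c(dnorm(1:5, 3.5, 1.5), rep(0, 5)),
  magnitude = "fixed", scale = 1, noise_sd = 0.02, offset = 0.8,
  seed = seed)
sim <- simulate_sparse_landscape(spec)
write_landscape(sim$landscape, file.path(out_dir, "landscape_n10.tsv"))
write_spectrum(sim$truth, file.path(out_dir, "truth_spectrum_n10.tsv"))
cat("N = 10 landscape:", length(sim$landscape$phenotypes), "genotypes,",
    sum(sim$truth$terms[-1] != 0), "planted interaction terms\n")

## FACS-seq counts: N = 8, 20 uniqueness barcodes per allele, 1e6 input
## reads per channel, top-1% gate, 1% planted 100x outlier barcodes.
## Parents anchor the bright end of their channels.
set.seed(seed)
y_true <- runif(2^8, 0.3, 1)
y_true[1] <- 1
y_true[2^8] <- 0.9
brightness <- landscape(y_true)
counts_sim <- simulate_counts_experiment(
  brightness,
  counts_sim_spec(barcodes_per_allele = 20, total_input_reads = 1e6,
                  gate_fraction = 0.01, outlier_rate = 0.01,
                  outlier_multiplier = 100, seed = seed))
write_counts(counts_sim$counts, file.path(out_dir, "counts_n8.tsv"))
write_landscape(brightness, file.path(out_dir, "true_brightness_n8.tsv"))
utils::write.table(counts_sim$outliers,
                   file.path(out_dir, "planted_outliers_n8.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("N = 8 counts:", nrow(counts_sim$counts), "barcode rows,",
    nrow(counts_sim$outliers), "planted outlier barcodes\n")
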