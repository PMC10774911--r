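#!/usr/bin/env Rscript
# Trains the scaled-down supervised localizer shipped with the package and
# writes it as a plain-text checkpoint:
#   Rscript scripts/train_supbd.R [--out inst/extdata/supbd_pretrained.txt]
#
# Configuration (the package's scaled-down study, see the methods
# vignette): 4,000 training pairs on 40-pixel windows, 8 feature channels,
# 4 residual blocks, peak-weighted pixelwise MSE, 12 epochs. PSF resize
# augmentation is narrowed to [0.8, 1.1] so every augmented kernel fits the
# 40-pixel training window; the full-scale configuration (250,000 pairs,
# 64 channels, resize up to 2 on 80-pixel windows) uses the same entry
# points with larger arguments. Takes roughly an hour on one CPU core.

suppressMessages(library(ulmkit))

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(i <- which(args == "--out")) && i < length(args))
  args[i + 1] else "inst/extdata/supbd_pretrained.txt"
dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)

g <- grid_spec(window = 40)
message("building training set ...")
ds <- build_training_set(4000, psf_pool = training_psf_pool(g), grid = g,
                         resize_range = c(0.8, 1.1), psf_variants = 96,
                         seed = 1234)
net <- build_supbd(supbd_spec(channels = 8, n_res = 4), seed = 99)
message("training ...")
fit <- train_supbd(net, ds,
                   sup_train_config(minibatch = 16, max_epochs = 12,
                                    peak_weight = 20, seed = 100),
                   verbose = TRUE)
print(glance(fit))
saveRDS(fit, "scratch/supbd_ship_fit.rds")
save_supbd_checkpoint(fit, out)
message("wrote ", out, " (", round(file.size(out) / 1024), " KB)")
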