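#!/usr/bin/env Rscript
# External validation on the PhysioNet MIT-BIH Atrial Fibrillation
# Database (optional; requires a manual download, never run in CI).
#
# Prepare the data (network access and the WFDB applications required):
#   1. download the afdb records, e.g.
#        wget -r -np https://physionet.org/files/afdb/1.0.0/
#   2. export the annotations of each record as text:
#        rdann -r afdb/<rec> -a qrs  > <rec>.qrs.txt   # beats
#        rdann -r afdb/<rec> -a atr  > <rec>.atr.txt   # rhythm changes
#      (a single combined export containing both beat and '+' rhythm
#       annotations also works)
#   3. concatenate each record's beat + rhythm annotations, sorted by
#      sample number, into <dir>/<rec>.txt
#
# usage: Rscript scripts/afdb_validation.R <annotation-dir> [window]

suppressPackageStartupMessages(library(srqafib))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: Rscript scripts/afdb_validation.R <annotation-dir> [window]\n",
       "This validation needs locally downloaded PhysioNet afdb ",
       "annotations exported as text (see the header of this script); ",
       "it is optional and entirely external to the test suite.")
}
dir <- args[1]
w <- if (length(args) >= 2) as.integer(args[2]) else 200L

files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
if (!length(files)) stop("no .txt annotation exports found under ", dir)

records <- lapply(files, import_physionet_afdb, fs = 250)
feats <- build_dataset(records, w = w)
message(nrow(feats), " windows (",
        sum(feats$label == "AF"), " AF / ",
        sum(feats$label == "nonAF"), " non-AF) at w = ", w)

model <- fit_af_model(feats)
roc <- roc_threshold(predict_af(model, feats), feats$label)
print(evaluate_threshold(predict_af(model, feats), feats$label, roc$tau))

cv <- kfold_cv(feats, k = 10, seed = 1)
print(cv$summary)
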