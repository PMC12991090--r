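# Shared fixtures, built lazily and cached for the whole test run. The
# expensive objects (simulated biopsies, trained models) are reused across
# test files to keep the suite within its time budget.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(builder)()
  .fixtures[[name]]
}

# Default-condition biopsy (the study conditions; used by most tests).
fx_sim <- function() fx("sim", function() {
  simulate_biopsy(simulation_config(seed = 42L))
})

# Error-free variant observation for the labeling oracle.
fx_sim_clean <- function() fx("sim_clean", function() {
  simulate_biopsy(simulation_config(seed = 43L, seq_error_rate = 0))
})

fx_site_dist <- function() fx("site_dist", function() {
  compute_site_distribution(fx_sim()$reads)
})

fx_truth_labels <- function() fx("truth_labels", function() {
  tr <- fx_sim()$truth
  data.frame(read_id = tr$read_id,
             label = ifelse(tr$origin == "tumor", "tumor", "non_tumor"),
             stringsAsFactors = FALSE)
})

# Ground-truth-labeled feature sets for a seeded subsample of the default
# biopsy (training-scale fixture).
fx_feats <- function() fx("feats", function() {
  sim <- fx_sim()
  set.seed(5)
  idx <- sample.int(length(sim$reads), 2500L)
  suppressMessages(build_feature_sets(sim$reads[idx], fx_site_dist(),
                                      sim$atlas,
                                      labels = fx_truth_labels()))
})

# Desk-scale transformer settings (embedding 64, 2 blocks) used everywhere a
# trained model is needed.
fx_model_cfg <- function(max_cpgs = 112L, ...) {
  model_config(embed_dim = 64L, n_heads = 2L, n_blocks = 2L, ff_dim = 128L,
               max_cpgs = max_cpgs,
               n_cell_types = length(fx_sim()$atlas$cell_types), ...)
}

fx_train_cfg <- function(max_epochs = 10L, ...) {
  train_config(seed = 7L, max_epochs = max_epochs, batch_size = 128L,
               lr = 1e-3, warmup_steps = 20L, ...)
}

# The main desk-scale transformer, trained once on the labeled subsample.
fx_fit <- function() fx("fit", function() {
  fit_read_classifier(fx_feats(), model_cfg = fx_model_cfg(),
                      train_cfg = fx_train_cfg(), verbose = FALSE)
})

# Cached predictions of the main model on the training-scale fixture.
fx_preds <- function() fx("preds", function() {
  predict(fx_fit(), fx_feats())
})

# 1.5 kb crops of a fresh seeded subsample, featurized against the
# full-read site distribution (shared by the perturbation criterion).
fx_crop_feats <- function() fx("crop_feats", function() {
  sim <- fx_sim()
  set.seed(6)
  idx <- sample.int(length(sim$reads), 2500L)
  cropped <- crop_reads(sim$reads[idx], 1500, seed = 3L)
  suppressMessages(build_feature_sets(cropped, fx_site_dist(), sim$atlas,
                                      labels = fx_truth_labels()))
})

# Short-read model for the perturbation experiments.
fx_crop_fit <- function() fx("crop_fit", function() {
  fit_read_classifier(fx_crop_feats(), model_cfg = fx_model_cfg(),
                      train_cfg = fx_train_cfg(max_epochs = 8L))
})

fx_test_auc <- function() fx("test_auc", function() {
  feats <- fx_feats()
  grp <- split_assign(feats, fx_fit()$split)
  y <- ifelse(vapply(feats, `[[`, "", "label") == "tumor", 1L, 0L)
  te <- which(grp == "test")
  evaluate_auc(y[te], predict(fx_fit(), feats[te]))
})

# Minimal hand-built feature set for unit tests.
toy_feature_set <- function(id = "r1", n = 5L, K = 3L, chrom = "chr1",
                            label = "tumor", seed = 1L) {
  set.seed(seed)
  atl <- matrix(stats::runif(n * K), n, K,
                dimnames = list(NULL, paste0("ct", seq_len(K))))
  structure(list(read_id = id, chrom = chrom,
                 meth = stats::runif(n),
                 pos_norm = sort(stats::runif(n, -0.5, 0.5)),
                 pct = matrix(stats::runif(n * 19), n, 19),
                 atlas = atl, atlas_missing = is.na(atl),
                 n_cpg = as.integer(n), label = label),
            class = "feature_set")
}

# Minimal synthetic read.
toy_read <- function(id = "r1", chrom = "chr1", start = 1000L,
                     cpg_pos = c(1100L, 1300L, 1500L),
                     meth_raw = c(10L, 250L, 128L), haplotype = 1L,
                     phase_block = "pb1", var_obs = NULL,
                     end = max(cpg_pos) + 100L) {
  methyl_read(read_id = id, chrom = chrom, start = start, end = end,
              cpg_pos = cpg_pos, meth_raw = meth_raw,
              haplotype = haplotype, phase_block = phase_block,
              var_obs = var_obs)
}
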