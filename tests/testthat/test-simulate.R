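# Properties of the synthetic biopsy generator.

test_that("simulation is deterministic given the seed", {
  a <- simulate_biopsy(simulation_config(seed = 3L, n_reads = 200L,
                                         n_normal_reads = 20L))
  b <- simulate_biopsy(simulation_config(seed = 3L, n_reads = 200L,
                                         n_normal_reads = 20L))
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads[[17]]$meth_raw, b$reads[[17]]$meth_raw)
  expect_identical(a$variants, b$variants)
})

test_that("per-segment tumor read fractions track the copy-number model", {
  sim <- fx_sim()
  cfg <- sim$config
  tr <- sim$truth
  seg <- sim$segments
  for (s in seq_len(nrow(seg))) {
    inseg <- tr[tr$segment == s, ]
    if (nrow(inseg) < 200) next
    f_exp <- expected_tumor_fraction(cfg$purity, seg$n_total[s],
                                     seg$n_normal[s])
    f_obs <- mean(inseg$origin == "tumor")
    se <- sqrt(f_exp * (1 - f_exp) / nrow(inseg))
    expect_lt(abs(f_obs - f_exp), 4 * se)
  }
})

test_that("tumor reads never sit on the lost haplotype of an LOH segment", {
  sim <- fx_sim()
  tr <- sim$truth
  seg <- sim$segments
  loh <- which(seg$n_minor == 0)
  expect_gt(length(loh), 0)
  for (s in loh) {
    inseg <- tr[tr$segment == s & tr$origin == "tumor", ]
    # the simulator assigns the retained haplotype label 1
    expect_true(all(inseg$haplotype == 1L))
  }
})

test_that("planted variant allele fractions match the expectation", {
  sim <- fx_sim()
  vt <- sim$variant_truth
  sup <- readorigin:::.variant_read_support(sim$reads, vt)
  cfg <- sim$config
  ok <- 0L
  for (i in seq_len(nrow(vt))) {
    n <- sup$cov_total[i]
    if (n < 15) next
    s <- vt$segment[i]
    f <- expected_variant_fraction(vt$mult[i], vt$ccf[i],
                                   cfg$purity,
                                   sim$segments$n_total[s],
                                   sim$segments$n_normal[s])
    se <- sqrt(f * (1 - f) / n)
    if (abs(sup$alt_total[i] / n - f) < 4 * se + 0.02) ok <- ok + 1L
    expect_lt(abs(sup$alt_total[i] / n - f), 6 * se + 0.05)
  }
  expect_gt(ok, 0.9 * sum(sup$cov_total >= 15))
})

test_that("read methylation reflects the cell-type profile", {
  sim <- simulate_biopsy(simulation_config(
    seed = 21L, n_reads = 300L, n_normal_reads = 10L,
    caller_noise_sd = 0.01))
  tr <- sim$truth
  sm <- sim$site_means
  site_key <- paste(sm$chrom, sm$pos)
  cor_own <- numeric(0)
  for (i in seq_len(100)) {
    r <- sim$reads[[i]]
    ct <- tr$cell_type[match(r$read_id, tr$read_id)]
    gi <- match(paste(r$chrom, r$cpg_pos), site_key)
    mu <- if (ct == "tumor") sm$tumor[gi] else sm$cell_types[gi, ct]
    if (sum(!is.na(mu)) < 20) next
    cor_own <- c(cor_own, cor(r$meth_prob, mu, use = "complete.obs"))
  }
  expect_gt(median(cor_own), 0.5)
})

test_that("cropping preserves CpG identity inside a shorter window", {
  sim <- simulate_biopsy(simulation_config(seed = 4L, n_reads = 100L,
                                           n_normal_reads = 10L))
  long <- Filter(function(r) r$end - r$start >= 10000, sim$reads)
  cropped <- crop_reads(long, 1500, seed = 2L)
  expect_length(cropped, length(long))
  for (i in c(1L, length(cropped))) {
    co <- cropped[[i]]
    or <- long[[i]]
    expect_lte(co$end - co$start, 1501)
    expect_gte(co$start, or$start)
    expect_lte(co$end, or$end)
    keep <- or$cpg_pos >= co$start & or$cpg_pos < co$end
    expect_identical(co$cpg_pos, or$cpg_pos[keep])
    expect_identical(co$meth_raw, or$meth_raw[keep])
  }
})

test_that("rescue variants are planted with the requested properties", {
  sim <- simulate_biopsy(simulation_config(
    seed = 31L, n_reads = 4000L, n_normal_reads = 400L, seq_error_rate = 0,
    n_rescue_true = 10L, n_rescue_artifact = 10L))
  vt <- sim$variant_truth
  sr <- sim$sr_variants
  expect_gte(sum(vt$type == "rescue_true"), 8L)
  expect_gte(sum(vt$type == "artifact"), 8L)
  # true rescue candidates pass the short-read caller, artifacts fail;
  # neither is called by the long-read caller
  expect_true(all(sr$sr_status[vt$type == "rescue_true"] == "PASS"))
  expect_true(all(sr$sr_status[vt$type == "artifact"] == "FAIL"))
  expect_true(all(sr$lr_status[vt$type %in% c("rescue_true", "artifact")] ==
                    "ABSENT"))
  # without sequencing error, artifact carriers are never tumor reads and
  # true rescue carriers are always tumor reads
  tr <- sim$truth
  art <- readorigin:::.supporting_read_ids(sim$reads,
                                           vt[vt$type == "artifact", ])
  expect_true(all(tr$origin[match(unique(unlist(art)),
                                  tr$read_id)] == "normal"))
  tru <- readorigin:::.supporting_read_ids(sim$reads,
                                           vt[vt$type == "rescue_true", ])
  expect_true(all(tr$origin[match(unique(unlist(tru)),
                                  tr$read_id)] == "tumor"))
})
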