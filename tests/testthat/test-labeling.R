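# Tumor/non-tumor labeling filters: every variant filter is exercised by a
# violating input constructed by hand.

seg1 <- data.frame(chrom = "chr1", start = 0, end = 2e6,
                   n_total = 2L, n_minor = 1L, n_normal = 2L)
clus1 <- data.frame(cluster_id = 1L, ccf = 1.0, n_variants = 10L)

# A locus-covering read: var_obs holds the base seen at pos 1000.
mk_read <- function(id, hap, base, block = "b1", start = 500,
                    end = 599500) {
  toy_read(id = id, start = start, end = end,
           cpg_pos = c(start + 100, start + 300),
           meth_raw = c(10L, 200L), haplotype = hap, phase_block = block,
           var_obs = data.frame(pos = 1000, base = base,
                                stringsAsFactors = FALSE))
}

mk_variant <- function(chrom = "chr1", pos = 1000, lr = "PASS",
                       sr = "PASS") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
             lr_status = lr, sr_status = sr, stringsAsFactors = FALSE)
}

# 4 alt reads on haplotype 1, 4 reference reads on haplotype 2, one phase
# block spanning ~600 kb: passes every filter at rho = 0.5.
base_reads <- c(
  lapply(1:4, function(i) mk_read(paste0("alt", i), 1L, "T")),
  lapply(1:4, function(i) mk_read(paste0("ref", i), 2L, "A")))

expect_kept <- function(variants, reads, ...) {
  out <- filter_tumor_label_variants(variants, reads, seg1, clus1,
                                     rho = 0.5, ...)
  expect_equal(nrow(out), 1L)
  invisible(out)
}
expect_dropped <- function(variants, reads, ...) {
  out <- filter_tumor_label_variants(variants, reads, seg1, clus1,
                                     rho = 0.5, ...)
  expect_equal(nrow(out), 0L)
}

test_that("the baseline variant passes all tumor-label filters", {
  v <- expect_kept(mk_variant(), base_reads)
  expect_equal(v$hap, 1L)
  expect_equal(v$cluster_id, 1L)
})

test_that("non-canonical contigs are excluded", {
  seg_m <- seg1; seg_m$chrom <- "chrM"
  reads <- lapply(base_reads, function(r) { r$chrom <- "chrM"; r })
  out <- filter_tumor_label_variants(mk_variant(chrom = "chrM"), reads,
                                     seg_m, clus1, rho = 0.5)
  expect_equal(nrow(out), 0L)
})

test_that("long-read caller status must be PASS", {
  expect_dropped(mk_variant(lr = "FAIL"), base_reads)
})

test_that("short-read status: strict wants PASS, relaxed only non-germline", {
  expect_dropped(mk_variant(sr = "FAIL"), base_reads,
                 cohort_mode = "strict")
  expect_kept(mk_variant(sr = "FAIL"), base_reads,
              cohort_mode = "relaxed")
  expect_dropped(mk_variant(sr = "GERMLINE"), base_reads,
                 cohort_mode = "relaxed")
})

test_that("a 400 kb phase block is excluded", {
  reads <- c(
    lapply(1:4, function(i) mk_read(paste0("alt", i), 1L, "T",
                                    end = 400000)),
    lapply(1:4, function(i) mk_read(paste0("ref", i), 2L, "A",
                                    end = 400000)))
  expect_dropped(mk_variant(), reads)
})

test_that("an SNV with 2 supporting reads is excluded", {
  reads <- c(
    lapply(1:2, function(i) mk_read(paste0("alt", i), 1L, "T")),
    lapply(1:6, function(i) mk_read(paste0("ref", i), 2L, "A")))
  expect_dropped(mk_variant(), reads)
})

test_that("variant reads split across haplotypes are excluded", {
  reads <- c(
    lapply(1:3, function(i) mk_read(paste0("alt", i), 1L, "T")),
    mk_read("alt4", 2L, "T") |> list(),
    lapply(1:4, function(i) mk_read(paste0("ref", i), 2L, "A")))
  expect_dropped(mk_variant(), reads)
})

test_that("loci covered by a single haplotype are excluded", {
  reads <- lapply(1:8, function(i) {
    mk_read(paste0("alt", i), 1L, if (i <= 4) "T" else "A")
  })
  expect_dropped(mk_variant(), reads)
})

test_that("cluster CCF of 1.1 or more is excluded", {
  # 6/8 alt reads: maximum-likelihood assignment prefers ccf 1.2 at
  # multiplicity 2 (expected 0.6) over ccf 1.0 (expected 0.5)
  clus_high <- data.frame(cluster_id = c(1L, 2L), ccf = c(1.0, 1.2),
                          n_variants = c(10L, 10L))
  reads <- c(
    lapply(1:6, function(i) mk_read(paste0("alt", i), 1L, "T")),
    lapply(1:2, function(i) mk_read(paste0("ref", i), 2L, "A")))
  out <- filter_tumor_label_variants(mk_variant(), reads, seg1, clus_high,
                                     rho = 0.5)
  expect_equal(nrow(out), 0L)
})

test_that("phase blocks inconsistent with f_minor are excluded", {
  # 28 vs 2 haplotype counts in the block: two-tailed binomial p << 0.1
  reads <- c(
    lapply(1:4, function(i) mk_read(paste0("alt", i), 1L, "T")),
    lapply(1:2, function(i) mk_read(paste0("ref", i), 2L, "A")),
    lapply(1:24, function(i) mk_read(paste0("pad", i), 1L, "A")))
  expect_dropped(mk_variant(), reads)
})

test_that("all-copies selection follows clonality and multiplicity", {
  # segment (2,1), rho .5: minor allele has 1 copy, major 1... use (3,1)
  seg <- data.frame(chrom = "chr1", start = 0, end = 2e6,
                    n_total = 3L, n_minor = 1L, n_normal = 2L)
  clus <- data.frame(cluster_id = c(1L, 2L), ccf = c(1.0, 0.4),
                     n_variants = c(20L, 5L))
  v <- mk_variant()
  v$segment <- 1L; v$hap <- 1L; v$cluster_id <- 1L
  v$multiplicity <- 2L; v$ccf <- 1.0
  v$alt_count <- 10L; v$total_count <- 16L
  v$alt_h1 <- 10L; v$alt_h2 <- 0L; v$cov_h1 <- 12L; v$cov_h2 <- 4L
  # haplotype 1 has more reads -> major allele (copy number 2);
  # multiplicity 2 >= 2 -> kept
  kept <- select_all_copies_variants(v, seg, clus, rho = 0.5)
  expect_equal(nrow(kept), 1L)
  # multiplicity 1 < major copy number 2 -> dropped
  v2 <- v; v2$multiplicity <- 1L
  expect_equal(nrow(select_all_copies_variants(v2, seg, clus, rho = 0.5)),
               0L)
  # subclonal cluster -> dropped
  v3 <- v; v3$cluster_id <- 2L; v3$ccf <- 0.4
  expect_equal(nrow(select_all_copies_variants(v3, seg, clus, rho = 0.5)),
               0L)
})

test_that("LOH labeling enforces the segment filters", {
  rho <- 0.6
  # f_lost at (n_total=2, rho=.6): 0.4/(1.2+0.8) = 0.2 -> 1:4 hap ratio
  mk_loh_read <- function(id, hap, start, len = 5e4, block = "L1",
                          chrom = "chr1") {
    toy_read(id = id, chrom = chrom, start = start, end = start + len,
             cpg_pos = start + c(100, 200), meth_raw = c(5L, 250L),
             haplotype = hap, phase_block = block)
  }
  mk_cohort <- function(seg_len, n = 50L) {
    starts <- round(seq(1000, seg_len - 6e4, length.out = n))
    haps <- rep(c(1L, 2L, 2L, 2L, 2L), length.out = n)
    lapply(seq_len(n), function(i) {
      mk_loh_read(paste0("r", i), haps[i], starts[i])
    })
  }
  seg_ok <- data.frame(chrom = "chr1", start = 0, end = 1.5e6,
                       n_total = 2L, n_minor = 0L, n_normal = 2L)
  lab <- label_non_tumor_by_loh(mk_cohort(1.5e6), seg_ok, rho)
  expect_gt(nrow(lab), 0)
  expect_true(all(lab$label == "non_tumor"))
  # 0.9 Mb segment -> no labels
  seg_short <- seg_ok; seg_short$end <- 0.9e6
  expect_equal(nrow(label_non_tumor_by_loh(mk_cohort(0.9e6), seg_short,
                                           rho)), 0L)
  # major copy number above 4 -> no labels
  seg_cn <- seg_ok; seg_cn$n_total <- 5L
  expect_equal(nrow(label_non_tumor_by_loh(mk_cohort(1.5e6), seg_cn, rho)),
               0L)
  # fewer than 20 reads -> no labels
  expect_equal(nrow(label_non_tumor_by_loh(mk_cohort(1.5e6, n = 15L),
                                           seg_ok, rho)), 0L)
  # |f_observed - f_minor| > 0.05: half the reads on the lost haplotype
  reads_dev <- mk_cohort(1.5e6)
  for (i in seq(1, 50, by = 2)) reads_dev[[i]]$haplotype <- 1L
  for (i in seq(2, 50, by = 2)) reads_dev[[i]]$haplotype <- 2L
  expect_equal(nrow(label_non_tumor_by_loh(reads_dev, seg_ok, rho)), 0L)
})

test_that("conflicting evidence excludes a read from the label set", {
  tv <- mk_variant()
  tv$hap <- 1L
  ac <- mk_variant(pos = 2000)
  ac$hap <- 1L
  # one read carries the tumor variant but misses the all-copies variant
  # on the same haplotype: tumor and non-tumor evidence conflict
  r <- toy_read("rc", start = 500, end = 5000,
                cpg_pos = c(600, 700), meth_raw = c(1L, 2L),
                haplotype = 1L, phase_block = "b1",
                var_obs = data.frame(pos = c(1000, 2000),
                                     base = c("T", "A"),
                                     stringsAsFactors = FALSE))
  lab <- label_reads(list(r), tv, ac)
  expect_equal(nrow(lab), 0L)
  expect_equal(attr(lab, "conflicts"), 1L)
})
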