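# Downstream consumers of per-read tumor probabilities.

test_that("expected-vs-observed fractions recover truth exactly on calls", {
  sim <- fx_sim()
  # perfect classifier: probability 1 for true tumor reads, 0 otherwise
  truth <- fx_truth_labels()
  ids <- vapply(sim$reads, `[[`, "", "read_id")
  probs <- as.numeric(truth$label[match(ids, truth$read_id)] == "tumor")
  ove <- observed_vs_expected(sim$reads, probs, sim$segments, sim$purity)
  ps <- ove$per_segment
  expect_gt(nrow(ps), 5)
  # with truth labels the observed fraction is binomially distributed
  # around the expectation in every segment
  expect_true(all(abs(ps$z) < 4))
  expect_equal(ps$se, sqrt(ps$expected * (1 - ps$expected) / ps$n_reads))
  expect_gt(ove$pearson_r, 0.95)
  # state aggregation pools reads over segments sharing a state
  st <- ove$per_state
  expect_equal(sum(st$n_reads), sum(ps$n_reads))
  expect_equal(sum(st$n_segments), nrow(ps))
})

test_that("segments below the read-count floor are dropped", {
  sim <- fx_sim()
  probs <- rep(0.9, length(sim$reads))
  ove <- observed_vs_expected(sim$reads, probs, sim$segments, sim$purity,
                              min_reads = 10 + length(sim$reads))
  expect_null(ove$per_segment)
  expect_true(is.na(ove$pearson_r))
})

test_that("rescue cohorts apply every candidate filter", {
  mk_support <- function(prefix, n, pos, base, chrom = "chr1") {
    lapply(seq_len(n), function(i) {
      toy_read(paste0(prefix, i), chrom = chrom, start = pos - 500,
               cpg_pos = pos - 400 + c(0L, 100L), meth_raw = c(5L, 250L),
               end = pos + 500,
               var_obs = data.frame(pos = pos, base = base,
                                    stringsAsFactors = FALSE))
    })
  }
  sr <- data.frame(chrom = "chr1", pos = c(1000, 5000, 9000, 13000, 17000),
                   ref = "A", alt = "T",
                   sr_status = c("PASS", "FAIL", "PASS", "PASS", "PASS"),
                   stringsAsFactors = FALSE)
  lr <- data.frame(chrom = "chr1", pos = c(9000, 13050),
                   ref = "A", alt = "T", lr_status = "PASS",
                   stringsAsFactors = FALSE)
  reads <- c(mk_support("a", 12, 1000, "T"),    # test candidate
             mk_support("b", 12, 5000, "T"),    # control candidate
             mk_support("c", 12, 9000, "T"),    # in the long-read call set
             mk_support("d", 12, 13000, "T"),   # within 100 bp of a PASS
             mk_support("e", 12, 17000, "T"))   # killed by normal support
  normals <- mk_support("n", 1, 17000, "T")
  cohort <- build_rescue_cohort(sr, lr, reads, normals, min_reads = 10L)
  expect_equal(nrow(cohort), 2L)
  expect_equal(cohort$pos, c(1000, 5000))
  expect_equal(cohort$cohort, c("test", "control"))
  expect_equal(cohort$n_support, c(12L, 12L))
  expect_equal(sort(cohort$support[[1]]), sort(paste0("a", 1:12)))
  # support below the floor drops the candidate
  expect_null(build_rescue_cohort(sr[1, ], lr, mk_support("a", 5, 1000, "T"),
                                  list(), min_reads = 10L))
})

test_that("cohort comparison separates tumor-supported candidates", {
  set.seed(2)
  n_var <- 30
  cohort <- data.frame(chrom = "chr1", pos = seq_len(2 * n_var) * 1000,
                       ref = "A", alt = "T",
                       cohort = rep(c("test", "control"), each = n_var),
                       n_support = 10L, stringsAsFactors = FALSE)
  cohort$support <- lapply(seq_len(2 * n_var), function(i) {
    paste0("v", i, "_r", 1:10)
  })
  probs <- c()
  for (i in seq_len(2 * n_var)) {
    p <- if (i <= n_var) runif(10, 0.6, 1) else runif(10, 0, 0.4)
    names(p) <- paste0("v", i, "_r", 1:10)
    probs <- c(probs, p)
  }
  res <- compare_cohorts(cohort, probs)
  expect_equal(res$test_median, 1)
  expect_equal(res$control_median, 0)
  expect_lt(res$p_value, 1e-6)
  expect_equal(nrow(res$table), 2 * n_var)
})

test_that("suspect somatic calls are flagged by mean support probability", {
  v <- data.frame(chrom = "chr1", pos = c(1000, 2000, 3000), ref = "A",
                  alt = "T", lr_status = c("PASS", "PASS", "FAIL"),
                  stringsAsFactors = FALSE)
  reads <- list(
    toy_read("r1", start = 500, end = 2500, cpg_pos = c(600L, 700L),
             meth_raw = c(1L, 2L),
             var_obs = data.frame(pos = c(1000, 2000), base = c("T", "A"))),
    toy_read("r2", start = 500, end = 2500, cpg_pos = c(600L, 700L),
             meth_raw = c(1L, 2L),
             var_obs = data.frame(pos = c(1000, 2000), base = c("T", "T"))))
  probs <- c(r1 = 0.9, r2 = 0.1)
  out <- flag_suspect_somatic_calls(v, reads, probs)
  expect_equal(nrow(out), 2L)             # FAIL call is not scored
  expect_equal(out$mean_prob, c(0.5, 0.1))
  expect_equal(out$suspect, c(FALSE, TRUE))
  expect_equal(out$n_support, c(2L, 1L))
  # chromosome whitelist removes everything
  expect_null(flag_suspect_somatic_calls(v, reads, probs, chroms = "chr9"))
})
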