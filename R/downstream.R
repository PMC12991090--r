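# Downstream applications of per-read origin calls: expected-vs-observed
# tumor read fractions across copy-number segments, and rescue of somatic
# SNVs missed by the long-read caller.

#' Expected versus observed tumor read fraction per copy-number segment
#'
#' Assigns each read to the copy-number segment it overlaps most, computes
#' the observed fraction of reads called tumor (probability >= 0.5) per
#' segment, and compares it with the expected tumor read fraction
#' rho * N_total / (rho * N_total + (1 - rho) * N_normal). Segments are also
#' aggregated by copy-number state (N_total, N_minor). The binomial
#' standard error sqrt(f (1 - f) / n) of each observed fraction is reported
#' against the expectation.
#'
#' @param reads List of [methyl_read()].
#' @param probs Tumor probabilities for `reads` (same order).
#' @param segments Copy-number segment table (see [load_segments()]).
#' @param rho Sample purity.
#' @param min_reads Segments with fewer reads are dropped (default 20).
#' @return List with `per_segment` and `per_state` data.frames (each with
#'   `expected`, `observed`, `n_reads`, `se`, `z`) and `pearson_r`, the
#'   per-segment correlation between expected and observed fractions.
#' @export
observed_vs_expected <- function(reads, probs, segments, rho,
                                 min_reads = 20L) {
  stopifnot(length(reads) == length(probs))
  segments <- validate_segments(segments)
  rt <- .read_table(reads)
  rt <- rt[match(vapply(reads, `[[`, "", "read_id"), rt$read_id)]
  seg_i <- .segment_of(rt$chrom, rt$start, rt$end, segments)
  call_tumor <- probs >= 0.5
  per_segment <- NULL
  for (s in seq_len(nrow(segments))) {
    inseg <- which(!is.na(seg_i) & seg_i == s)
    if (length(inseg) < min_reads) next
    f_exp <- expected_tumor_fraction(rho, segments$n_total[s],
                                     segments$n_normal[s])
    f_obs <- mean(call_tumor[inseg])
    se <- sqrt(f_exp * (1 - f_exp) / length(inseg))
    per_segment <- rbind(per_segment, data.frame(
      chrom = segments$chrom[s], start = segments$start[s],
      end = segments$end[s], n_total = segments$n_total[s],
      n_minor = segments$n_minor[s], n_reads = length(inseg),
      expected = f_exp, observed = f_obs, se = se,
      z = (f_obs - f_exp) / se, stringsAsFactors = FALSE))
  }
  if (is.null(per_segment)) {
    return(list(per_segment = NULL, per_state = NULL,
                pearson_r = NA_real_))
  }
  rownames(per_segment) <- NULL
  state <- paste(per_segment$n_total, per_segment$n_minor, sep = "/")
  per_state <- do.call(rbind, lapply(split(per_segment, state), function(g) {
    n <- sum(g$n_reads)
    f_exp <- g$expected[1L]
    f_obs <- sum(g$observed * g$n_reads) / n
    se <- sqrt(f_exp * (1 - f_exp) / n)
    data.frame(n_total = g$n_total[1L], n_minor = g$n_minor[1L],
               n_segments = nrow(g), n_reads = n, expected = f_exp,
               observed = f_obs, se = se, z = (f_obs - f_exp) / se,
               stringsAsFactors = FALSE)
  }))
  rownames(per_state) <- NULL
  r <- if (nrow(per_segment) >= 3 &&
             stats::sd(per_segment$expected) > 0 &&
             stats::sd(per_segment$observed) > 0) {
    stats::cor(per_segment$expected, per_segment$observed)
  } else NA_real_
  list(per_segment = per_segment, per_state = per_state, pearson_r = r)
}

#' Build rescue cohorts of short-read-only SNV candidates
#'
#' Candidate variants come from the short-read cohort and must be absent
#' from the long-read call set, supported by at least `min_reads` tumor
#' biopsy long reads, supported by zero reads in the matched normal biopsy,
#' and more than `min_dist_bp` away from any long-read PASS call. Candidates
#' passing the short-read caller form the test cohort; candidates the
#' short-read caller rejected form the control cohort.
#'
#' @param sr_variants Short-read variant table with `sr_status`
#'   ("PASS"/"FAIL") set (see [load_variants()]).
#' @param lr_variants Long-read variant table (its PASS positions define
#'   exclusion zones; any long-read call at the same position disqualifies a
#'   candidate).
#' @param reads Tumor biopsy long reads with `var_obs` at candidate loci.
#' @param normal_reads Matched normal biopsy long reads.
#' @param min_reads Minimum supporting tumor biopsy reads (default 10).
#' @param min_dist_bp Exclusion distance around long-read PASS calls
#'   (default 100).
#' @return `data.frame(chrom, pos, ref, alt, cohort, n_support)` with a
#'   list column `support` of supporting read ids.
#' @export
build_rescue_cohort <- function(sr_variants, lr_variants, reads,
                                normal_reads, min_reads = 10L,
                                min_dist_bp = 100L) {
  v <- sr_variants
  if (!nrow(v)) return(NULL)
  ## absent from the long-read call set
  in_lr <- paste(v$chrom, v$pos) %in%
    paste(lr_variants$chrom, lr_variants$pos)
  v <- v[!in_lr, , drop = FALSE]
  if (!nrow(v)) return(NULL)
  ## distance from long-read PASS calls
  lr_pass <- lr_variants[lr_variants$lr_status == "PASS", , drop = FALSE]
  near <- vapply(seq_len(nrow(v)), function(i) {
    same <- lr_pass$pos[lr_pass$chrom == v$chrom[i]]
    length(same) > 0 && min(abs(same - v$pos[i])) <= min_dist_bp
  }, NA)
  v <- v[!near, , drop = FALSE]
  if (!nrow(v)) return(NULL)
  sup <- .variant_read_support(reads, v)
  nsup <- .variant_read_support(normal_reads, v)
  keep <- sup$alt_total >= min_reads & nsup$alt_total == 0L
  v <- v[keep, , drop = FALSE]
  if (!nrow(v)) return(NULL)
  support <- .supporting_read_ids(reads, v)
  out <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref,
                    alt = v$alt,
                    cohort = ifelse(v$sr_status == "PASS", "test",
                                    "control"),
                    n_support = sup$alt_total[keep],
                    stringsAsFactors = FALSE)
  out$support <- support
  rownames(out) <- NULL
  out
}

# Read ids of the variant-allele-carrying reads for each variant row.
.supporting_read_ids <- function(reads, v) {
  key <- paste(v$chrom, v$pos)
  out <- rep(list(character(0)), nrow(v))
  for (r in reads) {
    if (is.null(r$var_obs) || nrow(r$var_obs) == 0) next
    hit <- match(paste(r$chrom, r$var_obs$pos), key)
    ok <- which(!is.na(hit))
    for (j in ok) {
      i <- hit[j]
      if (r$var_obs$base[j] == v$alt[i]) {
        out[[i]] <- c(out[[i]], r$read_id)
      }
    }
  }
  out
}

#' Compare tumor-call rates between rescue cohorts
#'
#' For each candidate variant, computes the proportion of its supporting
#' reads that the classifier calls tumor, then compares the test and
#' control cohorts' per-variant proportions with a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test.
#'
#' @param cohort Output of [build_rescue_cohort()].
#' @param probs Named vector of tumor probabilities (names = read ids).
#' @return List with `table` (per-variant cohort and tumor-call
#'   proportion), `test_median`, `control_median`, `p_value` and
#'   `statistic`.
#' @export
compare_cohorts <- function(cohort, probs) {
  stopifnot(!is.null(names(probs)))
  prop <- vapply(cohort$support, function(ids) {
    p <- probs[ids]
    p <- p[!is.na(p)]
    if (!length(p)) return(NA_real_)
    mean(p >= 0.5)
  }, 0)
  tab <- data.frame(chrom = cohort$chrom, pos = cohort$pos,
                    cohort = cohort$cohort, prop_tumor = prop,
                    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$prop_tumor), , drop = FALSE]
  a <- tab$prop_tumor[tab$cohort == "test"]
  b <- tab$prop_tumor[tab$cohort == "control"]
  wt <- if (length(a) && length(b)) {
    stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
  } else NULL
  list(table = tab,
       test_median = if (length(a)) stats::median(a) else NA_real_,
       control_median = if (length(b)) stats::median(b) else NA_real_,
       p_value = if (!is.null(wt)) wt$p.value else NA_real_,
       statistic = if (!is.null(wt)) unname(wt$statistic) else NA_real_)
}

#' Flag somatic calls whose supporting reads look non-tumor
#'
#' For each long-read PASS somatic SNV, averages the classifier tumor
#' probability over its variant-allele-carrying reads and flags calls whose
#' mean falls below `threshold` as suspect (likely artifacts or germline
#' leakage). Restrict to held-out chromosomes via `chroms` to avoid scoring
#' reads the classifier trained on.
#'
#' @param variants Long-read variant table; only `lr_status == "PASS"` rows
#'   are scored.
#' @param reads Reads with `var_obs` at the variant loci.
#' @param probs Named vector of tumor probabilities (names = read ids).
#' @param threshold Mean-probability cutoff (default 0.5).
#' @param chroms Optional chromosome whitelist.
#' @return `data.frame(chrom, pos, ref, alt, n_support, mean_prob,
#'   suspect)`.
#' @export
flag_suspect_somatic_calls <- function(variants, reads, probs,
                                       threshold = 0.5, chroms = NULL) {
  stopifnot(!is.null(names(probs)))
  v <- variants[variants$lr_status == "PASS", , drop = FALSE]
  if (!is.null(chroms)) v <- v[v$chrom %in% chroms, , drop = FALSE]
  if (!nrow(v)) return(NULL)
  support <- .supporting_read_ids(reads, v)
  mp <- vapply(support, function(ids) {
    p <- probs[ids]
    p <- p[!is.na(p)]
    if (!length(p)) return(NA_real_)
    mean(p)
  }, 0)
  out <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                    n_support = lengths(support), mean_prob = mp,
                    suspect = !is.na(mp) & mp < threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
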