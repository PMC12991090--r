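# Ground-truth read labeling from somatic variants, copy number, purity and
# phasing. Tumor labels come from reads carrying retained somatic SNVs;
# non-tumor labels come from haplotype-matched reads missing an "all copies"
# clonal SNV and from reads on the lost haplotype of clonal LOH segments.

# Segment index of maximum overlap for an interval; NA if no overlap.
.segment_of <- function(chrom, start, end, seg) {
  out <- rep(NA_integer_, length(start))
  for (i in seq_along(start)) {
    same <- which(seg$chrom == chrom[i])
    if (!length(same)) next
    ov <- pmin(end[i], seg$end[same]) - pmax(start[i], seg$start[same])
    if (all(ov <= 0)) next
    out[i] <- same[which.max(ov)]
  }
  out
}

#' Identify the clonal mutation cluster
#'
#' The clonal cluster is the cluster with cancer cell fraction between 0.9
#' and 1.1 that holds at least 30% of all somatic variants; if several
#' qualify the largest wins, and if none qualifies `NA` is returned.
#'
#' @param clusters `data.frame(cluster_id, ccf, n_variants)`.
#' @return Clonal `cluster_id`, or NA.
#' @export
identify_clonal_cluster <- function(clusters) {
  tot <- sum(clusters$n_variants)
  ok <- clusters$ccf >= 0.9 & clusters$ccf <= 1.1 &
    clusters$n_variants >= 0.3 * tot
  if (!any(ok)) return(NA_integer_)
  cand <- clusters[ok, , drop = FALSE]
  cand$cluster_id[which.max(cand$n_variants)]
}

#' Maximum-likelihood cluster and multiplicity assignment for an SNV
#'
#' For every cluster and every admissible multiplicity (1..major copy number
#' for the clonal cluster, exactly 1 for subclonal clusters), the binomial
#' likelihood of the observed alt/total read counts at the expected variant
#' fraction ([expected_variant_fraction()], capped at 1) is weighted by the
#' cluster size. A cluster's likelihood is the sum over its admissible
#' multiplicities; the best cluster is chosen first (ties to the higher CCF),
#' then the best multiplicity within it (ties to the lower multiplicity).
#'
#' @param alt_count,total_count Variant read counts.
#' @param clusters `data.frame(cluster_id, ccf, n_variants)`.
#' @param n_total,n_minor Local tumor copy numbers.
#' @param rho Sample purity.
#' @param n_normal Normal copy number (default 2).
#' @return `list(cluster_id, multiplicity)`; both NA when no admissible
#'   state exists.
#' @export
assign_cluster_multiplicity <- function(alt_count, total_count, clusters,
                                        n_total, n_minor, rho,
                                        n_normal = 2) {
  major <- n_total - n_minor
  clonal_id <- identify_clonal_cluster(clusters)
  best <- list(cluster_id = NA_integer_, multiplicity = NA_integer_)
  best_clu_lik <- -Inf; best_ccf <- -Inf
  for (ci in seq_len(nrow(clusters))) {
    is_clonal <- !is.na(clonal_id) &&
      clusters$cluster_id[ci] == clonal_id
    mults <- if (is_clonal) seq_len(max(major, 1L)) else 1L
    f <- pmin(1, expected_variant_fraction(mults, clusters$ccf[ci], rho,
                                           n_total, n_normal))
    lik <- stats::dbinom(alt_count, total_count, f) *
      clusters$n_variants[ci]
    clu_lik <- sum(lik)
    if (clu_lik > best_clu_lik + 1e-300 ||
        (abs(clu_lik - best_clu_lik) <= 1e-300 &&
           clusters$ccf[ci] > best_ccf)) {
      if (clu_lik > 0) {
        best_clu_lik <- clu_lik
        best_ccf <- clusters$ccf[ci]
        best <- list(cluster_id = clusters$cluster_id[ci],
                     multiplicity = mults[which.max(lik)])
      }
    }
  }
  best
}

#' Two-tailed phase-block consistency test
#'
#' Tests whether the minor-allele read count in a phase block is consistent
#' with the copy-number-expected minor fraction ([expected_minor_fraction()])
#' under Binomial(coverage, f_minor). The minor allele is taken as the
#' haplotype with the smaller read count. Blocks with p < 0.1 are rejected
#' by the calling filters.
#'
#' @param n_hap1,n_hap2 Haplotype-assigned read counts in the block (within
#'   the segment).
#' @param f_minor Expected minor-allele read fraction.
#' @param method Two-sided p-value convention, see [binom_two_tailed()].
#' @return The p-value; NA when coverage is zero.
#' @export
phase_block_consistency_test <- function(n_hap1, n_hap2, f_minor,
                                         method = "minlik") {
  cov <- n_hap1 + n_hap2
  if (cov == 0) return(NA_real_)
  binom_two_tailed(min(n_hap1, n_hap2), cov, f_minor, method = method)
}

# Phase-block/segment read counts per haplotype: data.table with one row per
# (phase_block, segment) combination carrying hap1/hap2 counts.
.block_hap_counts <- function(reads, seg) {
  rt <- .read_table(reads)
  rt <- rt[!is.na(rt$haplotype) & !is.na(rt$phase_block)]
  if (nrow(rt) == 0) return(NULL)
  rt$segment <- .segment_of(rt$chrom, rt$start, rt$end, seg)
  rt <- rt[!is.na(rt$segment)]
  agg <- rt[, list(n_hap1 = sum(haplotype == 1L),
                   n_hap2 = sum(haplotype == 2L),
                   block_start = min(start), block_end = max(end)),
            by = c("phase_block", "segment")]
  agg
}

#' Filter somatic SNVs usable as tumor read labels
#'
#' Applies the tumor-label variant filters: canonical autosome/chrX
#' location, long-read caller PASS plus (strict mode) short-read caller PASS
#' or (relaxed mode) not flagged germline by the short-read caller, a phase
#' block of at least `min_block_bp` (default 500 kb), at least
#' `min_alt_reads` (default 3) variant-carrying reads, reads present on both
#' haplotypes with all variant reads on a single haplotype, cluster CCF
#' below 1.1, and a phase block consistent with the expected minor-allele
#' fraction (two-tailed binomial p >= 0.1).
#'
#' @param variants Variant `data.frame` (see [load_variants()]).
#' @param reads List of [methyl_read()] with `var_obs` at the variant loci.
#' @param segments Copy-number segments.
#' @param clusters Cluster summary table.
#' @param rho Sample purity.
#' @param cohort_mode "strict" or "relaxed" short-read filter.
#' @param min_block_bp Minimum phase-block span.
#' @param min_alt_reads Minimum variant-carrying read count.
#' @param p_cut Binomial-test rejection threshold (default 0.1).
#' @return The retained variants with added columns `hap` (variant
#'   haplotype), `segment`, `cluster_id`, `multiplicity`, and per-haplotype
#'   read counts at the locus.
#' @export
filter_tumor_label_variants <- function(variants, reads, segments, clusters,
                                        rho,
                                        cohort_mode = c("strict", "relaxed"),
                                        min_block_bp = 5e5,
                                        min_alt_reads = 3L, p_cut = 0.1) {
  cohort_mode <- match.arg(cohort_mode)
  v <- variants
  ## caller status and contig filters
  keep <- grepl("^(chr)?([0-9]+|X)$", v$chrom) & v$lr_status == "PASS"
  keep <- keep & if (cohort_mode == "strict") v$sr_status == "PASS" else
    v$sr_status != "GERMLINE"
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0) return(v)

  ## per-variant read support from the reads themselves
  sup <- .variant_read_support(reads, v)
  v$alt_count <- sup$alt_total
  v$total_count <- sup$cov_total
  v$alt_h1 <- sup$alt_h1; v$alt_h2 <- sup$alt_h2
  v$cov_h1 <- sup$cov_h1; v$cov_h2 <- sup$cov_h2
  v$phase_block <- sup$block

  ## segment and cluster assignment
  v$segment <- .segment_of(v$chrom, v$pos, v$pos + 1, segments)
  blocks <- .block_hap_counts(reads, segments)
  res <- logical(nrow(v))
  v$hap <- NA_integer_
  v$cluster_id <- NA_integer_
  v$multiplicity <- NA_integer_
  v$ccf <- NA_real_
  for (i in seq_len(nrow(v))) {
    if (is.na(v$segment[i])) next
    s <- v$segment[i]
    ## >=3 variant reads, both haplotypes covered, single-haplotype variant
    if (v$alt_h1[i] + v$alt_h2[i] < min_alt_reads) next
    if (v$cov_h1[i] == 0 || v$cov_h2[i] == 0) next
    if (v$alt_h1[i] > 0 && v$alt_h2[i] > 0) next
    v$hap[i] <- if (v$alt_h1[i] > 0) 1L else 2L
    ## phase block size
    if (is.na(v$phase_block[i]) || is.null(blocks)) next
    b <- blocks[blocks$phase_block == v$phase_block[i] &
                  blocks$segment == s]
    if (nrow(b) == 0) next
    if (max(b$block_end) - min(b$block_start) < min_block_bp) next
    ## cluster CCF < 1.1
    asg <- assign_cluster_multiplicity(
      v$alt_count[i], v$total_count[i], clusters,
      segments$n_total[s], segments$n_minor[s], rho,
      segments$n_normal[s])
    if (is.na(asg$cluster_id)) next
    ccf <- clusters$ccf[match(asg$cluster_id, clusters$cluster_id)]
    if (ccf >= 1.1) next
    v$cluster_id[i] <- asg$cluster_id
    v$multiplicity[i] <- asg$multiplicity
    v$ccf[i] <- ccf
    ## phase-block consistency with expected minor fraction
    f_minor <- expected_minor_fraction(rho, segments$n_minor[s],
                                       segments$n_total[s],
                                       segments$n_normal[s])
    p <- phase_block_consistency_test(sum(b$n_hap1), sum(b$n_hap2), f_minor)
    if (is.na(p) || p < p_cut) next
    res[i] <- TRUE
  }
  v[res, , drop = FALSE]
}

# Read support of each variant: per-haplotype alt and coverage counts plus
# the modal phase block of its alt reads.
.variant_read_support <- function(reads, v) {
  n <- nrow(v)
  alt_h1 <- alt_h2 <- cov_h1 <- cov_h2 <- integer(n)
  alt_total <- cov_total <- integer(n)
  block <- rep(NA_character_, n)
  key <- paste(v$chrom, v$pos)
  for (r in reads) {
    if (is.null(r$var_obs) || nrow(r$var_obs) == 0) next
    hit <- match(paste(r$chrom, r$var_obs$pos), key)
    ok <- which(!is.na(hit))
    for (j in ok) {
      i <- hit[j]
      isalt <- r$var_obs$base[j] == v$alt[i]
      cov_total[i] <- cov_total[i] + 1L
      if (isalt) alt_total[i] <- alt_total[i] + 1L
      if (!is.na(r$haplotype)) {
        if (r$haplotype == 1L) {
          cov_h1[i] <- cov_h1[i] + 1L
          if (isalt) alt_h1[i] <- alt_h1[i] + 1L
        } else {
          cov_h2[i] <- cov_h2[i] + 1L
          if (isalt) alt_h2[i] <- alt_h2[i] + 1L
        }
      }
      if (isalt && is.na(block[i]) && !is.na(r$phase_block)) {
        block[i] <- r$phase_block
      }
    }
  }
  list(alt_h1 = alt_h1, alt_h2 = alt_h2, cov_h1 = cov_h1, cov_h2 = cov_h2,
       alt_total = alt_total, cov_total = cov_total, block = block)
}

#' Select clonal variants present on all copies of their haplotype
#'
#' Starting from variants that already pass
#' [filter_tumor_label_variants()], keeps those with a maximum-likelihood
#' assignment to the clonal cluster, assigns each to the major or minor
#' allele by which haplotype carries more reads at the locus, drops variants
#' whose multiplicity is below their allele's copy number, and applies a
#' two-tailed binomial test (p >= 0.1) of the variant-haplotype carrier
#' count against the all-copies expectation
#' ([expected_allcopies_read_fraction()]).
#'
#' @param tumor_variants Output of [filter_tumor_label_variants()].
#' @param segments,clusters,rho As in [filter_tumor_label_variants()].
#' @param p_cut Binomial-test rejection threshold (default 0.1).
#' @return The retained all-copies variants with an `allele` column.
#' @export
select_all_copies_variants <- function(tumor_variants, segments, clusters,
                                       rho, p_cut = 0.1) {
  v <- tumor_variants
  if (nrow(v) == 0) return(v)
  clonal <- identify_clonal_cluster(clusters)
  keep <- logical(nrow(v))
  v$allele <- NA_character_
  for (i in seq_len(nrow(v))) {
    if (is.na(clonal) || is.na(v$cluster_id[i]) ||
        v$cluster_id[i] != clonal) next
    s <- v$segment[i]
    ## allele by haplotype read majority at the locus
    hap <- v$hap[i]
    hap_cov <- c(v$cov_h1[i], v$cov_h2[i])
    v$allele[i] <- if (hap_cov[hap] >= hap_cov[3 - hap]) "major" else
      "minor"
    n_allele <- if (v$allele[i] == "major") {
      segments$n_total[s] - segments$n_minor[s]
    } else segments$n_minor[s]
    if (is.na(v$multiplicity[i]) || v$multiplicity[i] < n_allele) next
    f_reads <- expected_allcopies_read_fraction(rho, n_allele)
    n_hap <- hap_cov[hap]
    k <- c(v$alt_h1[i], v$alt_h2[i])[hap]
    if (n_hap == 0) next
    p <- binom_two_tailed(k, n_hap, min(1, f_reads))
    if (p < p_cut) next
    keep[i] <- TRUE
  }
  v[keep, , drop = FALSE]
}

#' Label non-tumor reads through clonal LOH segments
#'
#' In segments of loss of heterozygosity (minor copy number 0) every read on
#' the lost haplotype derives from normal cells. Eligible segments are at
#' least `min_segment_bp` (1 Mb) long with major copy number 1-4, coverage
#' of at least `min_coverage` (20) reads and both haplotypes observed.
#' Within them, haplotype blocks are kept when the observed lost-allele read
#' share is within `max_dev` (0.05) of the expected share
#' ([expected_lost_allele_fraction()]); the check is repeated on equal
#' sub-intervals as close to 100 kb as possible, and reads whose
#' maximum-overlap sub-interval fails are dropped. The lost haplotype is the
#' minority haplotype of each block.
#'
#' @param reads List of [methyl_read()].
#' @param segments Copy-number segments.
#' @param rho Sample purity.
#' @param min_segment_bp,min_coverage,max_dev,subinterval_bp Filter
#'   parameters as above.
#' @return `data.frame(read_id, label, evidence, locus)` of non-tumor
#'   labels.
#' @export
label_non_tumor_by_loh <- function(reads, segments, rho,
                                   min_segment_bp = 1e6, min_coverage = 20,
                                   max_dev = 0.05, subinterval_bp = 1e5) {
  rt <- .read_table(reads)
  rt$segment <- .segment_of(rt$chrom, rt$start, rt$end, segments)
  out <- list()
  for (s in seq_len(nrow(segments))) {
    if (segments$n_minor[s] != 0) next
    major <- segments$n_total[s]
    if (segments$end[s] - segments$start[s] < min_segment_bp) next
    if (major < 1 || major > 4) next
    inseg <- rt[!is.na(rt$segment) & rt$segment == s &
                  !is.na(rt$haplotype)]
    if (nrow(inseg) < min_coverage) next
    if (length(unique(inseg$haplotype)) < 2) next
    f_lost <- expected_lost_allele_fraction(rho, segments$n_total[s],
                                            segments$n_normal[s])
    for (blk in unique(inseg$phase_block)) {
      if (is.na(blk)) next
      inb <- inseg[inseg$phase_block == blk]
      lost_hap <- if (sum(inb$haplotype == 1L) <=
                        sum(inb$haplotype == 2L)) 1L else 2L
      f_obs <- mean(inb$haplotype == lost_hap)
      if (abs(f_obs - f_lost) > max_dev) next
      ## sub-interval re-check: equal intervals nearest 100 kb
      b0 <- max(min(inb$start), segments$start[s])
      b1 <- min(max(inb$end), segments$end[s])
      n_int <- max(1L, round((b1 - b0) / subinterval_bp))
      bounds <- seq(b0, b1, length.out = n_int + 1L)
      mid_ok <- rep(FALSE, n_int)
      iv <- pmin(pmax(findInterval(pmin(pmax(inb$start, b0), b1 - 1),
                                   bounds, rightmost.closed = TRUE),
                      1L), n_int)
      ## assign each read to its maximum-overlap sub-interval
      ov_iv <- integer(nrow(inb))
      for (j in seq_len(nrow(inb))) {
        ov <- pmin(inb$end[j], bounds[-1]) - pmax(inb$start[j],
                                                  bounds[-(n_int + 1L)])
        ov_iv[j] <- which.max(ov)
      }
      for (k in seq_len(n_int)) {
        here <- ov_iv == k
        if (!any(here)) next
        f_k <- mean(inb$haplotype[here] == lost_hap)
        mid_ok[k] <- abs(f_k - f_lost) <= max_dev
      }
      lab <- inb[ov_iv > 0 & mid_ok[ov_iv] & inb$haplotype == lost_hap]
      if (nrow(lab)) {
        out[[length(out) + 1L]] <- data.frame(
          read_id = lab$read_id, label = "non_tumor",
          evidence = "loh_lost_haplotype",
          locus = sprintf("%s:%d-%d", segments$chrom[s],
                          as.integer(segments$start[s]),
                          as.integer(segments$end[s])),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(read_id = character(0), label = character(0),
                      evidence = character(0), locus = character(0)))
  }
  unique(do.call(rbind, out))
}

#' Assemble per-read tumor / non-tumor labels
#'
#' Reads carrying the alt base of a retained tumor-label variant are labeled
#' tumor; haplotype-matched reads covering an all-copies variant locus with
#' the reference base are labeled non-tumor; LOH-derived non-tumor labels
#' are merged in. Reads receiving conflicting labels are excluded (and
#' counted in the `conflicts` attribute).
#'
#' @param reads List of [methyl_read()].
#' @param tumor_variants Output of [filter_tumor_label_variants()].
#' @param all_copies_variants Output of [select_all_copies_variants()].
#' @param loh_labels Output of [label_non_tumor_by_loh()] (optional).
#' @return `data.frame(read_id, label, evidence, locus)`; one row per
#'   labeled read.
#' @export
label_reads <- function(reads, tumor_variants, all_copies_variants,
                        loh_labels = NULL) {
  rows <- list()
  tv_key <- if (nrow(tumor_variants)) {
    paste(tumor_variants$chrom, tumor_variants$pos)
  } else character(0)
  ac_key <- if (nrow(all_copies_variants)) {
    paste(all_copies_variants$chrom, all_copies_variants$pos)
  } else character(0)
  for (r in reads) {
    if (is.null(r$var_obs) || nrow(r$var_obs) == 0) next
    keys <- paste(r$chrom, r$var_obs$pos)
    th <- match(keys, tv_key)
    hit <- which(!is.na(th))
    for (j in hit) {
      i <- th[j]
      if (r$var_obs$base[j] == tumor_variants$alt[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = r$read_id, label = "tumor", evidence = "snv_carrier",
          locus = sprintf("%s:%d", r$chrom,
                          as.integer(tumor_variants$pos[i])),
          stringsAsFactors = FALSE)
      }
    }
    ah <- match(keys, ac_key)
    hit <- which(!is.na(ah))
    for (j in hit) {
      i <- ah[j]
      if (is.na(r$haplotype) ||
          r$haplotype != all_copies_variants$hap[i]) next
      if (r$var_obs$base[j] != all_copies_variants$alt[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = r$read_id, label = "non_tumor",
          evidence = "missing_all_copies_snv",
          locus = sprintf("%s:%d", r$chrom,
                          as.integer(all_copies_variants$pos[i])),
          stringsAsFactors = FALSE)
      }
    }
  }
  lab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), label = character(0),
               evidence = character(0), locus = character(0))
  if (!is.null(loh_labels) && nrow(loh_labels)) {
    lab <- rbind(lab, loh_labels)
  }
  if (nrow(lab) == 0) {
    attr(lab, "conflicts") <- 0L
    return(lab)
  }
  per <- split(lab$label, lab$read_id)
  conflicted <- names(per)[vapply(per, function(x)
    length(unique(x)) > 1, TRUE)]
  lab <- lab[!lab$read_id %in% conflicted, , drop = FALSE]
  lab <- lab[!duplicated(lab$read_id), , drop = FALSE]
  rownames(lab) <- NULL
  attr(lab, "conflicts") <- length(conflicted)
  lab
}

#' Run the full labeling pipeline on a biopsy
#'
#' Convenience wrapper: filters tumor-label variants, selects all-copies
#' variants, derives LOH labels and assembles the final per-read label
#' table.
#'
#' @param reads List of [methyl_read()] with variant observations.
#' @param variants Somatic variant table ([load_variants()] format).
#' @param segments,clusters,rho Copy-number segments, cluster table and
#'   purity.
#' @param cohort_mode Short-read filter stringency, see
#'   [filter_tumor_label_variants()].
#' @return `list(labels, tumor_variants, all_copies_variants, loh_labels)`.
#' @export
derive_labels <- function(reads, variants, segments, clusters, rho,
                          cohort_mode = "strict") {
  tv <- filter_tumor_label_variants(variants, reads, segments, clusters,
                                    rho, cohort_mode = cohort_mode)
  ac <- select_all_copies_variants(tv, segments, clusters, rho)
  loh <- label_non_tumor_by_loh(reads, segments, rho)
  labels <- label_reads(reads, tv, ac, loh)
  list(labels = labels, tumor_variants = tv, all_copies_variants = ac,
       loh_labels = loh)
}
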