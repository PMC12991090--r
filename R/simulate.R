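#' Configuration for the synthetic bulk biopsy simulator
#'
#' Returns the default simulation conditions as a named list; any field can
#' be overridden through `...`. The defaults describe a desk-scale bulk tumor
#' biopsy: two 5 Mb training chromosomes plus four 2.5 Mb held-out
#' chromosomes (named after the conventional validation/test hold-out pairs),
#' ~20,000 reads of mean length 15 kb, a CpG every 100 bp, purity 0.6, a
#' clonal and one subclonal SNV cluster, copy-number segments including LOH,
#' and five normal cell populations mixed with the tumor.
#'
#' Methylation is modelled as per-site, per-cell-type Beta-distributed mean
#' propensities with Bernoulli molecule states; the caller reports the state
#' plus Gaussian noise, re-quantized to the 0-255 grid.
#'
#' @param ... Named overrides of any default field.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    seed = 1L,
    chromosomes = c(chr1 = 5e6, chr2 = 5e6, chr4 = 2.5e6, chr21 = 2.5e6,
                    chr5 = 2.5e6, chr22 = 2.5e6),
    segments = data.frame(
      chrom = c("chr1", "chr1", "chr1", "chr2", "chr2",
                "chr4", "chr4", "chr21", "chr21",
                "chr5", "chr5", "chr22", "chr22"),
      start = c(0, 2e6, 3.5e6, 0, 2.5e6, 0, 1.3e6, 0, 1.3e6,
                0, 1.3e6, 0, 1.3e6),
      end = c(2e6, 3.5e6, 5e6, 2.5e6, 5e6, 1.3e6, 2.5e6, 1.3e6, 2.5e6,
              1.3e6, 2.5e6, 1.3e6, 2.5e6),
      n_total = c(2, 1, 3, 2, 4, 2, 1, 2, 3, 2, 3, 1, 2),
      n_minor = c(1, 0, 1, 0, 1, 1, 0, 1, 1, 1, 1, 0, 0),
      n_normal = 2L),
    purity = 0.6,
    n_reads = 20000L,
    n_normal_reads = 2000L,
    read_length_mean = 15000, read_length_sd = 3000, read_length_min = 200,
    cpg_spacing = 100,
    cell_types = c("epithelial", "t_cell", "b_cell", "stromal",
                   "endothelial"),
    mixture_weights = c(0.40, 0.25, 0.15, 0.10, 0.10),
    beta_a = 0.3, beta_b = 0.3,
    tumor_diff_fraction = 0.2, tumor_diff_shift = 0.5,
    celltype_diff_fraction = 0.05,
    atlas_missing_fraction = 0.05,
    caller_noise_sd = 0.1,
    seq_error_rate = 0.002,
    unphased_fraction = 0.1,
    phase_block_min = 6e5, phase_block_max = 1.4e6,
    n_clonal_snvs = 40L, n_subclonal_snvs = 20L, subclonal_ccf = 0.4,
    n_rescue_true = 0L, n_rescue_artifact = 0L,
    artifact_carrier_rate = 0.35
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (abs(sum(cfg$mixture_weights) - 1) > 1e-8) {
    stop("mixture_weights must sum to 1")
  }
  if (cfg$purity <= 0 || cfg$purity > 1) stop("purity must be in (0, 1]")
  if (cfg$subclonal_ccf > 1) stop("subclonal CCF above 1 is infeasible")
  validate_segments(cfg$segments)
  class(cfg) <- "simulation_config"
  cfg
}

# Per-chromosome CpG grid (0-based positions).
.cpg_grid <- function(chrom_len, spacing) {
  seq(spacing / 2, chrom_len - 2, by = spacing)
}

#' Simulate a complete synthetic bulk tumor biopsy
#'
#' Generates reads with known per-read cell of origin, planted clonal and
#' subclonal SNVs with copy-number-consistent allele fractions, phase blocks,
#' LOH segments, a matched-normal read set, a cell-type methylation atlas
#' and a ground-truth table. Deterministic given `config$seed`.
#'
#' Each read's origin is drawn with probability equal to the local expected
#' tumor read share ([expected_tumor_fraction()]); tumor reads on a segment's
#' lost haplotype are never emitted in LOH regions; a tumor read carries a
#' planted SNV if the sampled cell carries it (its cluster CCF) and the
#' sampled haplotype copy carries it (multiplicity / haplotype copy number).
#' Planted rescue candidates are short-read-only calls: `rescue_true`
#' variants behave like clonal tumor SNVs, while `artifact` variants model
#' biopsy-specific artifacts observed on the tumor biopsy's non-tumor reads
#' (rate `artifact_carrier_rate`) and never in the matched normal biopsy.
#'
#' @param config A [simulation_config()].
#' @return Object of class `synthetic_biopsy`: lists of [methyl_read()]
#'   (`reads`, `normal_reads`), variant tables (`variants` long-read calls,
#'   `sr_variants` short-read calls, `variant_truth`), `segments`,
#'   `clusters`, `purity`, `atlas` (a `cell_type_atlas`), `atlas_df`, and
#'   `truth` (per-read origin table).
#' @export
simulate_biopsy <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  chroms <- names(config$chromosomes)
  seg <- config$segments
  rho <- config$purity

  ## per-site methylation propensities ------------------------------------
  grids <- lapply(chroms, function(cn)
    .cpg_grid(config$chromosomes[[cn]], config$cpg_spacing))
  names(grids) <- chroms
  n_sites <- vapply(grids, length, 0L)
  total_sites <- sum(n_sites)
  site_chrom <- rep(chroms, n_sites)
  site_pos <- unlist(grids, use.names = FALSE)
  K <- length(config$cell_types)
  base_mean <- stats::rbeta(total_sites, config$beta_a, config$beta_b)
  ct_means <- matrix(rep(base_mean, K), ncol = K,
                     dimnames = list(NULL, config$cell_types))
  for (k in seq_len(K)) {
    own <- stats::runif(total_sites) < config$celltype_diff_fraction
    ct_means[own, k] <- stats::rbeta(sum(own), config$beta_a, config$beta_b)
  }
  tumor_mean <- base_mean
  diff_site <- stats::runif(total_sites) < config$tumor_diff_fraction
  shift <- ifelse(base_mean[diff_site] < 0.5, config$tumor_diff_shift,
                  -config$tumor_diff_shift)
  tumor_mean[diff_site] <- pmin(0.98, pmax(0.02,
                                           base_mean[diff_site] + shift))
  ## phase blocks ----------------------------------------------------------
  block_bounds <- list()
  block_counter <- 0L
  block_ids <- list()
  for (cn in chroms) {
    len <- config$chromosomes[[cn]]
    b <- 0
    bounds <- 0
    while (b < len) {
      b <- b + stats::runif(1, config$phase_block_min, config$phase_block_max)
      bounds <- c(bounds, min(b, len))
    }
    block_bounds[[cn]] <- bounds
    ids <- block_counter + seq_len(length(bounds) - 1L)
    block_counter <- block_counter + length(ids)
    block_ids[[cn]] <- ids
  }

  ## plant variants --------------------------------------------------------
  seg$copies_h1 <- seg$n_total - seg$n_minor
  seg$copies_h2 <- seg$n_minor
  seg_len <- seg$end - seg$start
  plant <- function(n, type) {
    if (n == 0) return(NULL)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        s <- sample.int(nrow(seg), 1, prob = seg_len)
        copies <- c(seg$copies_h1[s], seg$copies_h2[s])
        if (sum(copies) == 0) next
        hap <- sample.int(2L, 1, prob = copies)
        pos <- floor(stats::runif(1, seg$start[s], seg$end[s] - 2))
        off <- pos %% config$cpg_spacing
        half <- config$cpg_spacing / 2
        if (off >= half - 1 && off <= half + 1) next  # avoid CpG grid
        break
      }
      mult <- switch(type,
        clonal = if (stats::runif(1) < 0.5) copies[hap] else 1L,
        subclonal = 1L,
        rescue_true = 1L,
        artifact = NA_integer_)
      ccf <- switch(type, clonal = 1, subclonal = config$subclonal_ccf,
                    rescue_true = 1, artifact = NA_real_)
      out[[i]] <- data.frame(
        chrom = seg$chrom[s], pos = pos, ref = "A", alt = "T",
        hap = hap, segment = s, copies_hap = copies[hap],
        cluster_id = switch(type, clonal = 1L, subclonal = 2L,
                            rescue_true = 1L, artifact = NA_integer_),
        ccf = ccf, mult = mult, type = type, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  vt <- rbind(plant(config$n_clonal_snvs, "clonal"),
              plant(config$n_subclonal_snvs, "subclonal"),
              plant(config$n_rescue_true, "rescue_true"),
              plant(config$n_rescue_artifact, "artifact"))
  if (!is.null(vt)) {
    # drop accidental duplicates and enforce >100 bp separation of
    # rescue/artifact candidates from long-read-callable variants
    vt <- vt[!duplicated(vt[, c("chrom", "pos")]), , drop = FALSE]
    lr_mask <- vt$type %in% c("clonal", "subclonal")
    if (any(!lr_mask) && any(lr_mask)) {
      keep <- vapply(which(!lr_mask), function(i) {
        same <- vt$chrom[lr_mask] == vt$chrom[i]
        !any(same & abs(vt$pos[lr_mask] - vt$pos[i]) <= 100)
      }, TRUE)
      vt <- vt[c(which(lr_mask), which(!lr_mask)[keep]), , drop = FALSE]
    }
    rownames(vt) <- NULL
  }

  ## reads -----------------------------------------------------------------
  make_reads <- function(n, pure_normal, id_prefix) {
    dens <- if (pure_normal) rep(1, nrow(seg)) else
      (rho * seg$n_total + (1 - rho) * seg$n_normal) / 2
    segi <- sample.int(nrow(seg), n, replace = TRUE,
                       prob = seg_len * dens)
    len <- pmax(config$read_length_min,
                round(stats::rnorm(n, config$read_length_mean,
                                   config$read_length_sd)))
    start <- floor(stats::runif(n, seg$start[segi], pmax(seg$start[segi] + 1,
                                                         seg$end[segi] - 1)))
    chrom <- seg$chrom[segi]
    chrom_len <- config$chromosomes[chrom]
    end <- pmin(start + len, chrom_len)
    f_tum <- if (pure_normal) rep(0, n) else
      expected_tumor_fraction(rho, seg$n_total[segi], seg$n_normal[segi])
    is_tumor <- stats::runif(n) < f_tum
    hap <- integer(n)
    p_h2_tum <- ifelse(seg$n_total[segi] > 0,
                       seg$copies_h2[segi] / pmax(seg$n_total[segi], 1), 0)
    hap[is_tumor] <- 1L + (stats::runif(sum(is_tumor)) <
                             p_h2_tum[is_tumor])
    hap[!is_tumor] <- sample(c(1L, 2L), sum(!is_tumor), replace = TRUE)
    ct <- rep(NA_character_, n)
    ct[!is_tumor] <- sample(config$cell_types, sum(!is_tumor),
                            replace = TRUE, prob = config$mixture_weights)
    unphased <- stats::runif(n) < config$unphased_fraction
    reads <- vector("list", n)
    chrom_idx_map <- stats::setNames(seq_along(chroms), chroms)
    for (i in seq_len(n)) {
      cn <- chrom[i]
      g <- grids[[cn]]
      lo <- ceiling((start[i] - config$cpg_spacing / 2) /
                      config$cpg_spacing) + 1L
      hi <- floor((end[i] - 1 - config$cpg_spacing / 2) /
                    config$cpg_spacing) + 1L
      idx_local <- if (hi >= lo && lo >= 1L) seq.int(max(1L, lo),
                                                     min(length(g), hi)) else
        integer(0)
      cp <- g[idx_local]
      gi <- if (length(idx_local)) {
        sum(n_sites[seq_len(chrom_idx_map[[cn]] - 1L)]) + idx_local
      } else integer(0)
      mu <- if (is_tumor[i]) tumor_mean[gi] else ct_means[gi, ct[i]]
      state <- stats::rbinom(length(mu), 1L, mu)
      p <- pmin(1, pmax(0, state + stats::rnorm(length(mu), 0,
                                                config$caller_noise_sd)))
      m_raw <- pmin(255L, as.integer(floor(p * 256)))
      blk <- block_ids[[cn]][findInterval(start[i], block_bounds[[cn]],
                                          rightmost.closed = TRUE)]
      vo <- NULL
      if (!is.null(vt)) {
        cover <- vt$chrom == cn & vt$pos >= start[i] & vt$pos < end[i]
        if (any(cover)) {
          vv <- vt[cover, , drop = FALSE]
          carrier <- logical(nrow(vv))
          for (j in seq_len(nrow(vv))) {
            if (vv$type[j] == "artifact") {
              # biopsy-specific artifacts: observed on non-tumor reads of
              # the tumor biopsy, never in the matched normal biopsy
              carrier[j] <- !pure_normal && !is_tumor[i] &&
                stats::runif(1) < config$artifact_carrier_rate
            } else {
              carrier[j] <- is_tumor[i] && hap[i] == vv$hap[j] &&
                stats::runif(1) < vv$ccf[j] &&
                stats::runif(1) < vv$mult[j] / max(vv$copies_hap[j], 1)
            }
          }
          if (config$seq_error_rate > 0) {
            flip <- stats::runif(nrow(vv)) < config$seq_error_rate
            carrier <- xor(carrier, flip)
          }
          vo <- data.frame(pos = vv$pos,
                           base = ifelse(carrier, vv$alt, vv$ref),
                           stringsAsFactors = FALSE)
        }
      }
      reads[[i]] <- methyl_read(
        read_id = sprintf("%s%06d", id_prefix, i), chrom = cn,
        start = start[i], end = end[i], cpg_pos = cp, meth_raw = m_raw,
        haplotype = if (unphased[i]) NA_integer_ else hap[i],
        phase_block = if (unphased[i]) NA else as.character(blk),
        var_obs = vo)
    }
    truth <- data.frame(
      read_id = vapply(reads, `[[`, "", "read_id"),
      origin = ifelse(is_tumor, "tumor", "normal"),
      cell_type = ifelse(is_tumor, "tumor", ct),
      haplotype = hap, chrom = chrom, start = start, end = end,
      segment = segi, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  }
  tum <- make_reads(config$n_reads, FALSE, "read")
  nrm <- if (config$n_normal_reads > 0) {
    make_reads(config$n_normal_reads, TRUE, "nread")
  } else list(reads = list(), truth = NULL)

  ## variant read counts and call tables -----------------------------------
  variants <- NULL
  sr_variants <- NULL
  if (!is.null(vt)) {
    counts <- .count_variant_support(tum$reads, vt)
    vt$alt_count <- counts$alt
    vt$total_count <- counts$total
    lr <- vt$type %in% c("clonal", "subclonal")
    variants <- data.frame(
      chrom = vt$chrom[lr], pos = vt$pos[lr], ref = vt$ref[lr],
      alt = vt$alt[lr], alt_count = vt$alt_count[lr],
      total_count = vt$total_count[lr], lr_status = "PASS",
      sr_status = "PASS", stringsAsFactors = FALSE)
    sr_variants <- data.frame(
      chrom = vt$chrom, pos = vt$pos, ref = vt$ref, alt = vt$alt,
      alt_count = vt$alt_count, total_count = vt$total_count,
      lr_status = ifelse(lr, "PASS", "ABSENT"),
      sr_status = ifelse(vt$type == "artifact", "FAIL", "PASS"),
      stringsAsFactors = FALSE)
  }

  ## atlas ------------------------------------------------------------------
  present <- stats::runif(total_sites) >= config$atlas_missing_fraction
  atlas_df <- data.frame(chrom = site_chrom[present],
                         pos = site_pos[present])
  atlas_df <- cbind(atlas_df, as.data.frame(ct_means[present, ,
                                                     drop = FALSE]))
  tmp <- tempfile(fileext = ".tsv")
  write_atlas(atlas_df, tmp)
  atlas <- load_atlas(tmp)
  unlink(tmp)

  clusters <- data.frame(cluster_id = c(1L, 2L),
                         ccf = c(1, config$subclonal_ccf),
                         n_variants = c(config$n_clonal_snvs,
                                        config$n_subclonal_snvs))

  structure(list(
    reads = tum$reads, truth = tum$truth,
    normal_reads = nrm$reads, normal_truth = nrm$truth,
    variants = variants, sr_variants = sr_variants, variant_truth = vt,
    segments = seg[, c("chrom", "start", "end", "n_total", "n_minor",
                       "n_normal")],
    clusters = clusters, purity = rho,
    atlas = atlas, atlas_df = atlas_df,
    site_means = list(chrom = site_chrom, pos = site_pos,
                      tumor = tumor_mean, cell_types = ct_means),
    config = config
  ), class = "synthetic_biopsy")
}

# Count alt / total read support per variant from read-level observations.
.count_variant_support <- function(reads, vt) {
  alt <- integer(nrow(vt))
  total <- integer(nrow(vt))
  key <- paste(vt$chrom, vt$pos)
  for (r in reads) {
    if (is.null(r$var_obs) || nrow(r$var_obs) == 0) next
    hit <- match(paste(r$chrom, r$var_obs$pos), key)
    ok <- !is.na(hit)
    if (!any(ok)) next
    total[hit[ok]] <- total[hit[ok]] + 1L
    isalt <- r$var_obs$base[ok] == vt$alt[hit[ok]]
    alt[hit[ok][isalt]] <- alt[hit[ok][isalt]] + 1L
  }
  list(alt = alt, total = total)
}

#' @export
print.synthetic_biopsy <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_biopsy  %d reads (%d normal-biopsy), ",
                     "%d planted variants, purity %.2f>\n"),
              length(x$reads), length(x$normal_reads),
              if (is.null(x$variant_truth)) 0L else nrow(x$variant_truth),
              x$purity))
  invisible(x)
}

#' Randomly crop reads to a fixed genomic length
#'
#' Each read longer than `target_length_bp` is replaced by a random
#' contiguous window of that length; CpGs and variant observations outside
#' the window are dropped. Shorter reads pass through unchanged.
#' Reproducible given `seed`.
#'
#' @param reads List of [methyl_read()] objects.
#' @param target_length_bp Window length in bp.
#' @param seed Integer seed.
#' @return List of cropped `methyl_read` objects.
#' @export
crop_reads <- function(reads, target_length_bp, seed = 1L) {
  set.seed(seed)
  lapply(reads, function(r) {
    len <- r$end - r$start
    if (len <= target_length_bp) return(r)
    w0 <- floor(stats::runif(1, r$start, r$end - target_length_bp + 1))
    w1 <- w0 + target_length_bp
    keep <- r$cpg_pos >= w0 & r$cpg_pos < w1
    vo <- r$var_obs
    if (!is.null(vo)) {
      vo <- vo[vo$pos >= w0 & vo$pos < w1, , drop = FALSE]
      if (nrow(vo) == 0) vo <- NULL
    }
    methyl_read(r$read_id, r$chrom, w0, w1, r$cpg_pos[keep],
                r$meth_raw[keep], r$haplotype, r$phase_block, vo)
  })
}

#' Write a synthetic biopsy to disk in standard formats
#'
#' Emits the exact formats the loaders consume: `reads.sam`,
#' `normal_reads.sam`, `variants_longread.vcf`, `variants_shortread.vcf`,
#' `segments.tsv`, `clusters.tsv`, `atlas.tsv`, `purity.tsv` and
#' `truth.tsv`.
#'
#' @param sim A `synthetic_biopsy`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_biopsy <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- sim$config$chromosomes
  write_reads_sam(sim$reads, file.path(dir, "reads.sam"), cl)
  if (length(sim$normal_reads)) {
    write_reads_sam(sim$normal_reads, file.path(dir, "normal_reads.sam"), cl)
  }
  if (!is.null(sim$variants)) {
    write_variants_vcf(sim$variants,
                       file.path(dir, "variants_longread.vcf"), cl)
    write_variants_vcf(sim$sr_variants,
                       file.path(dir, "variants_shortread.vcf"), cl)
  }
  data.table::fwrite(sim$segments, file.path(dir, "segments.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$clusters, file.path(dir, "clusters.tsv"),
                     sep = "\t")
  write_atlas(sim$atlas_df, file.path(dir, "atlas.tsv"))
  data.table::fwrite(data.frame(rho = sim$purity),
                     file.path(dir, "purity.tsv"), sep = "\t")
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}
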