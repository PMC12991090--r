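# Per-read model inputs: methylation vector, normalized CpG positions,
# 19-percentile sample site distributions and cell-type atlas values with a
# missing mask.

#' Build the feature set for one read
#'
#' @param read A [methyl_read()].
#' @param site_dist A `site_distribution` from [compute_site_distribution()].
#' @param atlas A `cell_type_atlas` from [load_atlas()].
#' @param label Optional class label ("tumor"/"non_tumor") to attach.
#' @return Object of class `feature_set` with fields `meth` (N), `pos_norm`
#'   (N), `pct` (N x 19), `atlas` (N x K with NA for missing sites),
#'   `atlas_missing` (logical N x K), `chrom`, `read_id`, `n_cpg`, `label`;
#'   NULL for reads with zero CpGs (counted by the caller).
#' @export
build_feature_set <- function(read, site_dist, atlas, label = NA_character_) {
  n <- length(read$cpg_pos)
  if (n == 0) return(NULL)
  pct <- lookup_site_percentiles(site_dist, rep(read$chrom, n),
                                 read$cpg_pos)
  atl <- lookup_atlas(atlas, rep(read$chrom, n), read$cpg_pos)
  miss <- is.na(atl)
  structure(list(
    read_id = read$read_id, chrom = read$chrom,
    meth = read$meth_prob,
    pos_norm = normalize_positions(read$cpg_pos),
    pct = pct, atlas = atl, atlas_missing = miss,
    n_cpg = n, label = label
  ), class = "feature_set")
}

#' Build feature sets for a list of reads
#'
#' Zero-CpG reads and reads covering only sites absent from the sample
#' distribution are skipped with a message. Labels are joined by read id
#' when a label table is supplied.
#'
#' @param reads List of [methyl_read()].
#' @param site_dist,atlas As in [build_feature_set()].
#' @param labels Optional `data.frame(read_id, label)`; unlabeled reads get
#'   NA labels.
#' @return List of `feature_set` objects.
#' @export
build_feature_sets <- function(reads, site_dist, atlas, labels = NULL) {
  lab_of <- if (!is.null(labels)) {
    stats::setNames(labels$label, labels$read_id)
  } else NULL
  ## one bulk site lookup for all reads (per-read match() would rescan the
  ## whole site table once per read)
  lens <- vapply(reads, function(r) length(r$cpg_pos), 0L)
  chrom_all <- rep(vapply(reads, `[[`, "", "chrom"), lens)
  pos_all <- unlist(lapply(reads, `[[`, "cpg_pos"), use.names = FALSE)
  pct_all <- lookup_site_percentiles(site_dist, chrom_all, pos_all)
  atl_all <- lookup_atlas(atlas, chrom_all, pos_all)
  ends <- cumsum(lens)
  out <- vector("list", length(reads))
  kept <- 0L
  skipped <- 0L
  for (ri in seq_along(reads)) {
    r <- reads[[ri]]
    n <- lens[ri]
    if (n == 0L) {
      skipped <- skipped + 1L
      next
    }
    lab <- if (!is.null(lab_of)) {
      l <- lab_of[r$read_id]
      if (is.na(l)) NA_character_ else unname(l)
    } else NA_character_
    rows <- (ends[ri] - n + 1L):ends[ri]
    atl <- atl_all[rows, , drop = FALSE]
    kept <- kept + 1L
    out[[kept]] <- structure(list(
      read_id = r$read_id, chrom = r$chrom,
      meth = r$meth_prob,
      pos_norm = normalize_positions(r$cpg_pos),
      pct = pct_all[rows, , drop = FALSE],
      atlas = atl, atlas_missing = is.na(atl),
      n_cpg = n, label = lab
    ), class = "feature_set")
  }
  if (skipped > 0) {
    message(sprintf("build_feature_sets: skipped %d read(s) without CpGs",
                    skipped))
  }
  out[seq_len(kept)]
}

#' Cap the number of CpGs in a feature set
#'
#' Reads with more than `max_n` CpGs (default 511) are subsampled uniformly
#' at random to `max_n` sites with relative order preserved. During training
#' the subsample is redrawn every epoch; at inference a single seeded draw
#' is used.
#'
#' @param fs A `feature_set`.
#' @param max_n Maximum CpG count (default 511).
#' @return A `feature_set` with `n_cpg <= max_n`.
#' @export
cap_cpgs <- function(fs, max_n = 511L) {
  if (fs$n_cpg <= max_n) return(fs)
  keep <- sort(sample.int(fs$n_cpg, max_n))
  fs$meth <- fs$meth[keep]
  fs$pos_norm <- fs$pos_norm[keep]
  fs$pct <- fs$pct[keep, , drop = FALSE]
  fs$atlas <- fs$atlas[keep, , drop = FALSE]
  fs$atlas_missing <- fs$atlas_missing[keep, , drop = FALSE]
  fs$n_cpg <- max_n
  fs
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set %s  %d CpGs  %d cell types  label=%s>\n",
              x$read_id, x$n_cpg, ncol(x$atlas),
              ifelse(is.na(x$label), "-", x$label)))
  invisible(x)
}
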