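#' Construct a per-read methylation record
#'
#' The unit record of the package: one primary alignment of one long read,
#' carrying the reference coordinates of the CpG sites it covers, the caller's
#' binned methylation integers and their midpoint-scaled probabilities, the
#' read's haplotype and phase-block assignment, and any observed bases at
#' variant loci of interest.
#'
#' @param read_id Read name.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open alignment span.
#' @param cpg_pos Strictly increasing integer vector of 0-based reference
#'   coordinates of covered CpG sites (forward-strand C).
#' @param meth_raw Integer vector in 0..255, parallel to `cpg_pos`.
#' @param haplotype 1, 2 or NA (unassigned).
#' @param phase_block Phase-block identifier or NA.
#' @param var_obs `data.frame(pos, base)` of observed bases at variant loci,
#'   or NULL.
#' @return An object of class `methyl_read`.
#' @export
methyl_read <- function(read_id, chrom, start, end, cpg_pos, meth_raw,
                        haplotype = NA_integer_, phase_block = NA,
                        var_obs = NULL) {
  cpg_pos <- as.numeric(cpg_pos)
  if (length(cpg_pos) != length(meth_raw)) {
    stop("cpg_pos and meth_raw lengths differ")
  }
  if (length(cpg_pos) > 1 && any(diff(cpg_pos) <= 0)) {
    stop("cpg_pos must be strictly increasing")
  }
  if (!is.na(haplotype) && !haplotype %in% c(1L, 2L)) {
    stop("haplotype must be 1, 2 or NA")
  }
  structure(list(
    read_id = as.character(read_id), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    cpg_pos = cpg_pos, meth_raw = as.integer(meth_raw),
    meth_prob = scale_methylation(as.integer(meth_raw)),
    haplotype = as.integer(haplotype),
    phase_block = if (is.na(phase_block)) NA_character_ else
      as.character(phase_block),
    var_obs = var_obs
  ), class = "methyl_read")
}

#' @export
print.methyl_read <- function(x, ...) {
  cat(sprintf("<methyl_read %s %s:%d-%d  %d CpGs  hap=%s  block=%s>\n",
              x$read_id, x$chrom, x$start, x$end, length(x$cpg_pos),
              ifelse(is.na(x$haplotype), "-", x$haplotype),
              ifelse(is.na(x$phase_block), "-", x$phase_block)))
  invisible(x)
}

# Flat data.table summary of a read list (one row per read).
.read_table <- function(reads) {
  data.table::data.table(
    read_id = vapply(reads, `[[`, "", "read_id"),
    chrom = vapply(reads, `[[`, "", "chrom"),
    start = vapply(reads, `[[`, 0, "start"),
    end = vapply(reads, `[[`, 0, "end"),
    n_cpg = vapply(reads, function(r) length(r$cpg_pos), 0L),
    haplotype = vapply(reads, `[[`, NA_integer_, "haplotype"),
    phase_block = vapply(reads, `[[`, NA_character_, "phase_block")
  )
}

#' Per-site sample methylation percentile distribution
#'
#' For every CpG site covered by at least one read, the 5%, 10%, ..., 95%
#' percentiles (19 values, linear interpolation between closest ranks) of the
#' methylation probabilities of all reads covering the site.
#'
#' @param reads List of [methyl_read()] objects.
#' @return An object of class `site_distribution` supporting
#'   [lookup_site_percentiles()].
#' @export
compute_site_distribution <- function(reads) {
  stopifnot(length(reads) >= 1)
  chrom <- rep(vapply(reads, `[[`, "", "chrom"),
               vapply(reads, function(r) length(r$cpg_pos), 0L))
  pos <- unlist(lapply(reads, `[[`, "cpg_pos"), use.names = FALSE)
  p <- unlist(lapply(reads, `[[`, "meth_prob"), use.names = FALSE)
  if (length(pos) == 0) stop("no CpG observations in read set")
  chrom_levels <- sort(unique(chrom))
  skey <- .site_key(chrom, pos, chrom_levels)
  dt <- data.table::data.table(skey = skey, p = p)
  data.table::setorder(dt, skey, p)
  pct <- dt[, as.list(.quantile_sorted(p)), by = skey]
  mat <- as.matrix(pct[, -1L])
  colnames(mat) <- paste0("q", seq(5, 95, by = 5))
  structure(list(key = pct$skey, mat = mat, chrom_levels = chrom_levels),
            class = "site_distribution")
}

#' Look up site percentile vectors
#'
#' @param dist A `site_distribution` from [compute_site_distribution()].
#' @param chrom Chromosome vector.
#' @param pos 0-based position vector.
#' @return N x 19 matrix; rows of NA for sites absent from the distribution.
#' @export
lookup_site_percentiles <- function(dist, chrom, pos) {
  idx <- match(chrom, dist$chrom_levels)
  key <- as.numeric(idx) * 1e9 + as.numeric(pos)
  out <- matrix(NA_real_, length(pos), 19L,
                dimnames = list(NULL, colnames(dist$mat)))
  hit <- match(key, dist$key)
  ok <- !is.na(hit)
  out[ok, ] <- dist$mat[hit[ok], , drop = FALSE]
  out
}

#' @export
print.site_distribution <- function(x, ...) {
  cat(sprintf("<site_distribution  %d sites on %d chromosomes>\n",
              length(x$key), length(x$chrom_levels)))
  invisible(x)
}
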