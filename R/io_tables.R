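# Tabular inputs: cell-type methylation atlas, copy-number segments,
# subclonal cluster summaries, and small-variant VCFs.

#' Load a cell-type methylation reference atlas
#'
#' Reads a TSV with columns `chrom`, `pos` (0-based CpG coordinate) and one
#' column per cell type or biological replicate. Columns sharing a name are
#' replicates and are averaged (ignoring missing values). Values must lie in
#' \[0, 1\].
#'
#' @param path Atlas TSV path.
#' @return Object of class `cell_type_atlas` supporting [lookup_atlas()].
#' @export
load_atlas <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (ncol(dt) < 3) stop("atlas needs chrom, pos and >=1 cell-type column")
  nm <- names(dt)[-(1:2)]
  vals <- as.matrix(dt[, -(1:2)])
  rng <- range(vals, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("atlas methylation values must lie in [0, 1]")
  }
  types <- unique(nm)
  mat <- matrix(NA_real_, nrow(vals), length(types),
                dimnames = list(NULL, types))
  for (ct in types) {
    cols <- which(nm == ct)
    mat[, ct] <- rowMeans(vals[, cols, drop = FALSE], na.rm = TRUE)
  }
  mat[is.nan(mat)] <- NA_real_
  chrom <- as.character(dt[[1]])
  pos <- as.numeric(dt[[2]])
  chrom_levels <- sort(unique(chrom))
  key <- .site_key(chrom, pos, chrom_levels)
  o <- order(key)
  structure(list(key = key[o], mat = mat[o, , drop = FALSE],
                 cell_types = types, chrom_levels = chrom_levels),
            class = "cell_type_atlas")
}

#' Look up atlas methylation vectors for CpG sites
#'
#' @param atlas A `cell_type_atlas`.
#' @param chrom Chromosome vector.
#' @param pos 0-based position vector.
#' @return N x K matrix of per-cell-type average methylation; rows/entries are
#'   NA where the site (or a cell type's value) is absent.
#' @export
lookup_atlas <- function(atlas, chrom, pos) {
  idx <- match(chrom, atlas$chrom_levels)
  key <- as.numeric(idx) * 1e9 + as.numeric(pos)
  out <- matrix(NA_real_, length(pos), ncol(atlas$mat),
                dimnames = list(NULL, atlas$cell_types))
  hit <- match(key, atlas$key)
  ok <- !is.na(hit)
  out[ok, ] <- atlas$mat[hit[ok], , drop = FALSE]
  out
}

#' @export
print.cell_type_atlas <- function(x, ...) {
  cat(sprintf("<cell_type_atlas  %d sites x %d cell types>\n",
              length(x$key), length(x$cell_types)))
  invisible(x)
}

#' Write a cell-type atlas TSV
#'
#' @param atlas_df `data.frame` with `chrom`, `pos` and cell-type columns.
#' @param path Output path.
#' @export
write_atlas <- function(atlas_df, path) {
  data.table::fwrite(atlas_df, path, sep = "\t")
  invisible(path)
}

#' Load allele-specific copy-number segments
#'
#' TSV with header `chrom start end n_total n_minor` (0-based half-open) and
#' optionally `n_normal` (default 2).
#'
#' @param path Segments TSV path.
#' @return `data.frame` of validated segments.
#' @export
load_segments <- function(path) {
  seg <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("chrom", "start", "end", "n_total", "n_minor")
  if (!all(need %in% names(seg))) {
    stop("segments file must have columns: ", paste(need, collapse = ", "))
  }
  if (!"n_normal" %in% names(seg)) seg$n_normal <- 2L
  validate_segments(seg)
  seg
}

#' Validate copy-number segments
#'
#' Checks the segment invariants: positive length, non-negative copy numbers,
#' and minor copy number not exceeding the major (n_total - n_minor).
#'
#' @param seg Segment `data.frame`.
#' @return `seg`, invisibly; stops on violation with the offending row.
#' @export
validate_segments <- function(seg) {
  bad <- which(seg$end <= seg$start)
  if (length(bad)) stop("segment with end <= start at row ", bad[1])
  bad <- which(seg$n_minor < 0 | seg$n_total < 0)
  if (length(bad)) stop("negative copy number at row ", bad[1])
  bad <- which(seg$n_total > 0 & seg$n_minor > seg$n_total - seg$n_minor)
  if (length(bad)) {
    stop("n_minor exceeds major copy number at row ", bad[1])
  }
  invisible(seg)
}

#' Load subclonal cluster summaries
#'
#' TSV with header `cluster_id ccf n_variants`: the position (cancer cell
#' fraction) and size (assigned variant count) of each mutation cluster.
#'
#' @param path Clusters TSV path.
#' @return `data.frame` of clusters.
#' @export
load_clusters <- function(path) {
  cl <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("cluster_id", "ccf", "n_variants")
  if (!all(need %in% names(cl))) {
    stop("clusters file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(cl$ccf < 0) || any(cl$n_variants < 0)) {
    stop("negative ccf or cluster size")
  }
  cl
}

#' Load somatic SNVs from a VCF
#'
#' Parses a VCF 4.x file, splits multi-allelic rows, drops non-SNV records
#' and converts positions to the package's internal 0-based convention. Two
#' caller-status fields are recognised: the `FILTER` column is taken as the
#' long-read caller status and an optional `SR=` INFO key as the short-read
#' caller status (`PASS`, `FAIL` or `GERMLINE`; missing defaults to `PASS`).
#' Optional `VC=` (variant read count) and `DP=` (total read count) INFO keys
#' populate the read counts.
#'
#' @param path VCF path.
#' @return `data.frame` with columns `chrom, pos, ref, alt, alt_count,
#'   total_count, lr_status, sr_status`.
#' @export
load_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      alt_count = integer(0), total_count = integer(0),
                      lr_status = character(0), sr_status = character(0)))
  }
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    data.frame(chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]) - 1,
               ref = fix$REF[i], alt = alts,
               filter = fix$FILTER[i], info = fix$INFO[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[nchar(out$ref) == 1 & nchar(out$alt) == 1 &
               out$alt != "*", , drop = FALSE]
  grab <- function(key) {
    vapply(out$info, function(s) {
      m <- regmatches(s, regexpr(paste0("(?:^|;)", key, "=([^;]+)"), s,
                                 perl = TRUE))
      if (length(m) == 0) NA_character_ else sub(paste0("^.*", key, "="), "", m)
    }, "", USE.NAMES = FALSE)
  }
  vc <- suppressWarnings(as.integer(grab("VC")))
  dp <- suppressWarnings(as.integer(grab("DP")))
  sr <- grab("SR")
  data.frame(chrom = out$chrom, pos = out$pos, ref = out$ref, alt = out$alt,
             alt_count = vc, total_count = dp,
             lr_status = ifelse(out$filter %in% c(".", ""), "PASS",
                                out$filter),
             sr_status = ifelse(is.na(sr), "PASS", sr),
             stringsAsFactors = FALSE)
}

#' Write somatic SNVs to a minimal VCF
#'
#' Inverse of [load_variants()]: emits a VCF 4.2 file with the long-read
#' caller status in FILTER and `VC`/`DP`/`SR` INFO keys.
#'
#' @param variants `data.frame` as returned by [load_variants()].
#' @param path Output path.
#' @param chrom_lengths Named vector for contig header lines.
#' @export
write_variants_vcf <- function(variants, path, chrom_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(c(
    "##INFO=<ID=VC,Number=1,Type=Integer,Description=\"Variant read count\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read count\">",
    "##INFO=<ID=SR,Number=1,Type=String,Description=\"Short-read caller status\">"
  ), con)
  if (!is.null(chrom_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                       as.integer(chrom_lengths)), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants)) {
    info <- sprintf("VC=%d;DP=%d;SR=%s", as.integer(variants$alt_count),
                    as.integer(variants$total_count), variants$sr_status)
    writeLines(paste(variants$chrom, as.integer(variants$pos) + 1L, ".",
                     variants$ref, variants$alt, ".", variants$lr_status,
                     info, sep = "\t"), con)
  }
  invisible(path)
}
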