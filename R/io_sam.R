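# Alignment I/O: modified-base-tagged reads in SAM/BAM.
#
# Methylation calls arrive as MM (modified-base positions, delta-encoded over
# the relevant canonical base in original read orientation) and ML (binned
# probabilities, one byte per call) tags. Reverse-strand C+m calls sit on the
# G of the reference CpG and are mapped back to the forward-strand C
# coordinate so both strands index a single site.

# Parse a CIGAR string into parallel query/reference block starts for the
# aligned ops (M/=/X). Returns also the total query length consumed.
.cigar_blocks <- function(cigar, pos0) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  q <- 0L; r <- pos0
  qs <- integer(0); rs <- integer(0); bl <- integer(0)
  for (i in seq_along(ops)) {
    op <- ops[i]; l <- lens[i]
    if (op %in% c("M", "=", "X")) {
      qs <- c(qs, q); rs <- c(rs, r); bl <- c(bl, l)
      q <- q + l; r <- r + l
    } else if (op %in% c("I", "S")) {
      q <- q + l
    } else if (op %in% c("D", "N")) {
      r <- r + l
    } # H, P consume nothing here
  }
  list(q_start = qs, r_start = rs, len = bl, q_len = q)
}

# Map 0-based query offsets to 0-based reference coordinates (NA if the base
# has no reference position: insertion or clip).
.query_to_ref <- function(blocks, q) {
  out <- rep(NA_real_, length(q))
  for (i in seq_along(blocks$len)) {
    inb <- q >= blocks$q_start[i] & q < blocks$q_start[i] + blocks$len[i]
    out[inb] <- blocks$r_start[i] + (q[inb] - blocks$q_start[i])
  }
  out
}

# Inverse mapping: reference coordinate to 0-based query offset.
.ref_to_query <- function(blocks, r) {
  out <- rep(NA_real_, length(r))
  for (i in seq_along(blocks$len)) {
    inb <- r >= blocks$r_start[i] & r < blocks$r_start[i] + blocks$len[i]
    out[inb] <- blocks$q_start[i] + (r[inb] - blocks$r_start[i])
  }
  out
}

# Decode one MM tag ("C+m" sub-tag) against the stored sequence, returning
# 0-based query offsets (into the stored, reference-oriented SEQ) of the
# called bases, in ML order. `reverse` follows FLAG 0x10: the delta encoding
# then runs over G bases right-to-left in the stored sequence.
.decode_mm <- function(mm, seq_chars, reverse) {
  sub <- regmatches(mm, regexpr("C\\+m[.?]?,[0-9,]*;", mm))
  if (length(sub) == 0) return(integer(0))
  deltas <- as.integer(strsplit(sub("^C\\+m[.?]?,?", "", sub(";$", "", sub)),
                                ",")[[1]])
  if (length(deltas) == 0 || anyNA(deltas)) return(integer(0))
  base_positions <- if (!reverse) which(seq_chars == "C") else
    rev(which(seq_chars == "G"))
  idx <- cumsum(deltas + 1L)
  if (length(base_positions) < max(idx)) {
    stop("MM tag addresses more bases than present in SEQ")
  }
  base_positions[idx] - 1L  # 0-based offsets in stored SEQ
}

#' Load methylation-tagged reads from a BAM or SAM file
#'
#' Extracts one [methyl_read()] per primary alignment. CpG methylation calls
#' are decoded from the MM/ML tags; calls without a reference coordinate
#' (insertions, soft clips) are dropped, and reverse-strand calls are mapped
#' to the forward-strand C of their CpG. Haplotype (HP) and phase-set (PS)
#' tags are carried through when present.
#'
#' @param path BAM file (indexed or index-free) or a plain-text SAM file,
#'   which is converted on the fly.
#' @param min_mapq Minimum mapping quality (default 0).
#' @param include_supplementary Keep supplementary alignments (default FALSE).
#' @param loci Optional `data.frame(chrom, pos)` (0-based) of variant loci;
#'   for overlapping reads the aligned base at each locus is recorded in
#'   `var_obs`.
#' @return List of `methyl_read` objects. Reads lacking MM/ML tags are
#'   skipped; the skipped count is reported via a message.
#' @export
load_reads <- function(path, min_mapq = 0, include_supplementary = FALSE,
                       loci = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = TRUE)
  } else {
    bam <- path
  }
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("MM", "ML", "HP", "PS"))
  res <- Rsamtools::scanBam(bam, param = prm)[[1]]
  n <- length(res$qname)
  reads <- vector("list", n)
  skipped <- 0L
  kept <- 0L
  for (i in seq_len(n)) {
    flag <- res$flag[i]
    if (bitwAnd(flag, 4L) > 0L) next                    # unmapped
    if (bitwAnd(flag, 256L) > 0L) next                  # secondary
    if (!include_supplementary && bitwAnd(flag, 2048L) > 0L) next
    if (!is.na(res$mapq[i]) && res$mapq[i] < min_mapq) next
    mm <- res$tag$MM[[i]]
    ml <- res$tag$ML[[i]]
    if (is.null(mm) || is.null(ml) || is.na(mm[1])) {
      skipped <- skipped + 1L
      next
    }
    seq_chars <- strsplit(as.character(res$seq[i]), "")[[1]]
    reverse <- bitwAnd(flag, 16L) > 0L
    qoff <- .decode_mm(mm, seq_chars, reverse)
    ml <- as.integer(ml)[seq_along(qoff)]
    pos0 <- res$pos[i] - 1L  # SAM is 1-based
    blocks <- .cigar_blocks(res$cigar[i], pos0)
    refpos <- .query_to_ref(blocks, qoff)
    # reverse-strand calls sit on the CpG's G: shift to the forward C
    if (reverse) refpos <- refpos - 1
    keep <- !is.na(refpos)
    refpos <- refpos[keep]; ml <- ml[keep]
    o <- order(refpos)
    refpos <- refpos[o]; ml <- ml[o]
    dup <- duplicated(refpos)
    refpos <- refpos[!dup]; ml <- ml[!dup]
    chrom <- as.character(res$rname[i])
    end <- if (length(blocks$r_start)) {
      max(blocks$r_start + blocks$len)
    } else pos0
    vo <- NULL
    if (!is.null(loci)) {
      here <- loci$chrom == chrom & loci$pos >= pos0 & loci$pos < end
      if (any(here)) {
        qp <- .ref_to_query(blocks, loci$pos[here])
        ok <- !is.na(qp)
        if (any(ok)) {
          vo <- data.frame(pos = loci$pos[here][ok],
                           base = seq_chars[qp[ok] + 1L])
        }
      }
    }
    hp <- res$tag$HP[[i]]
    ps <- res$tag$PS[[i]]
    kept <- kept + 1L
    reads[[kept]] <- methyl_read(
      read_id = res$qname[i], chrom = chrom, start = pos0, end = end,
      cpg_pos = refpos, meth_raw = ml,
      haplotype = if (is.null(hp) || is.na(hp)) NA_integer_ else
        as.integer(hp),
      phase_block = if (is.null(ps) || is.na(ps)) NA else as.character(ps),
      var_obs = vo)
  }
  if (skipped > 0) {
    message(sprintf("load_reads: skipped %d alignment(s) without MM/ML tags",
                    skipped))
  }
  reads[seq_len(kept)]
}

# Build the MM delta string for forward-strand reads whose called C bases sit
# at the given 0-based query offsets.
.encode_mm <- function(seq_chars, qoff) {
  cpos <- which(seq_chars == "C") - 1L
  idx <- match(qoff, cpos)
  if (anyNA(idx)) stop("modified offsets must be C bases in SEQ")
  deltas <- diff(c(0L, idx)) - 1L
  paste0("C+m?,", paste(deltas, collapse = ","), ";")
}

#' Write reads to a SAM file
#'
#' Emits one forward-strand primary alignment per read with MM/ML methylation
#' tags and HP/PS phasing tags. The sequence is synthetic: `C` at CpG sites,
#' recorded variant bases at their loci and `A` elsewhere; it exists to carry
#' the tag coordinate system, not sequence content.
#'
#' @param reads List of [methyl_read()] objects.
#' @param path Output SAM path.
#' @param chrom_lengths Named vector of chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, path, chrom_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (cn in names(chrom_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", cn,
                       as.integer(chrom_lengths[[cn]])), con)
  }
  lines <- vapply(reads, function(r) {
    len <- as.integer(r$end - r$start)
    seq_chars <- rep("A", len)
    off <- as.integer(r$cpg_pos - r$start)
    seq_chars[off + 1L] <- "C"
    if (!is.null(r$var_obs) && nrow(r$var_obs) > 0) {
      voff <- as.integer(r$var_obs$pos - r$start)
      inr <- voff >= 0 & voff < len
      seq_chars[voff[inr] + 1L] <- r$var_obs$base[inr]
    }
    mm <- .encode_mm(seq_chars, off)
    ml <- paste0("ML:B:C,", paste(r$meth_raw, collapse = ","))
    tags <- c(paste0("MM:Z:", mm), ml)
    if (!is.na(r$haplotype)) tags <- c(tags, sprintf("HP:i:%d", r$haplotype))
    if (!is.na(r$phase_block)) {
      tags <- c(tags, sprintf("PS:i:%d", as.integer(r$phase_block)))
    }
    paste(r$read_id, 0L, r$chrom, as.integer(r$start) + 1L, 60L,
          paste0(len, "M"), "*", 0L, 0L, paste(seq_chars, collapse = ""),
          "*", paste(tags, collapse = "\t"), sep = "\t")
  }, "")
  writeLines(lines, con)
  invisible(path)
}
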