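#' Expected variant allele fraction of a somatic SNV
#'
#' Expected fraction of reads carrying a somatic SNV at a locus, given the
#' mutation multiplicity, the cancer cell fraction of its mutation cluster,
#' sample purity and the local tumor/normal copy number:
#' \deqn{f = \frac{n c \rho}{\rho N_{Total} + (1-\rho) N_{Normal}}}
#'
#' @param n Mutation multiplicity (allelic copies per tumor cell carrying the
#'   mutation), integer >= 1.
#' @param ccf Cancer cell fraction of the mutation's cluster (clonal ~ 1).
#' @param rho Sample purity, in (0, 1].
#' @param n_total Total tumor copy number of the segment.
#' @param n_normal Copy number in normal cells (2 on autosomes).
#' @return Expected fraction of reads at the locus carrying the variant.
#' @examples
#' expected_variant_fraction(1, 1, 1, 2, 2)   # 0.5
#' expected_variant_fraction(2, 1, 0.5, 2, 2) # 0.5
#' @export
expected_variant_fraction <- function(n, ccf, rho, n_total, n_normal = 2) {
  stopifnot(n >= 1, ccf >= 0, rho >= 0, rho <= 1)
  denom <- rho * n_total + (1 - rho) * n_normal
  if (any(denom <= 0)) stop("zero or negative DNA content in segment")
  n * ccf * rho / denom
}

#' Expected fraction of reads from the minor allele in a segment
#'
#' Under local tumor copy number (N_Total, N_Minor) and purity rho, the
#' expected proportion of reads deriving from the minor parental allele:
#' \deqn{f_{minor} = \frac{\rho N_{Minor} + (1-\rho)}{\rho N_{Total} +
#'   (1-\rho) N_{Normal}}}
#' The (1-rho) numerator term is the one normal copy of that haplotype.
#'
#' @param rho Sample purity in (0, 1].
#' @param n_minor Minor-allele tumor copy number.
#' @param n_total Total tumor copy number.
#' @param n_normal Normal-cell copy number (2 on autosomes).
#' @return Expected minor-allele read fraction.
#' @export
expected_minor_fraction <- function(rho, n_minor, n_total, n_normal = 2) {
  stopifnot(rho >= 0, rho <= 1, n_minor >= 0, n_total >= n_minor)
  denom <- rho * n_total + (1 - rho) * n_normal
  if (any(denom <= 0)) stop("zero or negative DNA content in segment")
  (rho * n_minor + (1 - rho)) / denom
}

#' Expected variant-read fraction on a haplotype for an all-copies mutation
#'
#' If a clonal mutation sits on every tumor copy of one parental allele, the
#' expected fraction of that haplotype's reads carrying it is
#' \deqn{f_{reads} = \frac{\rho N_{allele}}{\rho N_{allele} + (1-\rho)}}
#' (the denominator is the haplotype's tumor copies plus its single normal
#' copy).
#'
#' @param rho Sample purity in (0, 1].
#' @param n_allele Tumor copy number of the allele carrying the mutation.
#' @return Expected fraction of variant-haplotype reads carrying the variant.
#' @export
expected_allcopies_read_fraction <- function(rho, n_allele) {
  stopifnot(rho >= 0, rho <= 1, n_allele >= 0)
  denom <- rho * n_allele + (1 - rho)
  if (any(denom <= 0)) stop("degenerate allele: no DNA content")
  rho * n_allele / denom
}

#' Expected read fraction of the lost allele in an LOH segment
#'
#' Special case of [expected_minor_fraction()] with N_Minor = 0: in a region
#' of loss of heterozygosity all reads on the lost haplotype derive from
#' normal cells, with expected share
#' \deqn{f_{minor} = \frac{1-\rho}{\rho N_{Total} + (1-\rho) N_{Normal}}}
#'
#' @inheritParams expected_minor_fraction
#' @return Expected lost-allele read fraction.
#' @export
expected_lost_allele_fraction <- function(rho, n_total, n_normal = 2) {
  stopifnot(rho >= 0, rho <= 1)
  denom <- rho * n_total + (1 - rho) * n_normal
  if (any(denom <= 0)) stop("zero or negative DNA content in segment")
  (1 - rho) / denom
}

#' Expected share of tumor-derived reads in a copy-number segment
#'
#' \deqn{f_{tumor} = \frac{\rho N_{Total}}{\rho N_{Total} +
#'   (1-\rho) N_{Normal}}}
#'
#' @inheritParams expected_minor_fraction
#' @return Expected fraction of reads in the segment with tumor origin.
#' @export
expected_tumor_fraction <- function(rho, n_total, n_normal = 2) {
  stopifnot(rho >= 0, rho <= 1, n_total >= 0)
  denom <- rho * n_total + (1 - rho) * n_normal
  if (any(denom <= 0)) stop("zero or negative DNA content in segment")
  rho * n_total / denom
}

#' Scale a binned methylation call to a probability
#'
#' Modification callers report per-CpG methylation as an integer M in 0..255,
#' meaning a probability in the bin (M/256, (M+1)/256). Each value is replaced
#' by the midpoint of its bin: (M + 0.5) / 256.
#'
#' @param m_raw Integer vector with values in 0..255.
#' @return Numeric vector of methylation probabilities in (0, 1).
#' @examples
#' scale_methylation(c(0L, 255L)) # 0.001953125 0.998046875
#' @export
scale_methylation <- function(m_raw) {
  if (any(is.na(m_raw)) || any(m_raw < 0) || any(m_raw > 255) ||
      any(m_raw != floor(m_raw))) {
    stop("m_raw must be integers in [0, 255]")
  }
  (m_raw + 0.5) / 256
}

#' Normalize CpG reference positions within a read
#'
#' Positions are shifted to start at zero, divided by a fixed 20 kb
#' denominator and centred:
#' \deqn{R_{norm} = \frac{R - \min(R)}{20000} - 0.5}
#' The fixed denominator implicitly encodes read length: reads longer than
#' 20 kb have maxima above 0.5 and are deliberately not clipped.
#'
#' @param positions Sorted numeric vector of reference CpG coordinates.
#' @param denominator Scaling constant in bp (default 20000).
#' @return Numeric vector of normalized positions (first element -0.5).
#' @export
normalize_positions <- function(positions, denominator = 20000) {
  if (length(positions) == 0) return(numeric(0))
  if (is.unsorted(positions, strictly = FALSE)) {
    stop("positions must be sorted increasingly")
  }
  (positions - positions[1]) / denominator - 0.5
}

#' Positive-class weight for imbalanced read-origin training
#'
#' Ratio of non-tumor to tumor reads, applied to the tumor (positive) class in
#' the weighted binary cross-entropy loss.
#'
#' @param n_nontumor,n_tumor Class counts in the training set.
#' @return Scalar weight.
#' @export
positive_weight <- function(n_nontumor, n_tumor) {
  if (n_tumor <= 0) stop("no tumor reads: positive weight undefined")
  n_nontumor / n_tumor
}
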