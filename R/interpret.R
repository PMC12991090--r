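# Interpretation of counterfactual perturbations: spatial clustering of the
# perturbed CpGs along the read and concordance of the methylation shifts
# with cell-type atlas profiles.

#' Spatial clustering coefficient of perturbed CpGs
#'
#' Measures whether the perturbed sites cluster along the read in CpG-index
#' coordinates. The observed statistic is the mean nearest-neighbor distance
#' (in CpG index units) among the perturbed sites; the null distribution is
#' obtained by drawing the same number of sites uniformly without
#' replacement from the read's CpG indices. The coefficient is
#' C = -log2(observed / mean(null)), so C > 0 indicates clustering beyond
#' chance and C = 0 exactly when every CpG on the read is perturbed (the
#' permuted sets are then all identical to the observed set).
#'
#' @param perturbed_idx Integer indices (1-based CpG positions along the
#'   read) of perturbed sites; at least 2 required.
#' @param n_cpg Total number of CpGs on the read.
#' @param n_perm Number of permutations (default 5000).
#' @param seed RNG seed for the permutation draw.
#' @return The clustering coefficient (NA when fewer than 2 perturbed
#'   sites).
#' @export
clustering_coefficient <- function(perturbed_idx, n_cpg, n_perm = 5000L,
                                   seed = 1L) {
  perturbed_idx <- sort(unique(as.integer(perturbed_idx)))
  k <- length(perturbed_idx)
  if (k < 2L || n_cpg < 2L) return(NA_real_)
  stopifnot(all(perturbed_idx >= 1L), all(perturbed_idx <= n_cpg))
  obs <- .mean_nn_dist(perturbed_idx)
  if (k == n_cpg) return(0)              # permutations are all identical
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    .mean_nn_dist(sort(sample.int(n_cpg, k)))
  }, 0)
  -log2(obs / mean(perm))
}

# Mean distance from each site to its nearest neighbor, for sorted indices.
.mean_nn_dist <- function(v) {
  gaps <- diff(v)
  n <- length(v)
  nn <- c(gaps[1L],
          if (n > 2L) pmin(gaps[-(n - 1L)], gaps[-1L]),
          gaps[n - 1L])
  mean(nn)
}

#' Cell-type concordance of perturbation shifts
#'
#' For each cell type, marker CpGs are sites where the atlas value deviates
#' from the across-cell-type mean by at least `marker_diff`. Over the
#' successfully converted reads, each perturbed marker CpG is scored by
#' whether the perturbation moved the methylation toward or away from the
#' cell type's atlas value; for perturbations that decreased the tumor
#' probability the sign is inverted, so counts always accumulate in the
#' direction of increasing tumor character. Cell types with fewer than
#' `min_markers` perturbed marker sites are dropped.
#'
#' @param result A `perturbation_result` from [perturb_batch()].
#' @param min_markers Minimum perturbed marker sites per cell type
#'   (default 20).
#' @param marker_diff Minimum atlas deviation defining a marker site
#'   (default 0.5).
#' @return `data.frame(cell_type, n_sites, toward_tumor, away_tumor,
#'   prop_toward)`.
#' @export
cell_type_concordance <- function(result, min_markers = 20L,
                                  marker_diff = 0.5) {
  stopifnot(inherits(result, "perturbation_result"))
  if (is.null(result$table)) return(NULL)
  conv <- which(result$table$success)
  if (!length(conv)) return(NULL)
  ctypes <- colnames(result$features[[1L]]$atlas)
  toward <- stats::setNames(integer(length(ctypes)), ctypes)
  away <- toward
  for (i in conv) {
    fs <- result$features[[i]]
    d <- result$delta[[i]]
    pid <- which(d != 0)
    if (!length(pid)) next
    x_new <- pmin(1, pmax(0, fs$meth + d))
    to_tumor <- result$table$direction[i] == "non_tumor_to_tumor"
    atl <- fs$atlas[pid, , drop = FALSE]
    row_mean <- rowMeans(atl, na.rm = TRUE)
    for (k in seq_along(ctypes)) {
      a <- atl[, k]
      is_marker <- !is.na(a) & !is.nan(row_mean) &
        abs(a - row_mean) >= marker_diff
      if (!any(is_marker)) next
      closer <- abs(x_new[pid][is_marker] - a[is_marker]) <
        abs(fs$meth[pid][is_marker] - a[is_marker])
      n_to <- if (to_tumor) sum(closer) else sum(!closer)
      toward[k] <- toward[k] + n_to
      away[k] <- away[k] + sum(is_marker) - n_to
    }
  }
  n_sites <- toward + away
  keep <- n_sites >= min_markers
  if (!any(keep)) return(NULL)
  out <- data.frame(cell_type = ctypes[keep],
                    n_sites = unname(n_sites[keep]),
                    toward_tumor = unname(toward[keep]),
                    away_tumor = unname(away[keep]),
                    stringsAsFactors = FALSE)
  out$prop_toward <- out$toward_tumor / out$n_sites
  rownames(out) <- NULL
  out
}

#' Summarize a perturbation run
#'
#' @param result A `perturbation_result`.
#' @param n_perm Permutations for the clustering coefficient.
#' @param seed Seed for the permutation draws.
#' @return List with `n_reads`, `n_converted`, `conversion_rate`,
#'   `mean_frac_perturbed` (over converted reads), `frac_increased`
#'   (perturbed CpGs with raised methylation, over converted reads), and
#'   `clustering` (per-read data.frame of coefficients by direction).
#' @export
summarize_perturbations <- function(result, n_perm = 5000L, seed = 1L) {
  stopifnot(inherits(result, "perturbation_result"))
  tab <- result$table
  if (is.null(tab)) {
    return(list(n_reads = 0L, n_converted = 0L, conversion_rate = NA_real_,
                mean_frac_perturbed = NA_real_, frac_increased = NA_real_,
                clustering = NULL))
  }
  conv <- which(tab$success)
  cl <- if (length(conv)) {
    data.frame(
      read_id = tab$read_id[conv],
      direction = tab$direction[conv],
      coefficient = vapply(seq_along(conv), function(j) {
        i <- conv[j]
        clustering_coefficient(which(result$delta[[i]] != 0),
                               tab$n_cpg[i], n_perm = n_perm,
                               seed = .derive_seed(seed, j))
      }, 0),
      stringsAsFactors = FALSE)
  } else NULL
  up <- sum(tab$n_increased[conv])
  tot <- sum(tab$n_perturbed[conv])
  list(n_reads = nrow(tab), n_converted = length(conv),
       conversion_rate = length(conv) / nrow(tab),
       mean_frac_perturbed = if (length(conv)) {
         mean(tab$frac_perturbed[conv])
       } else NA_real_,
       frac_increased = if (tot) up / tot else NA_real_,
       clustering = cl)
}
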