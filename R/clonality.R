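## -- post-count barcode clonality analysis ------------------------------------

round_half_up <- function(x) floor(x + 0.5)

#' Normalize and threshold a barcode count table
#'
#' Scales each sample to a common reference depth (default: the mean of the
#' sample totals), rounds half-up to integers, zeroes every normalized count
#' below `min_count` (default 1000, the upstream arbitrary read-count
#' threshold), and drops barcodes left with all-zero rows. The removed read
#' mass per sample is reported in `attr(, "removed_mass")` and the scale
#' factors in `attr(, "scale_factors")`. Within-sample barcode ranking is
#' preserved.
#'
#' @param counts barcode x sample integer matrix.
#' @param min_count threshold below which normalized counts are zeroed.
#' @param reference_depth `"mean"` or a fixed depth.
#' @return Filtered integer matrix with attributes.
#' @export
preprocess_counts <- function(counts, min_count = 1000, reference_depth = "mean") {
  validate_counts(counts)
  if (!nrow(counts) || !ncol(counts)) stopf("empty count table")
  totals <- colSums(counts)
  zero <- names(totals)[totals == 0]
  if (length(zero))
    stopf("sample(s) with zero total count: %s", paste(zero, collapse = ", "))
  ref <- if (identical(reference_depth, "mean")) mean(totals)
         else assert_scalar_num(reference_depth, "reference_depth", positive = TRUE)
  factors <- ref / totals
  norm <- round_half_up(sweep(counts, 2L, factors, "*"))
  removed <- norm < min_count
  removed_mass <- colSums(norm * removed) / colSums(norm)
  norm[removed] <- 0
  keep <- rowSums(norm) > 0
  out <- norm[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  attr(out, "removed_mass") <- removed_mass
  attr(out, "scale_factors") <- factors
  out
}

#' Remove index-hopping bleed-through
#'
#' Dominant clones on patterned flow cells bleed a small fraction of their
#' reads into every other sample. For each barcode, counts below
#' `hop_fraction` times the barcode's maximum count over samples are set to
#' 0; the maximal sample's count is never removed. The filter is
#' deterministic and idempotent.
#'
#' @param counts barcode x sample integer matrix (typically from
#'   [preprocess_counts()]).
#' @param hop_fraction relative-maximum cut in `[0, 1)` (default 0.05).
#' @return Filtered matrix (same dimensions; attributes preserved).
#' @export
filter_index_hopping <- function(counts, hop_fraction = 0.05) {
  validate_counts(counts)
  if (hop_fraction < 0 || hop_fraction >= 1)
    stopf("'hop_fraction' must be in [0, 1)")
  if (!nrow(counts)) return(counts)
  M <- apply(counts, 1L, max)
  out <- counts
  out[counts < hop_fraction * M] <- 0L
  attributes(out) <- attributes(counts)
  out
}

#' Clone composition summary
#'
#' Per sample: the clone frequency vector (counts over the sample total,
#' descending), the top-clone fraction, the number of clones at or above a
#' frequency floor, and a monoclonality flag (top frequency >= 0.99, the
#' criterion that at least 99% of tumor cells express one barcode).
#' Globally: the number of retained barcodes and the fraction present in
#' exactly one sample.
#'
#' @param counts filtered barcode x sample matrix.
#' @param frequency_floor clone-count floor (default 0.001).
#' @param monoclonal_threshold top-clone fraction for the monoclonal call
#'   (default 0.99).
#' @return List of class `mn_clones`: `per_sample` (data.frame),
#'   `frequencies` (named list of descending named vectors), `n_barcodes`,
#'   `uniqueness_fraction`.
#' @export
clone_summary <- function(counts, frequency_floor = 0.001,
                          monoclonal_threshold = 0.99) {
  if (!is.matrix(counts) || !nrow(counts) || all(counts == 0))
    stopf("empty count table")
  validate_counts(counts)
  totals <- colSums(counts)
  per_sample <- list(); freqs <- list()
  for (s in colnames(counts)) {
    if (totals[[s]] == 0) {
      per_sample[[s]] <- data.frame(sample = s, total = 0L,
                                    top_clone_fraction = NA_real_,
                                    n_clones = 0L, monoclonal = NA)
      next
    }
    f <- counts[, s] / totals[[s]]
    f <- sort(f[f > 0], decreasing = TRUE)
    freqs[[s]] <- f
    per_sample[[s]] <- data.frame(
      sample = s, total = totals[[s]], top_clone_fraction = f[[1L]],
      n_clones = sum(f >= frequency_floor),
      monoclonal = f[[1L]] >= monoclonal_threshold,
      stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, per_sample)
  rownames(per_sample) <- NULL
  present <- rowSums(counts > 0)
  retained <- present > 0
  structure(list(per_sample = per_sample, frequencies = freqs,
                 n_barcodes = sum(retained),
                 uniqueness_fraction = sum(present == 1L) / sum(retained)),
            class = "mn_clones")
}
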