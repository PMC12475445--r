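#' @keywords internal
"_PACKAGE"

#' @importFrom stats complete.cases cutree dist hclust kruskal.test median
#'   p.adjust pnorm rbeta rbinom rmultinom rnorm rpois runif sd wilcox.test
#'   fisher.test chisq.test setNames quantile lm coef as.dendrogram
#' @importFrom utils read.csv write.csv head tail
NULL

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  invisible(x)
}

## closed vocabularies shared across readers and the generator
TISSUE_CLASSES <- c("tumor", "acinar", "adm", "duct", "islet", "fibrosis",
                    "immune", "nerve", "vessel", "other")
COMPARTMENTS <- c("lobule", "stroma", "other", "none")
ATROPHY_STAGES <- c("minimal", "mild", "moderate", "severe", "end-stage")
INVASION_CATEGORIES <- c("unaffected", "inflamed", "early_invasion",
                         "late_invasion")

#' Closed tissue-class vocabulary
#'
#' The tissue classes recognized throughout the package: tumor cells plus the
#' lobular and stromal constituents distinguished by the upstream segmentation
#' (acinar, ADM, duct, islet, fibrosis, immune, nerve, vessel, other).
#'
#' @return Character vector of accepted class names.
#' @export
tissue_classes <- function() TISSUE_CLASSES

#' Compartment and annotation vocabularies
#'
#' @return `compartments()`: the compartment labels (`lobule`, `stroma`,
#'   `other`, `none`). `atrophy_stages()`: the five-grade lobular atrophy
#'   vocabulary. `invasion_categories()`: the four lobule invasion states.
#' @export
compartments <- function() COMPARTMENTS

#' @rdname compartments
#' @export
atrophy_stages <- function() ATROPHY_STAGES

#' @rdname compartments
#' @export
invasion_categories <- function() INVASION_CATEGORIES

## deterministic 32-bit sub-seed derivation (keeps values < 2^31)
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label names), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return A single number (ARI).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
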