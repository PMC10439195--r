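#' Robust centered log-ratio transform
#'
#' Per sample, counts get a pseudo-count and are divided by the geometric
#' mean computed over the taxa that were observed (count > 0) in that
#' sample only; log-ratios of unobserved taxa are encoded as 0 and flagged
#' in a mask. Restricting the geometric mean to observed taxa avoids the
#' downward bias that sparse zero-heavy samples impose on the plain CLR.
#'
#' @param table an [otu_table()] or a non-negative numeric matrix
#'   (taxa x samples).
#' @param pseudo_count value added to counts before taking logs (default 1).
#' @param mask_zeros if `TRUE` (default) the geometric mean is taken over
#'   originally non-zero entries and zeros stay at 0 (robust CLR); if
#'   `FALSE` a plain CLR of `x + pseudo_count` over all taxa is returned
#'   with an all-`TRUE` mask.
#' @return a `clr_matrix`: list with `values` (taxa x samples), logical
#'   `mask` of originally observed entries, and `pseudo_count`. For every
#'   sample the mean of `values` over mask-true entries is 0.
#' @export
#' @examples
#' m <- matrix(c(1L, 3L, 0L, 2L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' robust_clr(m)$values
robust_clr <- function(table, pseudo_count = 1, mask_zeros = TRUE) {
  x <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  if (any(x < 0)) abort("Counts must be non-negative.")
  zero_tot <- colSums(x) == 0
  if (any(zero_tot)) {
    abort(paste0("Samples with zero total count: ",
                 paste(colnames(x)[zero_tot], collapse = ", ")))
  }
  mask <- if (mask_zeros) x > 0 else matrix(TRUE, nrow(x), ncol(x))
  lx <- log(x + pseudo_count)
  vals <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    mj <- mask[, j]
    gj <- mean(lx[mj, j])   # log geometric mean over observed taxa
    vals[mj, j] <- lx[mj, j] - gj
  }
  structure(list(values = vals, mask = mask, pseudo_count = pseudo_count),
            class = "clr_matrix")
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat("<clr_matrix> ", nrow(x$values), " taxa x ", ncol(x$values),
      " samples, pseudo-count ", x$pseudo_count,
      ", ", round(100 * mean(!x$mask), 1), "% masked zeros\n", sep = "")
  invisible(x)
}

clr_values <- function(x) {
  if (inherits(x, "clr_matrix")) x$values else as.matrix(x)
}

#' Per-sample relative abundances
#'
#' @param table an [otu_table()] or non-negative matrix (taxa x samples).
#' @return matrix whose columns sum to 1.
#' @export
relative_abundance <- function(table) {
  x <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  tot <- colSums(x)
  if (any(tot == 0)) {
    abort(paste0("Samples with zero total: ",
                 paste(colnames(x)[tot == 0], collapse = ", ")))
  }
  sweep(x, 2, tot, "/")
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d_{jk} = \sum_i |m_{ij} - m_{ik}| / \sum_i (m_{ij} + m_{ik})},
#' computed between sample columns. Defined for non-negative data only;
#' pass relative abundances (or counts) rather than CLR values, whose
#' negative entries make the index meaningless — use
#' [aitchison_distance()] for a CLR-space dissimilarity.
#'
#' @param m non-negative matrix (taxa x samples) or an [otu_table()]
#'   (converted to relative abundances first).
#' @return a [stats::dist] with `metric` attribute `"bray_curtis"`.
#' @export
bray_curtis <- function(m) {
  if (inherits(m, "otu_table")) m <- relative_abundance(m)
  m <- as.matrix(m)
  if (any(m < 0)) {
    abort("Bray-Curtis is undefined for negative values; use aitchison_distance() for CLR data.")
  }
  d <- vegan::vegdist(t(m), method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Aitchison distance (Euclidean distance between CLR sample vectors)
#'
#' @param clr a `clr_matrix` from [robust_clr()] or a numeric matrix
#'   (taxa x samples).
#' @return a [stats::dist] with `metric` attribute `"euclidean"`.
#' @export
aitchison_distance <- function(clr) {
  v <- clr_values(clr)
  d <- dist(t(v))
  attr(d, "metric") <- "euclidean"
  d
}

#' Euclidean distance between samples in environmental space
#'
#' @param env data frame with a `sample_id` column and numeric
#'   environmental variables (temperature, salinity, oxygen, nitrate,
#'   chlorophyll-a, particle flux, ...).
#' @param variables optional character vector selecting variables; default
#'   all numeric columns.
#' @param standardize z-score each variable first (default `TRUE`) so all
#'   contribute on unit scale.
#' @return a [stats::dist] labelled by sample id.
#' @export
env_distance <- function(env, variables = NULL, standardize = TRUE) {
  env <- as_tibble(env)
  ids <- if ("sample_id" %in% names(env)) env$sample_id else as.character(seq_len(nrow(env)))
  num <- env[vapply(env, is.numeric, logical(1))]
  if (!is.null(variables)) num <- num[variables]
  if (!ncol(num)) abort("No numeric environmental variables selected.")
  has_na <- rowSums(is.na(num)) > 0
  if (any(has_na)) {
    abort(paste0("Missing environmental values for samples: ",
                 paste(ids[has_na], collapse = ", ")))
  }
  x <- as.matrix(num)
  if (standardize) x <- scale(x)
  rownames(x) <- ids
  d <- dist(x)
  attr(d, "metric") <- "euclidean"
  d
}
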