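#' Shannon diversity of an abundance vector
#'
#' Natural-log Shannon index H = -sum p_i log p_i over the non-zero relative
#' abundances, computed via [vegan::diversity()].
#'
#' @param x non-negative abundance vector with positive sum.
#' @return H in nats.
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(x) <= 0) stop("all-zero abundance vector", call. = FALSE)
  unname(vegan::diversity(x, index = "shannon"))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' sum |x_i - y_i| / sum (x_i + y_i), via [vegan::vegdist()].
#'
#' @param x,y equal-length non-negative abundance vectors, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(x) + sum(y) <= 0) stop("both vectors are all-zero", call. = FALSE)
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Retention of baseline entities in a later sample
#'
#' Measures how much of an early community persists: the entities present in
#' both samples, the share of the later sample's richness they represent, and
#' the share of the later sample's abundance they carry.
#'
#' @param baseline,later abundance vectors over the same entity set (named or
#'   positionally aligned); presence is `value > 0`.
#' @return list with `n_retained`, `pct_of_richness`, `cum_rel_abund`
#'   (both percentages of the later sample).
#' @export
retention_metrics <- function(baseline, later) {
  if (length(baseline) != length(later))
    stop("baseline and later vectors differ in length", call. = FALSE)
  if (sum(later) <= 0) stop("later sample is empty", call. = FALSE)
  pb <- baseline > 0
  pl <- later > 0
  retained <- pb & pl
  list(n_retained = sum(retained),
       pct_of_richness = 100 * sum(retained) / sum(pl),
       cum_rel_abund = 100 * sum(later[retained]) / sum(later))
}

#' Partition a subject's entities into persistent and transient sets
#'
#' Entities present in at least `threshold` of the subject's samples form the
#' personal persistent virome (PPV); the remaining ever-present entities are
#' the transiently detected virome (TDV).
#'
#' @param presence logical or numeric matrix, entities x this subject's
#'   samples (`value > 0` is presence).
#' @param threshold persistence fraction, default 0.75 (boundary inclusive).
#' @param min_samples minimum samples required; subjects with fewer are
#'   skipped with a warning (returns `NULL`).
#' @return list with `ppv_ids` and `tdv_ids`.
#' @export
persistence_partition <- function(presence, threshold = 0.75, min_samples = 3L) {
  pres <- presence > 0
  if (ncol(pres) < min_samples) {
    warning(sprintf("subject has %d sample(s), fewer than %d; skipped",
                    ncol(pres), min_samples))
    return(NULL)
  }
  frac <- rowMeans(pres)
  ever <- rownames(pres)[frac > 0]
  ppv <- rownames(pres)[frac >= threshold]
  list(ppv_ids = ppv, tdv_ids = setdiff(ever, ppv))
}

#' Per-sample relative abundance of temperate phages
#'
#' @param matrix abundance matrix (entities x samples).
#' @param lifestyle character vector `"temperate"`/`"virulent"` named by
#'   entity id, covering all matrix rows.
#' @return named numeric vector of temperate fractions per sample.
#' @export
temperate_fraction <- function(matrix, lifestyle) {
  missing <- setdiff(rownames(matrix), names(lifestyle))
  if (length(missing) > 0L)
    stop("lifestyle labels missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  totals <- colSums(matrix)
  if (any(totals <= 0))
    stop("sample(s) with zero total abundance: ",
         paste(colnames(matrix)[totals <= 0], collapse = ", "), call. = FALSE)
  temp <- lifestyle[rownames(matrix)] == "temperate"
  colSums(matrix[temp, , drop = FALSE]) / totals
}

#' Bootstrap percentile confidence interval for a mean
#'
#' Resamples the values with replacement `n_boot` times, takes the mean of
#' each replicate, and returns the empirical 0.025 and 0.975 quantiles
#' (type-7 interpolation).
#'
#' @param values numeric vector with at least one value.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed optional integer for reproducibility.
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000L, seed = NULL, conf = 0.95) {
  if (length(values) == 0L) stop("empty vector", call. = FALSE)
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    means <- vapply(seq_len(n_boot), function(i)
      mean(sample(values, length(values), replace = TRUE)), numeric(1))
    unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  })
}
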