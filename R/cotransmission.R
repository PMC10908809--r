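#' Build the concurrent-sample subset for a virus-bacterium pair
#'
#' Selects the individual-timepoints where both the phage strain and the
#' bacterial strain were reconstructed, prioritising VLP metavirome samples
#' over total-metagenome (MGS) samples for the virus when both exist for the
#' same individual and timepoint. Normalized distances are binarized against
#' each entity's identity threshold (0 = shared strain, 1 = different), and a
#' control matrix encodes repeated sampling (0 = same individual, 1 =
#' different individuals; a mother and her infant are different individuals).
#'
#' @param virus,bacterium lists with a `dist` (`strain_dist` carrying
#'   `D_norm`) and a `cutpoint` (`cutpoint_result` or numeric threshold), as
#'   produced per entity by [transmission_analysis()].
#' @param metadata sample metadata table.
#' @param min_samples minimum concurrent samples (default 4); below this the
#'   pair is skipped (`NULL` returned).
#' @return list of class `concurrent_subset` with `sample_keys`,
#'   `virus_samples`, `bacterium_samples`, `M_v`, `M_b`, `C`, or `NULL`.
#' @export
build_concurrent_subset <- function(virus, bacterium, metadata,
                                    min_samples = 4L) {
  pick_samples <- function(entity, priority) {
    ids <- entity$dist$sample_ids
    m <- match(ids, metadata$sample_id)
    key <- sprintf("%s|%s", metadata$individual_id[m], metadata$timepoint[m])
    src <- metadata$source[m]
    ord <- order(key, match(src, priority))
    ids <- ids[ord]; key <- key[ord]
    keep <- !duplicated(key)
    stats::setNames(ids[keep], key[keep])
  }
  sv <- pick_samples(virus, c("VLP", "MGS", "TOTAL"))
  sb <- pick_samples(bacterium, c("TOTAL", "MGS", "VLP"))
  keys <- intersect(names(sv), names(sb))
  if (length(keys) < min_samples) return(NULL)

  binarize <- function(entity, ids) {
    thr <- entity$cutpoint
    if (inherits(thr, "cutpoint_result")) thr <- thr$threshold
    Dn <- entity$dist$D_norm[ids, ids, drop = FALSE]
    M <- ifelse(Dn < thr, 0L, 1L)
    if (anyNA(M)) {
      warning("saturated distances binarized as 'different strain'")
      M[is.na(M)] <- 1L
    }
    diag(M) <- 0L
    dimnames(M) <- NULL
    M
  }
  M_v <- binarize(virus, unname(sv[keys]))
  M_b <- binarize(bacterium, unname(sb[keys]))
  ind <- metadata$individual_id[match(unname(sv[keys]), metadata$sample_id)]
  C <- 1L - outer(ind, ind, function(a, b) as.integer(a == b))
  diag(C) <- 0L
  structure(list(sample_keys = keys, virus_samples = unname(sv[keys]),
                 bacterium_samples = unname(sb[keys]),
                 M_v = M_v, M_b = M_b, C = C),
            class = "concurrent_subset")
}

# all permutations of 1..n (n small), one per column: each permutation is a
# leading element followed by a sub-permutation of the remaining values
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (first in seq_len(n)) {
    for (k in seq_len(ncol(sub))) {
      col <- col + 1L
      out[, col] <- c(first, sub[, k] + (sub[, k] >= first))
    }
  }
  out
}

#' Partial Mantel test of two binarized strain-sharing matrices
#'
#' Correlates the vectorized upper triangles of the virus and bacterium
#' sharing matrices (Pearson), partialling out the same-individual control
#' matrix through the standard residual formula
#' r_M = (r_vb - r_vc r_bc) / sqrt((1 - r_vc^2)(1 - r_bc^2)).
#' Significance comes from simultaneously permuting the rows and columns of
#' the virus matrix; the one-sided p-value is
#' `(1 + #(r_perm >= r_obs)) / (n_perm + 1)`. When the control matrix is
#' constant the simple Mantel correlation is used instead; when either
#' sharing matrix is constant, or collinear with the control matrix, the pair
#' cannot be tested and is skipped.
#'
#' @param M_v,M_b,C symmetric 0/1 matrices of equal order (n >= 4).
#' @param n_perm permutations (default 999).
#' @param seed optional integer.
#' @param exact enumerate all `n!` permutations instead of sampling (used for
#'   small n).
#' @return list with `r` (Mantel or partial Mantel correlation), `p`,
#'   `used_partial`, `status` (`"ok"` or `"collinear_skipped"`).
#' @export
partial_mantel <- function(M_v, M_b, C, n_perm = 999L, seed = NULL,
                           exact = FALSE) {
  n <- nrow(M_v)
  stopifnot(n >= 4L, all(dim(M_b) == n), all(dim(C) == n))
  ut <- upper.tri(M_v)
  b <- M_b[ut]; cc <- C[ut]
  sd0 <- function(z) stats::sd(z) == 0
  skipped <- list(r = NA_real_, p = NA_real_, used_partial = NA,
                  status = "collinear_skipped")
  if (sd0(M_v[ut]) || sd0(b)) return(skipped)
  use_partial <- !sd0(cc)
  if (use_partial) {
    r_bc <- stats::cor(b, cc)
    if (abs(r_bc) >= 1 - 1e-12) return(skipped)
    if (abs(stats::cor(M_v[ut], cc)) >= 1 - 1e-12) return(skipped)
  }
  stat <- function(v) {
    r_vb <- stats::cor(v, b)
    if (!use_partial) return(r_vb)
    r_vc <- stats::cor(v, cc)
    (r_vb - r_vc * r_bc) / sqrt((1 - r_vc^2) * (1 - r_bc^2))
  }
  r_obs <- stat(M_v[ut])
  perm_stat <- function(p) {
    Mp <- M_v[p, p]
    stat(Mp[ut])
  }
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 2, perm_stat)
    p <- mean(r_perm >= r_obs - 1e-12)
  } else {
    r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(k)
      perm_stat(sample.int(n)), numeric(1)))
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (n_perm + 1)
  }
  list(r = r_obs, p = p, used_partial = use_partial, status = "ok")
}

#' Non-random linkage of phage and host strain sharing
#'
#' Over the unordered concurrent sample pairs, computes the observed joint
#' sharing frequency f_obs = frac(virus shared AND bacterium shared), the
#' expected frequency under independence f_exp = frac(virus shared) *
#' frac(bacterium shared), and their difference Delta ("non-random linkage").
#' Significance comes from a chi-squared test of independence on the 2x2
#' virus-shared x bacterium-shared table, without continuity correction.
#'
#' @param M_v,M_b symmetric 0/1 matrices (0 = shared).
#' @return list with `delta`, `p_chi2`, `f_obs`, `f_exp`, `n_pairs`, `table`.
#' @export
nonrandom_linkage <- function(M_v, M_b) {
  stopifnot(all(dim(M_v) == dim(M_b)))
  ut <- upper.tri(M_v)
  v <- M_v[ut] == 0L
  b <- M_b[ut] == 0L
  n <- length(v)
  if (n < 1L) stop("need at least one unordered sample pair", call. = FALSE)
  f_obs <- mean(v & b)
  f_exp <- mean(v) * mean(b)
  tab <- matrix(c(sum(v & b), sum(v & !b), sum(!v & b), sum(!v & !b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(virus = c("shared", "different"),
                                bacterium = c("shared", "different")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin; chi-squared undefined, p set to 1")
    p <- 1
  } else {
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  list(delta = f_obs - f_exp, p_chi2 = p, f_obs = f_obs, f_exp = f_exp,
       n_pairs = n, table = tab)
}

#' Are host-linked pairs co-transmitted more often than random pairs?
#'
#' One-sided Fisher's exact test comparing the frequency of co-transmission
#' calls between phage-bacterium pairs connected by a predicted virus-host
#' relationship and random phage-bacterium pairs.
#'
#' @param host_flags,random_flags logical vectors (co-transmitted or not).
#' @return list with `p` and the 2x2 `table`.
#' @export
host_vs_random_enrichment <- function(host_flags, random_flags) {
  host_flags <- host_flags[!is.na(host_flags)]
  random_flags <- random_flags[!is.na(random_flags)]
  if (length(host_flags) == 0L || length(random_flags) == 0L) {
    warning("empty class; p set to 1")
    return(list(p = 1, table = NULL))
  }
  tab <- matrix(c(sum(host_flags), sum(!host_flags),
                  sum(random_flags), sum(!random_flags)),
                nrow = 2, byrow = TRUE,
                dimnames = list(pair = c("host", "random"),
                                cotransmitted = c("yes", "no")))
  list(p = stats::fisher.test(tab, alternative = "greater")$p.value,
       table = tab)
}

#' Phage-host co-transmission analysis across virus-host pairs
#'
#' For every virus with sharing calls whose predicted host also has sharing
#' calls, builds the concurrent-sample subset and runs the partial Mantel
#' test and the non-random linkage statistic; Mantel p-values are BH-adjusted
#' across pairs. A pair is flagged co-transmitted when its adjusted Mantel
#' p-value falls below `alpha` with a positive correlation. Optionally, each
#' virus is also paired with a random non-host bacterium to supply the
#' comparison set for [host_vs_random_enrichment()].
#'
#' @param virus_details,bacterium_details the `details` element of a
#'   [transmission_analysis()] for viruses and bacteria (entries lacking
#'   `cutpoint`/`events` are skipped).
#' @param host_map data.frame with `virus_id`, `host_id`.
#' @param metadata sample metadata table.
#' @param n_perm Mantel permutations (default 999).
#' @param alpha FDR threshold for the co-transmission flag (default 0.05).
#' @param seed integer seed.
#' @param random_pairs also test each virus against a random non-host
#'   bacterium (default TRUE).
#' @return list of class `cotransmission_analysis` with `results` (one row
#'   per tested pair: `virus_id`, `bacterium_id`, `is_host_pair`, `n_samples`,
#'   `mantel_r`, `p_mantel`, `q_mantel`, `used_partial`, `status`, `delta`,
#'   `p_chi2`, `n_pairs`, `cotransmitted`) and `enrichment` (host-vs-random
#'   Fisher result, or `NULL`).
#' @export
cotransmission_analysis <- function(virus_details, bacterium_details,
                                    host_map, metadata, n_perm = 999L,
                                    alpha = 0.05, seed = 1L,
                                    random_pairs = TRUE) {
  has_calls <- function(det) !is.null(det) && !is.null(det$cutpoint) &&
    !is.null(det$dist$D_norm)
  viruses <- names(virus_details)[vapply(virus_details, has_calls, logical(1))]
  bacteria <- names(bacterium_details)[vapply(bacterium_details, has_calls,
                                              logical(1))]
  pairs <- list()
  for (v in viruses) {
    h <- host_map$host_id[host_map$virus_id == v]
    if (length(h) == 1L && h %in% bacteria)
      pairs[[length(pairs) + 1L]] <- list(v = v, b = h, host = TRUE)
  }
  if (random_pairs && length(bacteria) > 1L) {
    rnd <- with_seed(child_seed(seed, 0L), {
      lapply(viruses, function(v) {
        h <- host_map$host_id[host_map$virus_id == v]
        cand <- setdiff(bacteria, h)
        if (length(cand) == 0L) return(NULL)
        list(v = v, b = sample(cand, 1L), host = FALSE)
      })
    })
    pairs <- c(pairs, Filter(Negate(is.null), rnd))
  }
  rows <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    row <- data.frame(virus_id = pr$v, bacterium_id = pr$b,
                      is_host_pair = pr$host, n_samples = NA_integer_,
                      mantel_r = NA_real_, p_mantel = NA_real_,
                      q_mantel = NA_real_, used_partial = NA,
                      status = "skipped_too_few_samples", delta = NA_real_,
                      p_chi2 = NA_real_, n_pairs = NA_integer_,
                      cotransmitted = NA, stringsAsFactors = FALSE)
    sub <- build_concurrent_subset(virus_details[[pr$v]],
                                   bacterium_details[[pr$b]], metadata)
    if (!is.null(sub)) {
      row$n_samples <- length(sub$sample_keys)
      mt <- partial_mantel(sub$M_v, sub$M_b, sub$C, n_perm = n_perm,
                           seed = child_seed(seed, k))
      row$mantel_r <- mt$r
      row$p_mantel <- mt$p
      row$used_partial <- mt$used_partial
      row$status <- mt$status
      nl <- nonrandom_linkage(sub$M_v, sub$M_b)
      row$delta <- nl$delta
      row$p_chi2 <- nl$p_chi2
      row$n_pairs <- nl$n_pairs
    }
    rows[[k]] <- row
  }
  results <- do.call(rbind, rows)
  if (is.null(results)) results <- data.frame()
  if (nrow(results) > 0L) {
    results$q_mantel <- bh_adjust(results$p_mantel)
    results$cotransmitted <- results$status == "ok" &
      !is.na(results$q_mantel) & results$q_mantel < alpha & results$mantel_r > 0
  }
  enrichment <- NULL
  if (nrow(results) > 0L && any(results$is_host_pair) &&
      any(!results$is_host_pair)) {
    tested <- results$status == "ok"
    enrichment <- host_vs_random_enrichment(
      results$cotransmitted[results$is_host_pair & tested],
      results$cotransmitted[!results$is_host_pair & tested])
  }
  structure(list(results = results, enrichment = enrichment),
            class = "cotransmission_analysis")
}
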