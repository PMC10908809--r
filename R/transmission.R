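#' Label sample pairs by relatedness
#'
#' For one entity's reconstructed-strain samples, labels every unordered pair
#' as `within_individual` (longitudinal pair of one person), `related`
#' (mother-infant pair of the same family), `unrelated` (different families)
#' or `other` (same family, not mother-infant, e.g. twin infants). For
#' related pairs, the maternal sample is additionally classed as pre-birth or
#' post-birth by its timepoint label.
#'
#' @param sample_ids sample ids in matrix order.
#' @param metadata sample metadata table.
#' @param pre_birth,post_birth maternal timepoint labels counted as pre-birth
#'   (default P3, P7, B) and post-birth (default M1, M2, M3).
#' @return data.frame with columns `i`, `j` (matrix indices, i < j),
#'   `sample_i`, `sample_j`, `relation`, `birth_class`.
#' @export
label_pairs <- function(sample_ids, metadata,
                        pre_birth = c("P3", "P7", "B"),
                        post_birth = c("M1", "M2", "M3")) {
  m <- match(sample_ids, metadata$sample_id)
  if (anyNA(m))
    stop("sample id(s) missing from metadata: ",
         paste(sample_ids[is.na(m)], collapse = ", "), call. = FALSE)
  ind <- metadata$individual_id[m]
  fam <- metadata$family_id[m]
  role <- metadata$role[m]
  tp <- metadata$timepoint[m]
  n <- length(sample_ids)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  relation <- ifelse(ind[i] == ind[j], "within_individual",
              ifelse(fam[i] != fam[j], "unrelated",
              ifelse(role[i] != role[j], "related", "other")))
  # maternal timepoint class for related (mother-infant) pairs
  mother_tp <- ifelse(relation == "related",
                      ifelse(role[i] == "mother", tp[i], tp[j]),
                      NA_character_)
  birth_class <- ifelse(is.na(mother_tp), NA_character_,
                 ifelse(mother_tp %in% pre_birth, "pre_birth",
                 ifelse(mother_tp %in% post_birth, "post_birth",
                        NA_character_)))
  data.frame(i = i, j = j, sample_i = sample_ids[i], sample_j = sample_ids[j],
             relation = relation, birth_class = birth_class,
             stringsAsFactors = FALSE)
}

#' Permutation Wilcoxon test: are related-pair distances smaller?
#'
#' Tests, per entity, whether strain distances between samples of related
#' individuals are smaller than between unrelated individuals. The observed
#' statistic is the one-sided Wilcoxon rank sum of the related group; the
#' null distribution is built by permuting the related/unrelated labels over
#' the pooled distances, which respects the highly unequal group sizes. The
#' p-value is `(1 + #(permuted statistic <= observed)) / (n_iter + 1)`.
#'
#' With `exact = TRUE` (or automatically when the number of distinct label
#' assignments is at most `exact_limit`) the full enumeration over all
#' `choose(n, n_related)` assignments replaces Monte Carlo sampling and the
#' p-value is the exact proportion of assignments with a statistic at most
#' the observed one.
#'
#' @param d_related,d_unrelated finite distance vectors.
#' @param n_iter Monte Carlo iterations (default 1000).
#' @param seed optional integer.
#' @param exact force exhaustive enumeration.
#' @param exact_limit maximum number of assignments enumerated automatically.
#' @return list with `p`, `statistic` (related rank sum), `n_related`,
#'   `n_unrelated`, `exact`.
#' @export
related_unrelated_permutation_test <- function(d_related, d_unrelated,
                                               n_iter = 1000L, seed = NULL,
                                               exact = FALSE,
                                               exact_limit = 0L) {
  d_related <- d_related[is.finite(d_related)]
  d_unrelated <- d_unrelated[is.finite(d_unrelated)]
  m <- length(d_related); nu <- length(d_unrelated)
  if (m == 0L || nu == 0L)
    stop("both related and unrelated groups need at least one finite distance",
         call. = FALSE)
  pooled <- c(d_related, d_unrelated)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  n <- m + nu
  n_assign <- choose(n, m)
  if (exact || n_assign <= exact_limit) {
    combos <- utils::combn(n, m)
    stats_all <- colSums(matrix(r[combos], nrow = m))
    p <- mean(stats_all <= obs)
    return(list(p = p, statistic = obs, n_related = m, n_unrelated = nu,
                exact = TRUE))
  }
  perm <- with_seed(seed, vapply(seq_len(n_iter), function(k)
    sum(r[sample.int(n, m)]), numeric(1)))
  p <- (1 + sum(perm <= obs)) / (n_iter + 1)
  list(p = p, statistic = obs, n_related = m, n_unrelated = nu, exact = FALSE)
}

#' Permutation Wilcoxon test with individual-level label permutation
#'
#' Tests whether related (mother-infant) pair distances are smaller than
#' unrelated pair distances for one entity's distance matrix. Distances that
#' share an individual are statistically dependent — each individual's base
#' strain enters every pair it is part of — so the null is built by permuting
#' the family/role attributes over the *individuals*, which induces a valid
#' relabeling of the related/unrelated pairs while preserving the dependence
#' structure. The statistic is the rank-based AUC, P(related distance <
#' unrelated distance), which is comparable across permutations even though
#' the group sizes change; the one-sided p-value is
#' `(1 + #(AUC_perm <= AUC_obs)) / (n_valid_perm + 1)`.
#'
#' @param dset `strain_dist` from [pairwise_k2p()].
#' @param metadata sample metadata table.
#' @param n_iter permutation iterations (default 1000).
#' @param seed optional integer.
#' @return list with `p`, `auc`, `n_related`, `n_unrelated`, or `NULL` when a
#'   group has no finite distances.
#' @export
strain_distance_permutation_test <- function(dset, metadata, n_iter = 1000L,
                                             seed = NULL) {
  labels <- label_pairs(dset$sample_ids, metadata)
  d <- dset$D[cbind(labels$i, labels$j)]
  keep <- labels$relation != "within_individual" & is.finite(d)
  d <- d[keep]
  labels <- labels[keep, , drop = FALSE]
  if (nrow(labels) == 0L) return(NULL)

  m <- match(dset$sample_ids, metadata$sample_id)
  ind_of_sample <- metadata$individual_id[m]
  inds <- unique(ind_of_sample)
  fam <- metadata$family_id[match(inds, metadata$individual_id)]
  role <- metadata$role[match(inds, metadata$individual_id)]
  pi <- match(ind_of_sample[labels$i], inds)
  pj <- match(ind_of_sample[labels$j], inds)

  auc_for <- function(perm) {
    fi <- fam[perm[pi]]; fj <- fam[perm[pj]]
    ri <- role[perm[pi]]; rj <- role[perm[pj]]
    related <- fi == fj & ri != rj
    unrelated <- fi != fj
    nm <- sum(related); nu <- sum(unrelated)
    if (nm == 0L || nu == 0L) return(NA_real_)
    r <- rank(c(d[related], d[unrelated]))
    (sum(r[seq_len(nm)]) - nm * (nm + 1) / 2) / (nm * nu)
  }
  obs <- auc_for(seq_along(inds))
  if (is.na(obs)) return(NULL)
  perm <- with_seed(seed, vapply(seq_len(n_iter), function(k)
    auc_for(sample.int(length(inds))), numeric(1)))
  valid <- !is.na(perm)
  p <- (1 + sum(perm[valid] <= obs)) / (sum(valid) + 1)
  rel_obs <- fam[pi] == fam[pj] & role[pi] != role[pj]
  list(p = p, auc = obs,
       n_related = sum(rel_obs), n_unrelated = sum(fam[pi] != fam[pj]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement, via
#' [stats::p.adjust()]. `NA` entries propagate.
#'
#' @param p vector of p-values in (0, 1].
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Strain-identity cutpoint from within-individual vs unrelated distances
#'
#' Estimates the normalized-distance threshold below which two strains are
#' deemed identical. Within-individual longitudinal distances act as
#' positives and unrelated-pair distances as negatives; the primary threshold
#' maximizes the kernel-smoothed Youden index J(t) = TPR(t) + TNR(t) - 1,
#' with Gaussian kernel density estimates (Silverman bandwidth) of both
#' groups evaluated on a 512-point grid over the pooled range. When the
#' resulting threshold would admit more than `admit_cap` of the unrelated
#' pairs, the empirical-FDR fallback replaces it with the 5th percentile of
#' the unrelated distances.
#'
#' @param within_norm within-individual normalized distances (>= 3 values).
#' @param unrelated_norm unrelated-pair normalized distances (>= 3 values).
#' @param admit_cap maximum tolerated fraction of unrelated pairs below the
#'   Youden threshold before the fallback engages (default 0.05).
#' @param fdr_quantile quantile of the unrelated distances used by the
#'   fallback (default 0.05, type-7 interpolation).
#' @return list of class `cutpoint_result`: `threshold`, `method`
#'   (`"youden_kernel"` or `"empirical_fdr"`), `youden_J` (empirical J at the
#'   threshold), `unrelated_admit_rate`.
#' @export
estimate_cutpoint <- function(within_norm, unrelated_norm,
                              admit_cap = 0.05, fdr_quantile = 0.05) {
  within_norm <- within_norm[is.finite(within_norm)]
  unrelated_norm <- unrelated_norm[is.finite(unrelated_norm)]
  if (length(within_norm) < 3L || length(unrelated_norm) < 3L)
    stop("need >= 3 finite distances in each group", call. = FALSE)

  kde_cdf <- function(x, grid) {
    if (stats::sd(x) == 0) return(NULL)           # degenerate group
    bw <- stats::bw.nrd0(x)
    if (!is.finite(bw) || bw <= 0) return(NULL)
    vapply(grid, function(t) mean(stats::pnorm(t, mean = x, sd = bw)),
           numeric(1))
  }
  grid <- seq(min(c(within_norm, unrelated_norm)),
              max(c(within_norm, unrelated_norm)), length.out = 512L)
  Fw <- kde_cdf(within_norm, grid)
  Fu <- kde_cdf(unrelated_norm, grid)
  if (is.null(Fw) || is.null(Fu)) {
    warning("degenerate kernel density (zero-variance group); ",
            "using midpoint of the group extremes")
    threshold <- (max(within_norm) + min(unrelated_norm)) / 2
    method <- "youden_kernel"
  } else {
    J_kernel <- Fw - Fu   # TPR(t) + TNR(t) - 1 under the kernel CDFs
    # well-separated groups leave J flat over a wide interval; take the
    # midpoint of the optimal plateau (the maximal-margin separator) rather
    # than its first grid point
    plateau <- which(J_kernel >= max(J_kernel) - 1e-8)
    runs <- split(plateau, cumsum(c(1, diff(plateau) != 1)))
    best <- runs[[which(vapply(runs, function(r) which.max(J_kernel) %in% r,
                               logical(1)))[1]]]
    threshold <- mean(range(grid[best]))
    method <- "youden_kernel"
  }
  admit <- mean(unrelated_norm < threshold)
  if (admit > admit_cap) {
    threshold <- unname(stats::quantile(unrelated_norm, fdr_quantile, type = 7))
    method <- "empirical_fdr"
    admit <- mean(unrelated_norm < threshold)
  }
  J <- mean(within_norm < threshold) + mean(unrelated_norm >= threshold) - 1
  structure(list(threshold = threshold, method = method,
                 youden_J = J, unrelated_admit_rate = admit),
            class = "cutpoint_result")
}

#' Call strain-sharing events from normalized distances
#'
#' A pair of samples shares a strain when its normalized distance falls
#' strictly below the entity's identity threshold; pairs at or above the
#' threshold carry different strains. `NaN` (saturated) pairs become `NA`.
#'
#' @param D_norm normalized distance matrix (or a `strain_dist` with
#'   `D_norm`).
#' @param threshold identity cutoff from [estimate_cutpoint()] (or a
#'   `cutpoint_result`).
#' @return object of class `sharing_calls`: list with binary symmetric
#'   `events` matrix (diagonal `NA`) and `threshold`.
#' @export
call_sharing_events <- function(D_norm, threshold) {
  if (inherits(D_norm, "strain_dist")) {
    if (is.null(D_norm$D_norm)) stop("strain_dist has no D_norm; run median_normalize()",
                                     call. = FALSE)
    D_norm <- D_norm$D_norm
  }
  if (inherits(threshold, "cutpoint_result")) threshold <- threshold$threshold
  events <- (D_norm < threshold) * 1L
  events[is.nan(D_norm)] <- NA_integer_
  diag(events) <- NA_integer_
  structure(list(events = events, threshold = threshold),
            class = "sharing_calls")
}

# shared / total counts for the pairs selected by a label subset
count_events <- function(events, pairs) {
  if (inherits(events, "sharing_calls")) events <- events$events
  e <- events[cbind(pairs$i, pairs$j)]
  c(shared = sum(e == 1L, na.rm = TRUE), total = sum(!is.na(e)))
}

#' One-sided Fisher test of sharing enrichment in related pairs
#'
#' Compares strain-sharing frequencies between related (mother-infant) and
#' unrelated sample pairs with a one-sided Fisher's exact test (alternative:
#' related pairs share more often).
#'
#' @param events `sharing_calls` or binary event matrix.
#' @param labels pair labels from [label_pairs()].
#' @return list with `p`, `share_rate_related`, `share_rate_unrelated`,
#'   `n_related`, `n_unrelated`, `n_events`.
#' @export
sharing_enrichment_fisher <- function(events, labels) {
  rel <- count_events(events, labels[labels$relation == "related", ])
  unr <- count_events(events, labels[labels$relation == "unrelated", ])
  if (rel["total"] == 0L || unr["total"] == 0L) {
    warning("empty margin in the sharing table; p set to 1")
    p <- 1
  } else {
    tab <- matrix(c(rel["shared"], rel["total"] - rel["shared"],
                    unr["shared"], unr["total"] - unr["shared"]),
                  nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  list(p = p,
       share_rate_related = unname(ifelse(rel["total"] > 0,
                                          rel["shared"] / rel["total"], NA)),
       share_rate_unrelated = unname(ifelse(unr["total"] > 0,
                                            unr["shared"] / unr["total"], NA)),
       n_related = unname(rel["total"]), n_unrelated = unname(unr["total"]),
       n_events = unname(rel["shared"]))
}

#' Compare sharing with post-birth vs pre-birth maternal samples
#'
#' Among related (mother-infant) pairs, tests whether strain-sharing is more
#' frequent when the maternal sample was collected after birth than before,
#' with a one-sided Fisher's exact test.
#'
#' @param events `sharing_calls` or binary event matrix.
#' @param labels pair labels from [label_pairs()].
#' @return list with `p`, `shared_post`, `n_post`, `shared_pre`, `n_pre`, or
#'   `NULL` when either class has no pairs (entity skipped).
#' @export
prepost_birth_comparison <- function(events, labels) {
  rel <- labels[labels$relation == "related" & !is.na(labels$birth_class), ]
  post <- count_events(events, rel[rel$birth_class == "post_birth", ])
  pre <- count_events(events, rel[rel$birth_class == "pre_birth", ])
  if (post["total"] == 0L || pre["total"] == 0L) return(NULL)
  tab <- matrix(c(post["shared"], post["total"] - post["shared"],
                  pre["shared"], pre["total"] - pre["shared"]),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(p = p, shared_post = unname(post["shared"]), n_post = unname(post["total"]),
       shared_pre = unname(pre["shared"]), n_pre = unname(pre["total"]))
}

#' Strain-level transmission analysis across entities
#'
#' Runs the full per-entity chain: alignment trimming, pairwise K2P
#' distances, the related-vs-unrelated permutation Wilcoxon test (BH-adjusted
#' across entities), and — for entities with significantly closer related
#' strains — median normalization, cutpoint estimation, sharing calls, the
#' one-sided Fisher enrichment test, and the pre-/post-birth comparison.
#'
#' @param alignments named list of per-entity alignments (named character
#'   vectors of aligned sequences, names = sample ids).
#' @param metadata sample metadata table.
#' @param trim_bp columns trimmed from each alignment end (default 100).
#' @param n_iter permutation iterations (default 1000).
#' @param alpha FDR threshold selecting entities for sharing analysis
#'   (default 0.05).
#' @param seed integer seed; per-entity seeds are derived from it.
#' @param norm_scope normalization scope passed to [median_normalize()].
#' @return list of class `transmission_analysis` with `results` (one row per
#'   entity: `entity_id`, `p_perm`, `q`, `n_related`, `n_unrelated`,
#'   `threshold`, `cutpoint_method`, `share_rate_related`,
#'   `share_rate_unrelated`, `p_fisher`, `q_fisher`, `n_events`,
#'   `p_prepost`, `q_prepost`) and `details` (per entity: `dist`, `labels`,
#'   `cutpoint`, `events`).
#' @export
transmission_analysis <- function(alignments, metadata, trim_bp = 100L,
                                  n_iter = 1000L, alpha = 0.05, seed = 1L,
                                  norm_scope = "within_individual") {
  entities <- names(alignments)
  details <- stats::setNames(vector("list", length(entities)), entities)
  rows <- vector("list", length(entities))
  for (k in seq_along(entities)) {
    e <- entities[k]
    row <- data.frame(entity_id = e, p_perm = NA_real_, q = NA_real_,
                      n_related = NA_integer_, n_unrelated = NA_integer_,
                      threshold = NA_real_, cutpoint_method = NA_character_,
                      share_rate_related = NA_real_,
                      share_rate_unrelated = NA_real_,
                      p_fisher = NA_real_, q_fisher = NA_real_,
                      n_events = NA_integer_, p_prepost = NA_real_,
                      q_prepost = NA_real_, stringsAsFactors = FALSE)
    aln <- alignments[[e]]
    if (length(aln) < 2L) { rows[[k]] <- row; next }
    dset <- pairwise_k2p(trim_alignment(aln, trim_bp), entity_id = e)
    labels <- label_pairs(dset$sample_ids, metadata)
    details[[e]] <- list(dist = dset, labels = labels,
                         cutpoint = NULL, events = NULL)
    pt <- strain_distance_permutation_test(dset, metadata, n_iter = n_iter,
                                           seed = child_seed(seed, k))
    if (!is.null(pt)) {
      row$p_perm <- pt$p
      row$n_related <- pt$n_related
      row$n_unrelated <- pt$n_unrelated
    }
    rows[[k]] <- row
  }
  results <- do.call(rbind, rows)
  results$q <- bh_adjust(results$p_perm)

  # sharing analysis only where related strains are significantly closer
  for (k in seq_along(entities)) {
    e <- entities[k]
    if (is.na(results$q[k]) || results$q[k] >= alpha) next
    det <- details[[e]]
    dset <- median_normalize(det$dist, metadata, scope = norm_scope)
    if (is.null(dset)) next
    labels <- det$labels
    up <- cbind(labels$i, labels$j)
    within <- dset$D_norm[up][labels$relation == "within_individual"]
    unrel <- dset$D_norm[up][labels$relation == "unrelated"]
    if (sum(is.finite(within)) < 3L || sum(is.finite(unrel)) < 3L) next
    cp <- estimate_cutpoint(within, unrel)
    ev <- call_sharing_events(dset, cp)
    fs <- sharing_enrichment_fisher(ev, labels)
    pp <- prepost_birth_comparison(ev, labels)
    details[[e]]$dist <- dset
    details[[e]]$cutpoint <- cp
    details[[e]]$events <- ev
    results$threshold[k] <- cp$threshold
    results$cutpoint_method[k] <- cp$method
    results$share_rate_related[k] <- fs$share_rate_related
    results$share_rate_unrelated[k] <- fs$share_rate_unrelated
    results$p_fisher[k] <- fs$p
    results$n_events[k] <- fs$n_events
    if (!is.null(pp)) results$p_prepost[k] <- pp$p
  }
  results$q_fisher <- bh_adjust(results$p_fisher)
  results$q_prepost <- bh_adjust(results$p_prepost)
  structure(list(results = results, details = details),
            class = "transmission_analysis")
}
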