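#' Trim columns from both ends of a strain alignment
#'
#' Global alignments of per-sample consensus sequences accumulate gaps at
#' their ends; trimming a fixed number of columns from each flank before
#' distance estimation removes the gap-enriched margins.
#'
#' @param aln named character vector, character matrix or
#'   [Biostrings::DNAStringSet] of equal-length aligned sequences.
#' @param trim_bp number of columns removed from each end (default 100).
#' @return alignment in the same representation class (character matrix).
#' @export
#' @examples
#' aln <- c(s1 = paste(rep("ACGT", 100), collapse = ""),
#'          s2 = paste(rep("ACGT", 100), collapse = ""))
#' ncol(trim_alignment(aln, 100))  # 200
trim_alignment <- function(aln, trim_bp = 100L) {
  stopifnot(trim_bp >= 0L)
  mat <- alignment_matrix(aln)
  if (trim_bp == 0L) return(mat)
  if (ncol(mat) <= 2L * trim_bp)
    stop(sprintf("alignment of %d columns is too short to trim %d bp from both ends",
                 ncol(mat), trim_bp), call. = FALSE)
  mat[, (trim_bp + 1L):(ncol(mat) - trim_bp), drop = FALSE]
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes the K80 distance d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q)) where P
#' and Q are the proportions of transition (A<->G, C<->T) and transversion
#' differences over columns where both sequences carry an unambiguous base.
#' Columns with gaps or ambiguity codes in either sequence are excluded
#' (pairwise deletion).
#'
#' @param s1,s2 aligned sequences (equal-length character strings or
#'   character vectors of single bases).
#' @return list with `d` (substitutions/site; `NaN` when the distance is
#'   saturated), `P`, `Q`, and `n_sites` (compared columns).
#' @export
#' @examples
#' k2p_distance("ACGTACGT", "ACGTACGT")$d  # 0
k2p_distance <- function(s1, s2) {
  to_vec <- function(s) {
    if (length(s) == 1L) strsplit(toupper(s), "", fixed = TRUE)[[1]] else toupper(s)
  }
  v1 <- to_vec(s1); v2 <- to_vec(s2)
  if (length(v1) != length(v2))
    stop("sequences have unequal lengths", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  ok <- v1 %in% bases & v2 %in% bases
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites (all columns gapped or ambiguous)", call. = FALSE)
  a <- v1[ok]; b <- v2[ok]
  diff <- a != b
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- diff & (purine[a] == purine[b])   # A<->G or C<->T
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NaN else -0.5 * log(w1 * sqrt(w2))
  list(d = d, P = P, Q = Q, n_sites = n)
}

#' Pairwise K2P distance matrix for a strain alignment
#'
#' Computes all pairwise Kimura 2-parameter distances for one entity's
#' consensus-sequence alignment, with per-pair deletion of columns carrying a
#' gap or ambiguous base in either member of the pair. Saturated pairs (log of
#' a non-positive argument) are returned as `NaN` with a warning.
#'
#' @param aln alignment (named character vector, matrix or `DNAStringSet`).
#' @param entity_id optional identifier stored in the result.
#' @return object of class `strain_dist`: list with `entity_id`, `sample_ids`,
#'   `D` (symmetric distance matrix), `P`, `Q`, `valid_sites` (per-pair
#'   compared columns), and `D_norm`/`normalizer` (set by
#'   [median_normalize()], initially `NULL`).
#' @export
pairwise_k2p <- function(aln, entity_id = NA_character_) {
  mat <- alignment_matrix(aln)
  if (nrow(mat) < 2L) stop("alignment needs at least 2 records", call. = FALSE)
  ids <- rownames(mat)
  # Indicator matrices per base; BLAS crossproducts give per-pair counts of
  # matches, transitions and valid columns in O(n^2 L).
  A <- (mat == "A") * 1; C <- (mat == "C") * 1
  G <- (mat == "G") * 1; Tm <- (mat == "T") * 1
  V <- A + C + G + Tm
  n_sites <- tcrossprod(V)
  matches <- tcrossprod(A) + tcrossprod(C) + tcrossprod(G) + tcrossprod(Tm)
  transitions <- tcrossprod(A, G) + tcrossprod(G, A) +
    tcrossprod(C, Tm) + tcrossprod(Tm, C)
  transversions <- n_sites - matches - transitions
  if (any(n_sites[upper.tri(n_sites)] == 0))
    warning("some pairs have zero comparable sites; distances set to NaN")
  P <- transitions / n_sites
  Q <- transversions / n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  D <- suppressWarnings(-0.5 * log(w1 * sqrt(w2)))
  sat <- is.finite(P) & (w1 <= 0 | w2 <= 0)
  if (any(sat[upper.tri(sat)]))
    warning(sprintf("%d saturated pair(s) set to NaN", sum(sat[upper.tri(sat)])))
  D[sat] <- NaN
  diag(D) <- 0
  dimnames(D) <- dimnames(P) <- dimnames(Q) <- dimnames(n_sites) <- list(ids, ids)
  structure(list(entity_id = entity_id, sample_ids = ids, D = D,
                 P = P, Q = Q, valid_sites = n_sites,
                 D_norm = NULL, normalizer = NULL),
            class = "strain_dist")
}

#' Median-normalize a strain distance matrix
#'
#' Divides all pairwise distances by an entity-specific normalization median,
#' putting per-entity distances on a common scale before cutpoint estimation
#' and sharing calls. By default the median is taken over within-individual
#' longitudinal distances when at least one exists, otherwise over all finite
#' off-diagonal distances; a precomputed `normalizer` may be supplied instead.
#'
#' @param dset `strain_dist` object from [pairwise_k2p()].
#' @param metadata sample metadata table (used to identify within-individual
#'   pairs); ignored when `normalizer` is given.
#' @param normalizer optional positive scalar overriding the internal median.
#' @param scope `"within_individual"` (default) or `"all"` — which distances
#'   feed the internal median.
#' @return the `strain_dist` with `D_norm` and `normalizer` filled in, or
#'   `NULL` (with a warning) when no positive normalizer can be computed.
#' @export
median_normalize <- function(dset, metadata = NULL, normalizer = NULL,
                             scope = c("within_individual", "all")) {
  scope <- match.arg(scope)
  stopifnot(inherits(dset, "strain_dist"))
  D <- dset$D
  if (is.null(normalizer)) {
    up <- upper.tri(D)
    vals <- D[up]
    if (scope == "within_individual" && !is.null(metadata)) {
      ind <- metadata$individual_id[match(dset$sample_ids, metadata$sample_id)]
      same <- outer(ind, ind, "==")[up]
      within <- vals[same & is.finite(vals)]
      normalizer <- if (length(within) > 0L) stats::median(within)
                    else stats::median(vals[is.finite(vals)])
    } else {
      normalizer <- stats::median(vals[is.finite(vals)])
    }
  }
  if (!is.finite(normalizer) || normalizer <= 0) {
    warning(sprintf("entity %s: normalization median is zero or undefined; excluded",
                    dset$entity_id))
    return(NULL)
  }
  dset$D_norm <- D / normalizer
  dset$normalizer <- normalizer
  dset
}
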