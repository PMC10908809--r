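test_that("K2P distance matches the closed form and handles saturation", {
  # identical sequences
  expect_identical(k2p_distance("ACGTACGT", "ACGTACGT")$d, 0)

  # 100 sites, 10 transitions (A<->G), 5 transversions (A<->C):
  # d = -1/2 ln(0.75 * sqrt(0.90)) = 0.1701812
  base <- rep("A", 100)
  other <- base
  other[1:10] <- "G"
  other[11:15] <- "C"
  res <- k2p_distance(base, other)
  expect_equal(res$P, 0.10)
  expect_equal(res$Q, 0.05)
  expect_equal(res$d, -0.5 * log((1 - 2 * 0.10 - 0.05) * sqrt(1 - 2 * 0.05)))
  expect_equal(res$d, 0.170181, tolerance = 1e-5)

  # P = 0.5, Q = 0 saturates (log of a non-positive argument)
  sat <- rep(c("A", "G"), 50)
  expect_true(is.nan(k2p_distance(rep("A", 100), sat)$d))

  # gap/ambiguity columns are excluded pairwise
  expect_equal(k2p_distance("ACGT-N", "ACGTAA")$n_sites, 4)
  expect_error(k2p_distance("----", "ACGT"), "comparable")
})

test_that("K2P is monotone in P and Q and linear in the small-distance limit", {
  d_of <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  Ps <- seq(0.01, 0.2, by = 0.01)
  expect_true(all(diff(sapply(Ps, d_of, Q = 0.05)) > 0))
  expect_true(all(diff(sapply(Ps, d_of, Q = 0.10)) > 0))
  expect_lt(abs(d_of(0.001, 0.001) - 0.002), 1e-4)
})

test_that("pairwise_k2p is symmetric, zero-diagonal and matches the scalar path", {
  set.seed(42)
  anc <- random_dna_str(600)
  aln <- c(a = anc,
           b = evolve_sequence(anc, 0.05, seed = 1),
           c = evolve_sequence(anc, 0.10, seed = 2))
  dset <- pairwise_k2p(aln, "e1")
  expect_identical(dset$D, t(dset$D))
  expect_identical(unname(diag(dset$D)), c(0, 0, 0))
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    sc <- k2p_distance(aln[pr[1]], aln[pr[2]])
    expect_equal(unname(dset$D[pr[1], pr[2]]), sc$d)
    expect_equal(unname(dset$valid_sites[pr[1], pr[2]]), sc$n_sites)
  }
})

test_that("pairwise_k2p agrees with ape::dist.dna under pairwise deletion", {
  skip_if_not_installed("ape")
  set.seed(7)
  anc <- random_dna_str(800)
  aln <- c(a = evolve_sequence(anc, 0.02, seed = 11),
           b = evolve_sequence(anc, 0.05, seed = 12),
           c = evolve_sequence(anc, 0.08, seed = 13),
           d = anc)
  # plant some gaps and ambiguity
  aln[["a"]] <- paste0(strrep("-", 10), substring(aln[["a"]], 11))
  aln[["b"]] <- paste0(substring(aln[["b"]], 1, 20), strrep("N", 5),
                       substring(aln[["b"]], 26))
  D <- pairwise_k2p(aln)$D
  bin <- ape::as.DNAbin(strsplit(tolower(aln), ""))
  Dape <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(D), unname(Dape[rownames(D), colnames(D)]),
               tolerance = 1e-10)
})

test_that("an all-gap column changes no distance", {
  set.seed(3)
  anc <- random_dna_str(400)
  aln <- c(a = anc, b = evolve_sequence(anc, 0.07, seed = 5))
  with_gap <- paste0(substr(aln, 1, 200), "-", substr(aln, 201, 400))
  names(with_gap) <- names(aln)
  expect_equal(pairwise_k2p(aln)$D, pairwise_k2p(with_gap)$D)
})

test_that("trim_alignment removes the requested flanks", {
  aln <- c(a = strrep("ACGT", 250), b = strrep("ACGT", 250))
  expect_equal(ncol(trim_alignment(aln, 100)), 800)
  expect_equal(ncol(trim_alignment(aln, 0)), 1000)
  short <- c(a = strrep("AC", 75), b = strrep("AC", 75))
  expect_error(trim_alignment(short, 100), "too short")
})

test_that("median normalization divides by the right median and is scale-free", {
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D[upper.tri(D)] <- 1:6
  D <- D + t(D)
  dset <- structure(list(entity_id = "e", sample_ids = letters[1:4], D = D,
                         D_norm = NULL, normalizer = NULL),
                    class = "strain_dist")
  norm <- median_normalize(dset, scope = "all")
  expect_equal(norm$normalizer, 3.5)
  expect_equal(norm$D_norm[1, 2], 1 / 3.5)
  expect_equal(sort(norm$D_norm[upper.tri(D)]),
               c(1, 2, 3, 4, 5, 6) / 3.5)
  # internal median makes D_norm invariant to global rescaling
  dset2 <- dset; dset2$D <- 2 * D
  expect_equal(median_normalize(dset2, scope = "all")$D_norm, norm$D_norm)
  # zero matrix cannot be normalized
  dset0 <- dset; dset0$D <- D * 0
  expect_warning(out <- median_normalize(dset0, scope = "all"), "undefined")
  expect_null(out)
})

test_that("within-individual scope uses longitudinal distances only", {
  meta <- toy_metadata()
  ids <- c("F01_M_P7_VLP", "F01_M_B_VLP", "F02_M_P7_VLP")
  D <- matrix(0, 3, 3, dimnames = list(ids, ids))
  D[1, 2] <- D[2, 1] <- 0.01   # within F01_M
  D[1, 3] <- D[3, 1] <- 0.2
  D[2, 3] <- D[3, 2] <- 0.3
  dset <- structure(list(entity_id = "e", sample_ids = ids, D = D,
                         D_norm = NULL, normalizer = NULL),
                    class = "strain_dist")
  expect_equal(median_normalize(dset, meta)$normalizer, 0.01)
  expect_equal(median_normalize(dset, meta, scope = "all")$normalizer, 0.2)
})
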