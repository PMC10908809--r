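test_that("evolve_sequence is the identity at zero distance and deterministic", {
  anc <- "ACGTACGTAC"
  expect_identical(evolve_sequence(anc, 0), anc)
  expect_identical(evolve_sequence(anc, 0.1, seed = 5),
                   evolve_sequence(anc, 0.1, seed = 5))
  expect_error(evolve_sequence(anc, -0.1), "d_target")
  expect_error(evolve_sequence(anc, Inf), "d_target")
  expect_error(evolve_sequence("ACGX", 0.1), "alphabet")
})

test_that("re-estimated K2P distance is unbiased for the target", {
  # 200 replicate ancestor/child pairs at 10 kb; the mean re-estimated
  # distance must sit within 3 standard errors of the target 0.1
  set.seed(101)
  anc <- random_dna_str(10000)
  d_hat <- vapply(1:200, function(k)
    k2p_distance(anc, evolve_sequence(anc, 0.1, seed = k))$d, numeric(1))
  se <- sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) - 0.1), 3 * se)
})

test_that("kappa = 1 yields the 1:2 transition:transversion ratio", {
  # with equal rates there are two transversion channels per site
  set.seed(202)
  anc <- random_dna_str(5000)
  counts <- vapply(1:200, function(k) {
    child <- evolve_sequence(anc, 0.05, kappa = 1, seed = 1000 + k)
    r <- k2p_distance(anc, child)
    c(ts = r$P, tv = r$Q)
  }, numeric(2))
  ratio <- mean(counts["ts", ]) / mean(counts["tv", ])
  expect_equal(ratio, 0.5, tolerance = 0.05)
})

test_that("cohort generation is deterministic and obeys its invariants", {
  cfg <- cohort_config(n_families = 4, n_votus = 4, n_bacteria = 3,
                       seq_length = 1000, seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)

  # sample metadata well-formed; every individual keeps >= 2 timepoints
  tp_per_ind <- tapply(c1$samples$timepoint, c1$samples$individual_id,
                       function(x) length(unique(x)))
  expect_true(all(tp_per_ind >= 2))
  expect_false(anyDuplicated(c1$samples$sample_id) > 0)
  expect_true(all(c1$abundance >= 0))

  # truth invariant: coupled_host_id only for transmitted viruses
  bad <- !is.na(c1$truth$coupled_host_id) &
    (!c1$truth$transmitted | c1$truth$kind != "virus")
  expect_false(any(bad))

  # config invariants rejected
  expect_error(cohort_config(seq_length = 500), "seq_length")
  expect_error(cohort_config(d_within = 0.2, d_transmit = 0.1,
                             d_unrelated = 0.05), "d_within")
  expect_error(cohort_config(transmission_rate = 1.5), "transmission_rate")
})

test_that("coupled phage strains are present exactly where the host strain is", {
  cfg <- cohort_config(n_families = 4, n_votus = 6, n_bacteria = 2,
                       transmission_rate = 1, coupling_rate = 1,
                       seq_length = 1000, dropout = 0, seed = 21)
  co <- generate_cohort(cfg)
  meta <- co$samples
  key_of <- function(ids) {
    m <- match(ids, meta$sample_id)
    sort(unique(sprintf("%s|%s", meta$individual_id[m], meta$timepoint[m])))
  }
  for (v in names(co$alignments$virus)) {
    host <- co$host_map$host_id[co$host_map$virus_id == v]
    expect_identical(key_of(names(co$alignments$virus[[v]])),
                     key_of(names(co$alignments$bacteria[[host]])),
                     info = v)
  }
})

test_that("forced separation puts every related pair below every unrelated pair", {
  cfg <- cohort_config(n_families = 3, n_votus = 2, n_bacteria = 2,
                       transmission_rate = 1, d_within = 0.0005,
                       d_transmit = 0.001, d_unrelated = 0.1,
                       seq_length = 2000, dropout = 0, seed = 31)
  co <- generate_cohort(cfg)
  for (v in names(co$alignments$virus)) {
    dset <- pairwise_k2p(co$alignments$virus[[v]])
    lab <- label_pairs(dset$sample_ids, co$samples)
    d <- dset$D[cbind(lab$i, lab$j)]
    rel <- d[lab$relation == "related"]
    unr <- d[lab$relation == "unrelated"]
    expect_lt(max(rel), min(unr))
  }
})

test_that("planted related-pair distances concentrate near d_transmit", {
  cfg <- cohort_config(n_families = 5, n_votus = 3, n_bacteria = 2,
                       transmission_rate = 1, d_within = 0.001,
                       d_transmit = 0.05, d_unrelated = 0.2,
                       seq_length = 10000, dropout = 0, seed = 41)
  co <- generate_cohort(cfg)
  rel_all <- unlist(lapply(names(co$alignments$virus), function(v) {
    dset <- pairwise_k2p(co$alignments$virus[[v]])
    lab <- label_pairs(dset$sample_ids, co$samples)
    dset$D[cbind(lab$i, lab$j)][lab$relation == "related"]
  }))
  # expectation is d_transmit plus the longitudinal drift of both samples
  expect_equal(mean(rel_all), 0.05 + 0.001, tolerance = 0.1)
})
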