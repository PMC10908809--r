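make_subset_inputs <- function(ids, D_norm, threshold) {
  list(dist = structure(list(sample_ids = ids, D_norm = D_norm),
                        class = "strain_dist"),
       cutpoint = threshold)
}

test_that("concurrent subsets intersect individual-timepoints with VLP priority", {
  meta <- toy_metadata()
  vir_ids <- c("F01_M_P7_VLP", "F01_M_B_VLP", "F01_I1_M1_VLP",
               "F01_I1_M1_TOTAL", "F02_M_P7_VLP")
  bac_ids <- c("F01_M_P7_TOTAL", "F01_M_B_TOTAL", "F01_I1_M1_TOTAL",
               "F02_M_P7_TOTAL")
  Dv <- matrix(0.1, 5, 5, dimnames = list(vir_ids, vir_ids)); diag(Dv) <- 0
  Db <- matrix(0.1, 4, 4, dimnames = list(bac_ids, bac_ids)); diag(Db) <- 0
  sub <- build_concurrent_subset(make_subset_inputs(vir_ids, Dv, 0.5),
                                 make_subset_inputs(bac_ids, Db, 0.5), meta)
  expect_equal(length(sub$sample_keys), 4)
  # the infant M1 virus strain comes from the VLP record, not the MGS echo
  expect_true("F01_I1_M1_VLP" %in% sub$virus_samples)
  expect_false("F01_I1_M1_TOTAL" %in% sub$virus_samples)
  # mother and her infant are different individuals in the control matrix
  i_m <- match("F01|M_P7", gsub("F01_M\\|", "F01|M_", sub$sample_keys))
  ind <- meta$individual_id[match(sub$virus_samples, meta$sample_id)]
  C_manual <- 1L - outer(ind, ind, function(a, b) as.integer(a == b))
  diag(C_manual) <- 0L
  expect_identical(sub$C, C_manual)
  expect_true(all(sub$C[ind == "F01_M", ind == "F01_I1"] == 1L))

  # fewer than 4 concurrent samples -> skipped
  sub2 <- build_concurrent_subset(
    make_subset_inputs(vir_ids[1:3], Dv[1:3, 1:3], 0.5),
    make_subset_inputs(bac_ids[3:4], Db[3:4, 3:4], 0.5), meta)
  expect_null(sub2)
})

test_that("partial Mantel returns r = 1 for identical matrices", {
  set.seed(12)
  M <- random_binary_sym(6)
  C <- random_binary_sym(6)
  while (sd(C[upper.tri(C)]) == 0 ||
         abs(cor(M[upper.tri(M)], C[upper.tri(C)])) > 0.9) {
    C <- random_binary_sym(6)
  }
  res <- partial_mantel(M, M, C, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_true(res$used_partial)
  expect_equal(res$status, "ok")
})

test_that("exact partial Mantel p matches the 24-permutation oracle on 4x4", {
  set.seed(21)
  for (k in 1:8) {
    repeat {
      M_v <- random_binary_sym(4)
      M_b <- random_binary_sym(4)
      C <- random_binary_sym(4)
      ut <- upper.tri(M_v)
      if (sd(M_v[ut]) > 0 && sd(M_b[ut]) > 0 && sd(C[ut]) > 0 &&
          abs(cor(M_v[ut], C[ut])) < 1 - 1e-9 &&
          abs(cor(M_b[ut], C[ut])) < 1 - 1e-9) break
    }
    got <- partial_mantel(M_v, M_b, C, exact = TRUE)
    expect_equal(got$p, oracle_partial_mantel_p(M_v, M_b, C),
                 info = paste("case", k))
    # the closed-form partial correlation equals the residual-based one
    expect_equal(got$r, oracle_partial_cor(M_v[ut], M_b[ut], C[ut]))
  }
})

test_that("partial Mantel statistic agrees with vegan::mantel.partial", {
  skip_if_not_installed("vegan")
  set.seed(33)
  n <- 8
  M_v <- random_binary_sym(n); M_b <- random_binary_sym(n)
  C <- random_binary_sym(n)
  got <- partial_mantel(M_v, M_b, C, n_perm = 99, seed = 2)
  ref <- vegan::mantel.partial(as.dist(M_v), as.dist(M_b), as.dist(C),
                               method = "pearson", permutations = 99)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("collinear and constant matrices are skipped or downgraded", {
  n <- 5
  M_const <- matrix(0L, n, n)
  M <- random_binary_sym(n)
  while (sd(M[upper.tri(M)]) == 0) M <- random_binary_sym(n)
  C <- random_binary_sym(n)
  while (sd(C[upper.tri(C)]) == 0 ||
         abs(cor(M[upper.tri(M)], C[upper.tri(C)])) > 0.9)
    C <- random_binary_sym(n)
  # constant sharing matrix cannot be tested
  expect_equal(partial_mantel(M_const, M, C)$status, "collinear_skipped")
  # sharing matrix identical to the control matrix: collinear with C
  expect_equal(partial_mantel(C, M, C)$status, "collinear_skipped")
  # constant control matrix falls back to the simple Mantel test
  res <- partial_mantel(M, M, M_const, n_perm = 99, seed = 1)
  expect_false(res$used_partial)
  expect_equal(res$status, "ok")
  expect_equal(res$r, 1)
})

test_that("non-random linkage computes Delta and the 2x2 table by hand", {
  # 10 pairs (n = 5 samples): virus shared in 6, bacterium in 5, both in 4
  v_shared <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  b_shared <- c(1, 1, 1, 1, 0, 0, 1, 0, 0, 0)
  vec2sym <- function(z) {
    M <- matrix(0L, 5, 5)
    M[upper.tri(M)] <- 1L - z   # 0 encodes "shared"
    M + t(M)
  }
  nl <- nonrandom_linkage(vec2sym(v_shared), vec2sym(b_shared))
  expect_equal(nl$f_obs, 0.4)
  expect_equal(nl$f_exp, 0.3)
  expect_equal(nl$delta, 0.1)
  expect_equal(unname(nl$table), matrix(c(4, 2, 1, 3), 2, byrow = TRUE))
  expect_equal(nl$p_chi2,
               suppressWarnings(chisq.test(matrix(c(4, 2, 1, 3), 2),
                                           correct = FALSE)$p.value))

  # identical matrices: Delta = f - f^2
  M <- vec2sym(v_shared)
  f <- mean(v_shared)
  expect_equal(nonrandom_linkage(M, M)$delta, f - f^2)

  # degenerate margin: p = 1 with a warning
  all_shared <- vec2sym(rep(1, 10))
  expect_warning(nl0 <- nonrandom_linkage(all_shared, vec2sym(b_shared)),
                 "degenerate")
  expect_equal(nl0$p_chi2, 1)
})

test_that("host-vs-random enrichment is a one-sided Fisher test", {
  res <- host_vs_random_enrichment(c(rep(TRUE, 14), rep(FALSE, 18)),
                                   c(rep(TRUE, 2), rep(FALSE, 30)))
  expect_equal(res$p, fisher.test(matrix(c(14, 18, 2, 30), 2, byrow = TRUE),
                                  alternative = "greater")$p.value)
  expect_equal(res$p, oracle_fisher_tail(14, 32, 16, 64))
  expect_gte(host_vs_random_enrichment(c(TRUE, FALSE), c(TRUE, FALSE))$p, 0.5)
  expect_warning(res0 <- host_vs_random_enrichment(logical(0), c(TRUE)),
                 "empty")
  expect_equal(res0$p, 1)
})

test_that("Mantel r is invariant to simultaneous relabeling of all matrices", {
  set.seed(55)
  n <- 7
  M_v <- random_binary_sym(n); M_b <- random_binary_sym(n)
  C <- random_binary_sym(n)
  r1 <- partial_mantel(M_v, M_b, C, n_perm = 9, seed = 1)$r
  p <- sample(n)
  r2 <- partial_mantel(M_v[p, p], M_b[p, p], C[p, p], n_perm = 9, seed = 1)$r
  expect_equal(r1, r2)
})
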