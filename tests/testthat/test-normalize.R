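cm_fixture <- function(seed = 42, n_genes = 20, n_libs = 3) {
  set.seed(seed)
  x <- matrix(rpois(n_genes * n_libs, 60) + seq_len(n_genes * n_libs), # distinct counts, no rank ties
              n_genes, n_libs,
              dimnames = list(sprintf("Yg%02d", seq_len(n_genes)),
                              sprintf("lib%d", seq_len(n_libs))))
  x[1:5, 2] <- x[1:5, 2] * 8L  # one library with a few inflated genes
  count_matrix(x)
}

test_that("TMM factors are 1 for identical or proportional libraries and have geometric mean 1", {
  base <- matrix(c(10L, 25L, 40L, 7L), 4, 1)
  same <- count_matrix(cbind(l1 = base, l2 = base, l3 = base) |>
                         (\(m) {rownames(m) <- paste0("Yg", 1:4); colnames(m) <- paste0("l", 1:3); m})())
  expect_equal(tmm_factors(same)$tmm_factor, rep(1, 3))

  dbl <- count_matrix(matrix(c(base, base * 2L), 4, 2,
                             dimnames = list(paste0("Yg", 1:4), c("A", "B"))))
  expect_equal(tmm_factors(dbl)$tmm_factor, c(1, 1))

  nf <- tmm_factors(cm_fixture())
  expect_equal(exp(mean(log(nf$tmm_factor))), 1, tolerance = 1e-12)
  expect_equal(nf$effective_lib_size, nf$raw_lib_size * nf$tmm_factor)
})

test_that("TMM matches a literal trim-and-weight oracle and the reference implementation", {
  cm <- cm_fixture()
  nf <- tmm_factors(cm)
  expect_equal(nf$tmm_factor, oracle_tmm(unclass(cm)), tolerance = 1e-10)
  skip_if_not_installed("edgeR")
  ed <- edgeR::calcNormFactors(edgeR::DGEList(unclass(cm)))
  expect_equal(nf$tmm_factor, unname(ed$samples$norm.factors), tolerance = 1e-10)
})

test_that("TMM is invariant to library relabeling, and degenerate inputs error", {
  cm <- cm_fixture(seed = 9, n_libs = 4)
  nf <- tmm_factors(cm)
  perm <- c(3, 1, 4, 2)
  nf_p <- tmm_factors(count_matrix(unclass(cm)[, perm]))
  expect_equal(nf_p$tmm_factor[order(perm)], nf$tmm_factor, tolerance = 1e-12)

  z <- unclass(cm); z[, 2] <- 0L
  expect_error(tmm_factors(count_matrix(z)), "zero total count")
  expect_error(tmm_factors(count_matrix(unclass(cm)[, 1, drop = FALSE])),
               "at least 2")
})

test_that("log-CPM matches the closed-form prior-damped formula", {
  cm <- count_matrix(matrix(c(0L, 999990L, 10L, 999990L), 2, 2,
                            dimnames = list(c("Ylow", "Yhigh"), c("l1", "l2"))))
  nf <- data.frame(library_id = c("l1", "l2"), raw_lib_size = 1e6,
                   tmm_factor = 1, effective_lib_size = 1e6)
  e <- log_cpm(cm, nf, prior_count = 20)
  # equal effective sizes: p_j = 20, value = log2((c + 20) / (1e6 + 40) * 1e6)
  expect_equal(e["Ylow", "l1"], log2(20 / (1e6 + 40) * 1e6), tolerance = 1e-12)
  expect_equal(e["Ylow", "l2"], log2(30 / (1e6 + 40) * 1e6), tolerance = 1e-12)
  expect_equal(e["Ylow", "l1"], 4.3218705, tolerance = 1e-6)
  expect_equal(e["Ylow", "l2"], 4.9068333, tolerance = 1e-6)
  expect_true(all(is.finite(e)))
})

test_that("log-CPM agrees with the reference implementation on realistic counts", {
  skip_if_not_installed("edgeR")
  cm <- cm_fixture(seed = 5, n_genes = 50, n_libs = 4)
  nf <- tmm_factors(cm)
  mine <- log_cpm(cm, nf, prior_count = 20)
  dge <- edgeR::calcNormFactors(edgeR::DGEList(unclass(cm)))
  ref <- edgeR::cpm(dge, log = TRUE, prior.count = 20)
  expect_equal(unclass(mine), ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("log-CPM is scale-invariant, monotone in counts, and converges to plain CPM as the prior vanishes", {
  cm <- cm_fixture(seed = 3)
  nf <- tmm_factors(cm)
  e1 <- log_cpm(cm, nf)
  # the prior is scaled by relative, not absolute, library size, so doubling
  # every count is equivalent to halving the prior: values are unchanged
  # exactly when the prior doubles with the depth
  cm2 <- count_matrix(unclass(cm) * 2L)
  nf2 <- tmm_factors(cm2)
  expect_equal(unclass(log_cpm(cm2, nf2, prior_count = 40)), unclass(e1),
               tolerance = 1e-9, ignore_attr = TRUE)

  bumped <- unclass(cm); bumped[3, 1] <- bumped[3, 1] + 50L
  e_b <- log_cpm(count_matrix(bumped), nf)
  expect_gt(e_b[3, 1], e1[3, 1])
  expect_equal(e_b[-3, ], unclass(e1)[-3, ], ignore_attr = TRUE)

  tiny <- log_cpm(cm, nf, prior_count = 1e-9)
  plain <- log2(sweep(unclass(cm) + 0, 2, nf$effective_lib_size / 1e6, "/"))
  expect_equal(unclass(tiny), plain, tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(log_cpm(cm, nf[-1, ]), "missing from normalization")
})
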