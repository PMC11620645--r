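test_that("factor isolation zeroes the removed factor's level means exactly", {
  d <- make_design(reps = 3)
  # gene varying only with the removed (spatio) factor vanishes entirely
  Y <- make_expr(d, function(g, s, gene) c(day2 = 1, day5_in = 2, day5_out = 3)[s],
                 n_genes = 1)
  iso <- isolate_factor(Y, d, keep = "genotype")
  expect_equal(max(abs(iso)), 0, tolerance = 1e-12)

  # kept-factor contrasts survive isolation on a balanced design
  Yg <- make_expr(d, function(g, s, gene) c(tec1 = 0, wt = 1, sfl1 = 2, dig1 = 3)[g],
                  n_genes = 1)
  iso_g <- isolate_factor(Yg, d, keep = "genotype")
  expect_equal(unname(iso_g[1, ]), unname(Yg[1, ] - mean(Yg[1, ])),
               tolerance = 1e-12)

  set.seed(10)
  Yr <- make_expr(d, function(g, s, gene) 0, n_genes = 5, noise_sd = 1)
  iso_r <- isolate_factor(Yr, d, keep = "genotype")
  for (lev in spatio_levels())
    expect_equal(max(abs(rowMeans(iso_r[, d$spatio == lev]))), 0,
                 tolerance = 1e-12)
})

test_that("hierarchical clustering recovers planted groups and handles edge cases", {
  d <- make_design(reps = 3)
  set.seed(77)
  grp1 <- make_expr(d, function(g, s, gene) 2 * (s == "day2"), n_genes = 6,
                    noise_sd = 0.2, gene_ids = sprintf("Yup%d", 1:6))
  grp2 <- make_expr(d, function(g, s, gene) 2 * (s == "day5_out"), n_genes = 6,
                    noise_sd = 0.2, gene_ids = sprintf("Ydown%d", 1:6))
  cr <- cluster_genes(rbind(grp1, grp2), k = 2)
  expect_true(same_partition(cr$assignments,
                             rep(c("a", "b"), each = 6)))

  # k = n gives singletons
  crn <- cluster_genes(grp1, k = 6)
  expect_equal(length(unique(crn$assignments)), 6L)

  # duplicated rows always co-cluster
  dup <- rbind(grp1, Ycopy = grp1[1, ])
  for (k in 2:5) {
    a <- cluster_genes(dup, k = k)$assignments
    expect_identical(unname(a["Yup1"]), unname(a["Ycopy"]))
  }

  expect_error(cluster_genes(grp1, k = 7), "exceeds")
  flatrow <- grp1; flatrow[2, ] <- 5
  expect_error(cluster_genes(flatrow, k = 2), "Yup2")
})

test_that("complete-linkage agglomeration agrees with a naive O(n^3) oracle", {
  d <- make_design(reps = 1)
  set.seed(123)
  Y <- make_expr(d, function(g, s, gene) 0, n_genes = 12, noise_sd = 1)
  Z <- t(scale(t(Y)))
  for (k in c(2, 4, 7, 11)) {
    mine <- cluster_genes(Y, k = k)$assignments
    orc <- oracle_complete_linkage(Z, k)
    expect_true(same_partition(mine, orc), info = paste("k =", k))
  }
})

test_that("each template self-classifies and hand-computed correlations hold", {
  d <- make_design(reps = 3)
  tpls <- default_templates()
  Y <- t(vapply(tpls, function(p) p[as.integer(d$spatio)], numeric(36)))
  rownames(Y) <- paste0("Y", names(tpls)); colnames(Y) <- d$library_id
  got <- template_classify(Y, d)
  expect_identical(got$template, names(tpls))
  expect_equal(got$correlation, rep(1, 8))

  # (1,0,0) matches C1 = (2,0,0) exactly (affine invariance); its
  # correlation with C5 = (2,1,0) is sqrt(3)/2
  y100 <- matrix(c(1, 0, 0)[as.integer(d$spatio)], 1,
                 dimnames = list("Yx", d$library_id))
  r <- template_classify(y100, d)
  expect_identical(r$template, "C1")
  expect_equal(r$correlation, 1)
  expect_equal(attr(r, "correlations")[1, "C5"], sqrt(3) / 2, tolerance = 1e-12)

  y012 <- matrix(c(0, 1, 2)[as.integer(d$spatio)], 1,
                 dimnames = list("Yx", d$library_id))
  r2 <- template_classify(y012, d)
  expect_identical(r2$template, "C6")
  expect_equal(attr(r2, "correlations")[1, "C4"], sqrt(3) / 2, tolerance = 1e-12)

  expect_error(template_classify(matrix(1, 1, 36,
                                        dimnames = list("Yflat", d$library_id)), d),
               "constant gene")
})

test_that("template assignment is invariant to per-gene affine transforms", {
  d <- make_design(reps = 3)
  set.seed(14)
  Y <- make_expr(d, function(g, s, gene) c(day2 = 2, day5_in = 0, day5_out = 1)[s],
                 n_genes = 10, noise_sd = 0.4)
  base <- template_classify(Y, d)
  scaled <- template_classify(Y * 3.7 - 12, d)
  expect_identical(base$template, scaled$template)
})

test_that("genotype clusters are labeled by the direction of their mean profile", {
  d <- make_design(reps = 3)
  set.seed(42)
  ramp <- c(tec1 = -1.5, wt = -0.5, sfl1 = 0.5, dig1 = 1.5)
  up <- make_expr(d, function(g, s, gene) ramp[g], n_genes = 10, noise_sd = 0.3,
                  gene_ids = sprintf("Yup%02d", 1:10))
  down <- make_expr(d, function(g, s, gene) -ramp[g], n_genes = 10, noise_sd = 0.3,
                    gene_ids = sprintf("Ydn%02d", 1:10))
  peak <- make_expr(d, function(g, s, gene) 2 * (g == "sfl1"), n_genes = 10,
                    noise_sd = 0.3, gene_ids = sprintf("Ypk%02d", 1:10))
  cr <- genotype_clusters(rbind(up, down, peak), d)
  a <- cr$assignments
  expect_true(all(a[paste0("Yup", sprintf("%02d", 1:10))] == "G1"))
  expect_true(all(a[paste0("Ydn", sprintf("%02d", 1:10))] == "G2"))
  expect_true(all(a[paste0("Ypk", sprintf("%02d", 1:10))] == "G3"))
  expect_false(attr(cr, "degenerate"))

  # a single shared pattern forced into 3 clusters is flagged
  one <- make_expr(d, function(g, s, gene) ramp[g], n_genes = 12, noise_sd = 0.05,
                   gene_ids = sprintf("Yone%02d", 1:12))
  expect_warning(gd <- genotype_clusters(one, d), "degenerate|ranking")
  expect_true(attr(gd, "degenerate"))
})

test_that("interaction and list clustering recover planted patterns and validate k", {
  d <- make_design(reps = 3)
  set.seed(31)
  patterns <- lapply(1:9, function(i) {
    m <- matrix(rnorm(12, sd = 2), 4, 3,
                dimnames = list(genotype_levels(), spatio_levels()))
    function(g, s, gene) m[g, s]
  })
  Y <- do.call(rbind, lapply(1:9, function(i)
    make_expr(d, patterns[[i]], n_genes = 5, noise_sd = 0.2,
              gene_ids = sprintf("Yp%d_%d", i, 1:5))))
  cr <- interaction_clusters(Y, d, k = 9)
  expect_true(same_partition(cr$assignments, rep(1:9, each = 5)))
  expect_setequal(unique(cr$assignments), paste0("I", 1:9))

  expect_error(extracellular_clusters(Y, d, genes = rownames(Y)[1:4], k = 5),
               "exceeds")

  # a ruffled-morphology signature (high where genotype and region are
  # jointly structured, graded at day 2) co-clusters at k = 9
  ruff <- function(g, s, gene) {
    base <- c(tec1 = 0, wt = 0.3, sfl1 = 0.6, dig1 = 0.9)[g]
    if (s != "day2" && ((g == "wt" && s == "day5_out") || g %in% c("sfl1", "dig1")))
      base + 3 else base
  }
  Y2 <- rbind(Y, make_expr(d, ruff, n_genes = 6, noise_sd = 0.2,
                           gene_ids = sprintf("Yruf%d", 1:6)))
  cr2 <- interaction_clusters(Y2, d, k = 10)
  expect_equal(length(unique(cr2$assignments[sprintf("Yruf%d", 1:6)])), 1L)
})
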