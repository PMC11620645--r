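# Two-level toy design used for hand-verifiable sums of squares.
design_2x2 <- function() make_design(reps = 2, genotypes = c("gA", "gB"),
                                     spatios = c("sX", "sY"))

test_that("2x2 fixture reproduces hand-computed sums of squares and F statistics", {
  d <- design_2x2()
  cell_mean <- c(gA.sX = 1, gA.sY = 2, gB.sX = 3, gB.sY = 4)
  y <- cell_mean[paste(d$genotype, d$spatio, sep = ".")] +
    rep(c(0.5, -0.5), 4)  # +-0.5 within every cell
  fit <- fit_gene(unname(y), d)
  # hand decomposition: genotype means 1.5/3.5 -> SS_A = 8; spatio means 2/3
  # -> SS_B = 2; cell means additive -> SS_int = 0; 8 deviations of 0.5 ->
  # SSE = 2 on 5 additive-model residual df
  expect_equal(fit$add_SS_genotype, 8)
  expect_equal(fit$add_SS_spatio, 2)
  expect_equal(fit$int_SS, 0, tolerance = 1e-12)
  expect_equal(fit$add_F_genotype, (8 / 1) / (2 / 5))  # = 20
  expect_equal(fit$add_F_spatio, (2 / 1) / (2 / 5))    # = 5
  expect_equal(fit$int_p_interaction, 1, tolerance = 1e-10)
  expect_equal(fit$add_r2, 10 / 12)
  expect_equal(fit$variance, 12 / 7)
})

test_that("degenerate genes follow the stated conventions", {
  d <- design_2x2()
  flat <- fit_gene(rep(3.7, 8), d)
  expect_true(all(flat[grep("_p_", names(flat))] == 1))
  expect_equal(flat$add_r2, 0)
  expect_equal(flat$int_r2, 0)

  cell_mean <- c(gA.sX = 1, gA.sY = 2, gB.sX = 3, gB.sY = 4)
  perfect <- fit_gene(unname(cell_mean[paste(d$genotype, d$spatio, sep = ".")]), d)
  expect_equal(perfect$add_r2, 1)
  expect_equal(perfect$add_p_genotype, 0)   # zero residual, nonzero term SS
  expect_equal(perfect$int_p_interaction, 1)  # zero residual AND zero term SS
})

test_that("F and p agree with a least-squares model-comparison oracle on random fixtures", {
  d <- make_design(reps = 3)
  set.seed(101)
  for (i in 1:20) {
    y <- rnorm(36, sd = runif(1, 0.2, 2)) +
      as.integer(d$genotype) * runif(1, 0, 1) + as.integer(d$spatio) * runif(1, 0, 1)
    fit <- fit_gene(y, d)
    orc <- oracle_anova(y, d)
    expect_equal(fit$add_F_genotype, orc$genotype$F, tolerance = 1e-8)
    expect_equal(fit$add_p_genotype, orc$genotype$p, tolerance = 1e-8)
    expect_equal(fit$add_F_spatio, orc$spatio$F, tolerance = 1e-8)
    expect_equal(fit$int_F, orc$interaction$F, tolerance = 1e-8)
    expect_equal(fit$int_p_interaction, orc$interaction$p, tolerance = 1e-8)
    expect_equal(fit$add_F_null, orc$add_null$F, tolerance = 1e-8)
    expect_equal(fit$int_F_null, orc$int_null$F, tolerance = 1e-8)
    expect_equal(fit$add_r2, orc$add_r2, tolerance = 1e-10)
    expect_equal(fit$int_r2, orc$int_r2, tolerance = 1e-10)
  }
})

test_that("unbalanced designs still match the model-comparison oracle (type II by construction)", {
  d <- sample_design(as.data.frame(make_design(reps = 3))[-c(1, 2, 14), ])
  expect_false(attr(d, "balanced"))
  set.seed(7)
  y <- rnorm(nrow(d)) + as.integer(d$genotype) * 0.6
  fit <- fit_gene(y, d)
  orc <- oracle_anova(y, d)
  expect_equal(fit$add_p_genotype, orc$genotype$p, tolerance = 1e-8)
  expect_equal(fit$add_p_spatio, orc$spatio$p, tolerance = 1e-8)
  expect_equal(fit$int_p_interaction, orc$interaction$p, tolerance = 1e-8)
})

test_that("balanced-design sums of squares decompose orthogonally", {
  d <- make_design(reps = 3)
  set.seed(55)
  for (i in 1:10) {
    y <- rnorm(36, sd = 1.3)
    fit <- fit_gene(y, d)
    ss_tot <- fit$variance * 35
    sse_f <- (1 - fit$int_r2) * ss_tot
    expect_equal(fit$add_SS_genotype + fit$add_SS_spatio + fit$int_SS + sse_f,
                 ss_tot, tolerance = 1e-10)
  }
})

test_that("Holm adjustment matches the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(holm_adjust(0.2), 0.2)
  set.seed(8)
  p <- runif(200)^2
  adj <- holm_adjust(p)
  expect_equal(adj, oracle_holm(p))
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fit_all adjusts each of the five p-value families separately across genes", {
  d <- make_design(reps = 3)
  set.seed(12)
  Y <- make_expr(d, function(g, s, gene) if (gene == 1) 2 * (s == "day2") else 0,
                 n_genes = 2, noise_sd = 0.5)
  fits <- fit_all(Y, d)
  for (fam in c("add_p_genotype", "add_p_spatio", "int_p_interaction",
                "add_p_null", "int_p_null")) {
    expect_equal(fits[[paste0("adj_", fam)]], holm_adjust(fits[[fam]]),
                 info = fam)
  }
})

test_that("genes with pure spatiotemporal effects are called on that term only", {
  d <- make_design(reps = 3)
  set.seed(21)
  n_eff <- 50
  Y <- rbind(
    make_expr(d, function(g, s, gene) c(day2 = 1, day5_in = -1, day5_out = 0)[s],
              n_genes = n_eff, noise_sd = 0.3,
              gene_ids = sprintf("Yeff%02d", 1:n_eff)),
    make_expr(d, function(g, s, gene) 0, n_genes = 50, noise_sd = 0.3,
              gene_ids = sprintf("Ynull%02d", 1:50)))
  fits <- fit_all(Y, d)
  eff <- grepl("^Yeff", fits$gene_id)
  expect_gte(mean(fits$adj_add_p_spatio[eff] < 0.01), 0.95)
  expect_gte(mean(fits$adj_add_p_genotype[eff] > 0.1), 0.95)
})

test_that("designs with an empty cell are rejected with the cell named", {
  d <- as.data.frame(make_design(reps = 1))
  d <- d[!(d$genotype == "sfl1" & d$spatio == "day2"), ]
  expect_error(sample_design(d), "sfl1.*day2")
})
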