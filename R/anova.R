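# Per-gene two-factor ANOVA on log2 expression. All genes share one design,
# so residual-maker (annihilator) matrices for the five nested models are
# built once and every sum of squares is a quadratic form evaluated for all
# genes by two matrix products. Type II main-effect SS are model-comparison
# differences SS(g | s) = SSE(s) - SSE(g+s); the interaction SS adjusted for
# both main effects (type III for the highest-order term, contrast-invariant)
# is SSE(g+s) - SSE(g*s). Sum-to-zero contrasts are used for the full model.

# Residual projectors and degrees of freedom for a design. Factors with a
# single observed level are dropped from the model (their term p is NA).
.design_projectors <- function(design) {
  g <- droplevels(design$genotype)
  s <- droplevels(design$spatio)
  n <- nrow(design)
  has_g <- nlevels(g) >= 2L
  has_s <- nlevels(s) >= 2L
  if (!has_g && !has_s) stop("design has no factor with 2 or more levels")
  ann <- function(X) diag(n) - tcrossprod(qr.Q(qr(X)))
  one <- matrix(1, n, 1)
  ctr <- list(genotype = stats::contr.sum, spatio = stats::contr.sum)
  df_mm <- data.frame(genotype = g, spatio = s)
  Xg <- if (has_g) stats::model.matrix(~genotype, df_mm, contrasts.arg = ctr["genotype"]) else one
  Xs <- if (has_s) stats::model.matrix(~spatio, df_mm, contrasts.arg = ctr["spatio"]) else one
  Xa <- if (has_g && has_s)
    stats::model.matrix(~genotype + spatio, df_mm, contrasts.arg = ctr)
  else if (has_g) Xg else Xs
  Xf <- if (has_g && has_s)
    stats::model.matrix(~genotype * spatio, df_mm, contrasts.arg = ctr)
  else Xa
  if (has_g && has_s) {
    cells <- table(g, s)
    empty <- which(cells == 0, arr.ind = TRUE)
    if (nrow(empty))
      stop("singular design: empty cell(s) ",
           paste(sprintf("(%s, %s)", rownames(cells)[empty[, 1]],
                         colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  df_rf <- n - ncol(Xf)
  if (df_rf < 1L)
    stop("interaction model has no residual degrees of freedom (need >= 1)")
  list(R_null = ann(one), R_g = ann(Xg), R_s = ann(Xs),
       R_a = ann(Xa), R_f = ann(Xf),
       n = n, has_g = has_g, has_s = has_s,
       df_g = if (has_g) nlevels(g) - 1L else 0L,
       df_s = if (has_s) nlevels(s) - 1L else 0L,
       df_int = if (has_g && has_s) (nlevels(g) - 1L) * (nlevels(s) - 1L) else 0L,
       df_ra = n - ncol(Xa), df_rf = df_rf)
}

# F-test p-value with the degenerate conventions: a zero residual makes the
# tested term certain (p = 0) unless its own SS is also zero (p = 1).
# Tolerances are relative to the gene's total SS.
.term_p <- function(ss_term, df_term, sse, df_res, tol) {
  p <- rep(NA_real_, length(ss_term))
  if (df_term < 1L) return(p)
  zero_res <- sse <= tol
  ok <- !zero_res
  f <- (ss_term[ok] / df_term) / (sse[ok] / df_res)
  p[ok] <- stats::pf(f, df_term, df_res, lower.tail = FALSE)
  p[zero_res] <- ifelse(ss_term[zero_res] <= tol[zero_res], 1, 0)
  p
}

.term_F <- function(ss_term, df_term, sse, df_res) {
  if (df_term < 1L) return(rep(NA_real_, length(ss_term)))
  ifelse(sse > 0, (ss_term / df_term) / (sse / df_res), Inf)
}

# Raw per-gene statistics for an expression matrix Y (genes x libraries,
# columns in design order) given precomputed projectors.
.anova_stats <- function(Y, pj) {
  sse_of <- function(R) pmax(rowSums((Y %*% R) * Y), 0)
  sse_null <- sse_of(pj$R_null)
  sse_g <- sse_of(pj$R_g)
  sse_s <- sse_of(pj$R_s)
  sse_a <- sse_of(pj$R_a)
  sse_f <- sse_of(pj$R_f)
  ss_tot <- sse_null
  # relative to the gene's total SS, with an absolute floor against genes
  # whose SS_total is itself numerical noise (constant profiles)
  tol <- pmax(1e-12 * ss_tot, 1e-9 * rowSums(Y * Y), .Machine$double.xmin)
  ss_gII <- pmax(sse_s - sse_a, 0)   # SS(genotype | spatio)
  ss_sII <- pmax(sse_g - sse_a, 0)   # SS(spatio | genotype)
  ss_int <- pmax(sse_a - sse_f, 0)   # SS(g:s | g, s)
  ss_amod <- pmax(sse_null - sse_a, 0)
  ss_fmod <- pmax(sse_null - sse_f, 0)
  df_amod <- pj$df_g + pj$df_s
  df_fmod <- df_amod + pj$df_int
  out <- data.frame(
    gene_id = rownames(Y),
    variance = ss_tot / (pj$n - 1),
    add_SS_genotype = ss_gII, add_SS_spatio = ss_sII,
    add_F_genotype = .term_F(ss_gII, pj$df_g, sse_a, pj$df_ra),
    add_F_spatio = .term_F(ss_sII, pj$df_s, sse_a, pj$df_ra),
    add_p_genotype = .term_p(ss_gII, pj$df_g, sse_a, pj$df_ra, tol),
    add_p_spatio = .term_p(ss_sII, pj$df_s, sse_a, pj$df_ra, tol),
    add_F_null = .term_F(ss_amod, df_amod, sse_a, pj$df_ra),
    add_p_null = .term_p(ss_amod, df_amod, sse_a, pj$df_ra, tol),
    add_r2 = ifelse(ss_tot > tol, pmin(pmax(1 - sse_a / ss_tot, 0), 1), 0),
    int_SS = ss_int,
    int_F = .term_F(ss_int, pj$df_int, sse_f, pj$df_rf),
    int_p_interaction = .term_p(ss_int, pj$df_int, sse_f, pj$df_rf, tol),
    int_F_null = .term_F(ss_fmod, df_fmod, sse_f, pj$df_rf),
    int_p_null = .term_p(ss_fmod, df_fmod, sse_f, pj$df_rf, tol),
    int_r2 = ifelse(ss_tot > tol, pmin(pmax(1 - sse_f / ss_tot, 0), 1), 0),
    row.names = NULL)
  # a constant gene carries no evidence for any term
  flat <- ss_tot <= tol
  if (any(flat)) {
    for (pc in grep("_p_", names(out)))  # NA marks a term absent from the design
      out[[pc]][flat] <- ifelse(is.na(out[[pc]][flat]), NA_real_, 1)
    out[flat, c("add_r2", "int_r2")] <- 0
  }
  out
}

#' Fit the additive and interaction two-factor models for one gene
#'
#' The additive model `y ~ genotype + spatio` is summarized by type II
#' per-term sums of squares and F tests against its own residual; the
#' interaction model `y ~ genotype * spatio` contributes the interaction
#' term (adjusted for both main effects, sum-to-zero contrasts) tested
#' against the full-model residual. Each model is also tested against the
#' single-mean null, and r2 = 1 - SSE/SS_total is reported for both models.
#'
#' @param y numeric expression vector, one value per design row.
#' @param design a [sample_design].
#' @return one-row data.frame of raw (un-adjusted) per-gene statistics.
#' @export
fit_gene <- function(y, design) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  if (length(y) != nrow(design))
    stop("expression vector length differs from design size")
  Y <- matrix(y, nrow = 1, dimnames = list("gene", design$library_id))
  .anova_stats(Y, .design_projectors(design))
}

#' Holm step-down familywise p-value adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Fit per-gene two-factor models across an expression matrix
#'
#' Applies [fit_gene] (vectorized over genes) and then Holm-adjusts each
#' p-value family separately across genes. The five families are the
#' additive genotype term, the additive spatiotemporal term, the interaction
#' term, the additive-model-vs-null comparison and the
#' interaction-model-vs-null comparison.
#'
#' @param expr an `expr_matrix` (genes x libraries) from [log_cpm], or any
#'   numeric matrix of log2 expression.
#' @param design a [sample_design] covering the matrix columns.
#' @return data.frame of class `gene_fits`: raw statistics plus Holm-adjusted
#'   columns `adj_add_p_genotype`, `adj_add_p_spatio`, `adj_int_p_interaction`,
#'   `adj_add_p_null`, `adj_int_p_null`.
#' @export
fit_all <- function(expr, design) {
  Y <- .align_expr(expr, design)
  fits <- .anova_stats(Y, .design_projectors(design))
  fits$adj_add_p_genotype <- holm_adjust(fits$add_p_genotype)
  fits$adj_add_p_spatio <- holm_adjust(fits$add_p_spatio)
  fits$adj_int_p_interaction <- holm_adjust(fits$int_p_interaction)
  fits$adj_add_p_null <- holm_adjust(fits$add_p_null)
  fits$adj_int_p_null <- holm_adjust(fits$int_p_null)
  class(fits) <- c("gene_fits", "data.frame")
  fits
}

# Reorder expression columns to design row order; loud failure on mismatch.
.align_expr <- function(expr, design) {
  Y <- unclass(expr)
  if (is.null(dim(Y))) stop("expression input must be a matrix")
  miss <- setdiff(design$library_id, colnames(Y))
  extra <- setdiff(colnames(Y), design$library_id)
  if (length(miss) || length(extra))
    stop("expression/design library mismatch",
         if (length(miss)) paste0("; missing from expression: ",
                                  paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; absent from design: ",
                                   paste(extra, collapse = ", ")))
  Y[, design$library_id, drop = FALSE]
}
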