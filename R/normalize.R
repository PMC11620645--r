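# Between-library scaling by trimmed mean of M-values (TMM) and conversion
# to prior-damped log2 counts per million. The log-CPM dialect (library-size
# scaled prior, denominator offset by twice the scaled prior) is the one the
# standard count-analysis toolchain uses; reproducing published normalized
# tables requires this exact form.

#' TMM scaling factors
#'
#' Computes trimmed-mean-of-M-values normalization factors. The reference
#' library is the one whose 75th-percentile count fraction is closest to the
#' mean such fraction (ties broken by lowest column index). For every library
#' the per-gene log2 fold changes M and average log2 abundances A against the
#' reference are computed over genes with positive counts in both libraries,
#' doubly trimmed (`trim_M` of the most extreme M on each side, `trim_A` of
#' the most extreme A), and the factor is 2 to the precision-weighted mean of
#' the retained M, with inverse-variance weights from the binomial
#' delta-method approximation. Factors are rescaled to geometric mean 1.
#'
#' @param cm a [count_matrix] (at least two libraries, each with positive
#'   total count).
#' @param trim_M fraction of extreme M-values trimmed on each side (0.30).
#' @param trim_A fraction of extreme A-values trimmed on each side (0.05).
#' @return data.frame of class `norm_factors` with columns `library_id`,
#'   `raw_lib_size`, `tmm_factor`, `effective_lib_size`.
#' @export
tmm_factors <- function(cm, trim_M = 0.30, trim_A = 0.05) {
  x <- unclass(cm)
  if (ncol(x) < 2L) stop("TMM requires at least 2 libraries")
  lib_size <- colSums(x + 0)  # numeric, avoids integer overflow
  x <- x[rowSums(x > 0) > 0, , drop = FALSE]  # all-zero genes carry no ratio information
  if (any(lib_size <= 0))
    stop("library with zero total count: ",
         paste(colnames(x)[lib_size <= 0], collapse = ", "))
  f75 <- vapply(seq_len(ncol(x)),
                function(j) stats::quantile(x[, j], 0.75) / lib_size[j], 0)
  ref <- which.min(abs(f75 - mean(f75)))  # which.min takes the first tie
  factors <- vapply(seq_len(ncol(x)), function(j) {
    .tmm_pair(x[, j], x[, ref], lib_size[j], lib_size[ref],
              trim_M = trim_M, trim_A = trim_A)
  }, 0)
  factors <- factors / exp(mean(log(factors)))
  structure(data.frame(library_id = colnames(x),
                       raw_lib_size = lib_size,
                       tmm_factor = factors,
                       effective_lib_size = lib_size * factors,
                       row.names = NULL),
            class = c("norm_factors", "data.frame"),
            reference = colnames(x)[ref])
}

# One library against the reference: doubly trimmed, weighted mean of M.
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  pos <- obs > 0 & ref > 0
  obs <- as.numeric(obs[pos]); ref <- as.numeric(ref[pos])
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  keep <- is.finite(M) & is.finite(A)
  M <- M[keep]; A <- A[keep]; w <- w[keep]
  n <- length(M)
  if (!n) return(1)
  if (max(abs(M)) < 1e-6) return(1)  # identical composition
  lo_M <- floor(n * trim_M) + 1; hi_M <- n + 1 - lo_M
  lo_A <- floor(n * trim_A) + 1; hi_A <- n + 1 - lo_A
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= lo_M & rM <= hi_M & rA >= lo_A & rA <= hi_A
  if (!any(keep)) return(1)
  f <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
  if (!is.finite(f) || abs(f) < 1e-6) f <- 0
  2^f
}

#' Prior-damped log2 counts per million
#'
#' For library j with effective size N_j and mean effective size Nbar, the
#' scaled prior is p_j = prior_count * N_j / Nbar and
#' value(g, j) = log2( (count(g, j) + p_j) / (N_j + 2 p_j) * 1e6 ).
#' The prior bounds the variance of low-expression genes; the default 20 is
#' deliberately heavy damping for noisy low counts.
#'
#' @param cm a [count_matrix].
#' @param nf [tmm_factors] output covering all libraries of `cm`.
#' @param prior_count positive damping constant (default 20).
#' @return numeric matrix of class `expr_matrix` (genes x libraries) of
#'   log2 CPM values, with attribute `prior_count`.
#' @export
log_cpm <- function(cm, nf, prior_count = 20) {
  stopifnot(prior_count > 0)
  x <- unclass(cm) + 0
  miss <- setdiff(colnames(x), nf$library_id)
  if (length(miss))
    stop("library missing from normalization factors: ",
         paste(miss, collapse = ", "))
  eff <- nf$effective_lib_size[match(colnames(x), nf$library_id)]
  p <- prior_count * eff / mean(eff)
  v <- log2(sweep(sweep(x, 2, p, "+"), 2, (eff + 2 * p) / 1e6, "/"))
  structure(v, prior_count = prior_count,
            class = c("expr_matrix", class(v)))
}
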