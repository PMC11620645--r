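# Cluster-overlap contingency analysis: cross-tabulation of cluster
# memberships and Fisher exact tests of independence. The 2x2 test is
# computed directly from the hypergeometric distribution (the one-sided
# upper tail and the probability-ordering two-sided definition); r x c
# tables use the exact conditional network algorithm, falling back to
# Monte Carlo for large totals.

#' Cross-tabulate two gene-label assignments
#'
#' @param a,b named vectors (names = gene ids, values = labels). The
#'   intersection of the two gene universes is tabulated.
#' @return a contingency table (class `table`) with attribute `n_common`,
#'   rows from `a`, columns from `b`.
#' @export
crosstab <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (!length(common)) stop("label maps share no genes")
  tt <- table(a = as.character(a[common]), b = as.character(b[common]))
  attr(tt, "n_common") <- length(common)
  tt
}

#' Fisher's exact test for a 2x2 table
#'
#' Enumerates the hypergeometric distribution of the top-left cell given the
#' margins. `one_greater` is the upper tail on that cell (enrichment);
#' `two_sided` sums the probabilities of all outcomes no more likely than
#' the observed one (probability-ordering definition).
#'
#' @param m 2x2 matrix of non-negative counts.
#' @param tail `"one_greater"` or `"two_sided"`.
#' @return list with `p_value`, `odds_ratio` (sample odds ratio), `tail`.
#' @export
fisher_2x2 <- function(m, tail = c("one_greater", "two_sided")) {
  tail <- match.arg(tail)
  m <- as.matrix(m)
  if (!all(dim(m) == 2L)) stop("fisher_2x2 requires a 2x2 table")
  if (any(m < 0)) stop("negative cell count")
  x <- m[1, 1]
  m1 <- sum(m[1, ]); m2 <- sum(m[2, ]); kk <- sum(m[, 1])
  lo <- max(0, kk - m2); hi <- min(kk, m1)
  support <- lo:hi
  probs <- stats::dhyper(support, m1, m2, kk)
  p <- if (tail == "one_greater") {
    sum(probs[support >= x])
  } else {
    # relative tolerance guards against ties lost to floating rounding
    sum(probs[probs <= probs[support == x] * (1 + 1e-7)])
  }
  list(p_value = min(p, 1),
       odds_ratio = (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]),
       tail = tail)
}

#' Fisher's exact test for an r x c table
#'
#' Exact conditional test (probability-ordering two-sided definition) when
#' the table total is at most `max_exact_n` (or the table is 2x2, which
#' delegates to [fisher_2x2]); otherwise a Monte-Carlo estimate over tables
#' with the observed margins, returned with its standard error. Rows or
#' columns with a zero margin are dropped with a warning.
#'
#' @param m matrix of non-negative counts.
#' @param max_exact_n largest table total for the exact path (default 200).
#' @param B Monte-Carlo replicates (default 1e7).
#' @param seed RNG seed for the Monte-Carlo path.
#' @return list with `p_value`, `method`, `se` (NA unless Monte Carlo),
#'   `seed` (NA unless Monte Carlo).
#' @export
fisher_rxc <- function(m, max_exact_n = 200, B = 1e7, seed = 1L) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative cell count")
  zr <- rowSums(m) == 0; zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero-margin row(s) and ",
            sum(zc), " zero-margin column(s)")
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (min(dim(m)) <= 1L)
    return(list(p_value = 1, method = "degenerate", se = NA_real_,
                seed = NA_integer_))
  if (all(dim(m) == 2L)) {
    ft <- fisher_2x2(m, tail = "two_sided")
    return(list(p_value = ft$p_value, method = "exact_2x2", se = NA_real_,
                seed = NA_integer_))
  }
  if (sum(m) <= max_exact_n) {
    p <- stats::fisher.test(m, workspace = 2e8)$p.value
    return(list(p_value = min(p, 1), method = "exact_network", se = NA_real_,
                seed = NA_integer_))
  }
  set.seed(seed)
  p <- stats::fisher.test(m, simulate.p.value = TRUE, B = B)$p.value
  list(p_value = p, method = "monte_carlo",
       se = sqrt(p * (1 - p) / B), seed = as.integer(seed))
}

#' Reconstruct the 2x2 overlap table behind two responder sets
#'
#' Builds the contingency table of genotype-responsive against
#' spatiotemporally-responsive genes from printed summary counts. Under the
#' `inclusive` reading the two responder totals each contain the overlap
#' (the overlap is a subset of both); under `exclusive` the totals exclude
#' it.
#'
#' @param n_spatio genes responding to the spatiotemporal factor.
#' @param n_genotype genes responding to the genotype factor.
#' @param n_both genes responding to both.
#' @param n_universe total genes tested.
#' @param reading `"inclusive"` (default) or `"exclusive"`.
#' @return 2x2 integer matrix; rows = genotype responder yes/no, columns =
#'   spatiotemporal responder yes/no.
#' @export
both_factor_table <- function(n_spatio, n_genotype, n_both, n_universe,
                              reading = c("inclusive", "exclusive")) {
  reading <- match.arg(reading)
  a <- n_both                                        # spatio yes, genotype yes
  b <- if (reading == "inclusive") n_spatio - n_both else n_spatio
  cc <- if (reading == "inclusive") n_genotype - n_both else n_genotype
  d <- n_universe - a - b - cc
  if (min(a, b, cc, d) < 0) stop("counts are inconsistent with the universe")
  matrix(c(a, cc, b, d), 2, 2,
         dimnames = list(spatio = c("yes", "no"),
                         genotype = c("yes", "no")))
}
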