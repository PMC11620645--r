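# Expression-pattern characterization: factor-isolation normalization,
# hierarchical clustering of standardized profiles, and assignment of
# spatiotemporal template classes by maximal Pearson correlation.

#' Isolate one factor's effect by zeroing the other factor's level means
#'
#' For each gene and each level of the factor NOT kept, the gene's mean over
#' the libraries in that level is subtracted, so the returned matrix has per
#' gene an exact zero mean within every level of the removed factor. On a
#' balanced design this removes the nuisance factor's additive effect while
#' preserving contrasts of the kept factor.
#'
#' @param expr expression matrix (genes x libraries).
#' @param design a [sample_design].
#' @param keep `"genotype"` or `"spatio"`: the factor whose effect is kept.
#' @return matrix of the same shape.
#' @export
isolate_factor <- function(expr, design, keep = c("genotype", "spatio")) {
  keep <- match.arg(keep)
  Y <- .align_expr(expr, design)
  removed <- if (keep == "genotype") design$spatio else design$genotype
  for (lev in levels(removed)) {
    j <- which(removed == lev)
    if (length(j))
      Y[, j] <- Y[, j, drop = FALSE] - rowMeans(Y[, j, drop = FALSE])
  }
  Y
}

#' Hierarchical clustering of standardized gene profiles
#'
#' Rows are centered and scaled to mean 0, variance 1, then clustered
#' agglomeratively (default: complete linkage on Euclidean distance) and the
#' tree is cut into `k` clusters.
#'
#' @param expr expression matrix (genes x libraries); no constant rows.
#' @param k number of clusters (<= number of genes).
#' @param linkage_method linkage passed to [stats::hclust] (default
#'   `"complete"`).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param label_order `"input"` labels clusters 1..k by first gene
#'   appearance in row order; `"dendrogram"` by first appearance along the
#'   dendrogram leaf order.
#' @param prefix optional string prepended to cluster labels (e.g. `"I"`).
#' @return list of class `cluster_result`: `gene_ids`, `hclust` (merge
#'   history), `assignments` (named character vector gene -> label),
#'   `standardized` (the matrix actually clustered), `k`.
#' @export
cluster_genes <- function(expr, k, linkage_method = "complete",
                          distance = c("euclidean", "correlation"),
                          label_order = c("input", "dendrogram"),
                          prefix = "") {
  distance <- match.arg(distance)
  label_order <- match.arg(label_order)
  Y <- unclass(expr)
  if (k > nrow(Y))
    stop("k = ", k, " exceeds the number of genes (", nrow(Y), ")")
  sds <- apply(Y, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene profile(s) cannot be standardized: ",
         paste(utils::head(rownames(Y)[sds == 0], 5), collapse = ", "))
  Z <- t(scale(t(Y)))
  d <- if (distance == "euclidean") stats::dist(Z)
       else stats::as.dist(1 - stats::cor(t(Z)))
  hc <- stats::hclust(d, method = linkage_method)
  memb <- stats::cutree(hc, k = k)
  first_seen <- if (label_order == "input") unique(memb) else unique(memb[hc$order])
  relabel <- match(memb, first_seen)
  labels <- stats::setNames(paste0(prefix, relabel), rownames(Y))
  structure(list(gene_ids = rownames(Y), hclust = hc, assignments = labels,
                 standardized = Z, k = k),
            class = "cluster_result")
}

#' The eight spatiotemporal template patterns
#'
#' Encodes the recurring colony expression patterns over the three
#' spatiotemporal levels (day-2, day-5-inside, day-5-outside); 2 = high,
#' 1 = intermediate, 0 = low expression.
#'
#' @return named list C1..C8 of length-3 pattern vectors.
#' @export
default_templates <- function() {
  list(C1 = c(2, 0, 0), C2 = c(0, 2, 2), C3 = c(2, 2, 0), C4 = c(0, 0, 2),
       C5 = c(2, 1, 0), C6 = c(0, 1, 2), C7 = c(0, 2, 0), C8 = c(2, 0, 2))
}

# Expand a per-level template to library length via the design's spatio level.
.expand_template <- function(tpl, design) tpl[as.integer(design$spatio)]

#' Assign each gene's spatiotemporal profile to a template class
#'
#' Each template is expanded to library length (its value for a
#' spatiotemporal level applying to every library of that level) and the
#' gene is assigned to the template with the highest Pearson correlation;
#' ties break to the lowest template index. Profiles should be
#' genotype-isolated (spatio kept), see [isolate_factor].
#'
#' @param profiles expression matrix (genes x libraries).
#' @param design a [sample_design].
#' @param templates a named list of per-level patterns
#'   (default [default_templates]).
#' @return data.frame `gene_id`, `template`, `correlation` with the full
#'   gene x template correlation matrix as attribute `correlations`.
#' @export
template_classify <- function(profiles, design, templates = default_templates()) {
  Y <- .align_expr(profiles, design)
  Tm <- vapply(templates, .expand_template, numeric(nrow(design)), design = design)
  if (any(apply(Tm, 2, stats::sd) == 0))
    stop("template(s) constant after expansion: ",
         paste(names(templates)[apply(Tm, 2, stats::sd) == 0], collapse = ", "))
  sds <- apply(Y, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene profile(s) have undefined correlation: ",
         paste(utils::head(rownames(Y)[sds == 0], 5), collapse = ", "))
  C <- stats::cor(t(Y), Tm)
  best <- max.col(C, ties.method = "first")
  out <- data.frame(gene_id = rownames(Y),
                    template = names(templates)[best],
                    correlation = C[cbind(seq_len(nrow(C)), best)],
                    row.names = NULL)
  attr(out, "correlations") <- C
  out
}

#' Genotype-response clusters G1-G3
#'
#' Spatio-isolated profiles of the genotype-responsive genes are clustered
#' (complete linkage, k = 3) and the clusters are mapped to labels by the
#' direction of their mean standardized profile along the genotype order
#' (smooth to ruffled): G1 = the cluster whose mean increases (most positive
#' correlation with the genotype rank), G2 = decreasing, G3 = the remainder.
#' If the mean profiles do not show one clearly increasing and one clearly
#' decreasing cluster the result is flagged degenerate (attribute
#' `degenerate`) with a warning, and labels fall back to the correlation
#' ranking.
#'
#' @param expr expression matrix covering at least the selected genes.
#' @param design a [sample_design].
#' @param genes character vector of genotype-responsive gene ids.
#' @param k number of clusters (default 3).
#' @return a `cluster_result` with labels G1..Gk; attribute
#'   `genotype_means` holds each cluster's mean standardized profile by
#'   genotype.
#' @export
genotype_clusters <- function(expr, design, genes = rownames(expr), k = 3) {
  if (length(genes) < k)
    stop("need at least ", k, " genes for ", k, " genotype clusters")
  iso <- isolate_factor(unclass(expr)[genes, , drop = FALSE], design,
                        keep = "genotype")
  cr <- cluster_genes(iso, k = k)
  glev <- levels(design$genotype)
  memb <- cr$assignments
  gm <- t(vapply(sort(unique(memb)), function(cl) {
    rows <- cr$standardized[memb == cl, , drop = FALSE]
    vapply(glev, function(l) mean(rows[, design$genotype == l, drop = FALSE]),
           0)
  }, numeric(length(glev))))
  trend <- apply(gm, 1, function(m) stats::cor(m, seq_along(glev)))
  ord <- order(trend, decreasing = TRUE)
  degenerate <- !(trend[ord[1]] > 0 && trend[ord[k]] < 0)
  if (degenerate)
    warning("genotype cluster mean profiles lack a clear increasing and ",
            "decreasing pair; G labels assigned by trend ranking only")
  # most positive trend -> G1, most negative -> G2, remainder G3..Gk in rank order
  glabels <- character(k)
  glabels[ord[1]] <- "G1"
  glabels[ord[k]] <- "G2"
  if (k > 2) glabels[ord[seq(2, k - 1)]] <- paste0("G", seq(3, k))
  new_assign <- stats::setNames(glabels[match(memb, sort(unique(memb)))],
                                names(memb))
  cr$assignments <- new_assign
  rownames(gm) <- glabels
  attr(cr, "genotype_means") <- gm[order(rownames(gm)), , drop = FALSE]
  attr(cr, "degenerate") <- degenerate
  cr
}

#' Interaction-response clusters I1-I9
#'
#' Raw (non-isolated) standardized profiles of the interaction gene set,
#' complete-linkage clustering cut at `k`, labels in dendrogram leaf order.
#'
#' @inheritParams genotype_clusters
#' @param k number of clusters (default 9).
#' @return a `cluster_result` with labels I1..Ik.
#' @export
interaction_clusters <- function(expr, design, genes = rownames(expr), k = 9) {
  Y <- .align_expr(unclass(expr)[genes, , drop = FALSE], design)
  cluster_genes(Y, k = k, label_order = "dendrogram", prefix = "I")
}

#' Clusters of a supplied gene list (e.g. extracellular genes), E1-E5
#'
#' @inheritParams genotype_clusters
#' @param k number of clusters (default 5).
#' @return a `cluster_result` with labels E1..Ek.
#' @export
extracellular_clusters <- function(expr, design, genes, k = 5) {
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < k)
    stop("k = ", k, " exceeds the number of genes (", length(genes), ")")
  Y <- .align_expr(unclass(expr)[genes, , drop = FALSE], design)
  cluster_genes(Y, k = k, label_order = "dendrogram", prefix = "E")
}
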