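# The selection cascade partitioning genes by how their expression responds
# to genotype and colony age/region. Order matters: the variance filter runs
# first, significant interactions are removed before any additive call, and
# only then are factor-responsive genes split by per-term significance.

#' Status levels of the gene partition, in cascade order
#' @return character vector of the seven classification statuses
#' @export
partition_statuses <- function() {
  c("low_variance", "interaction", "set_aside", "additive_both",
    "additive_spatio_only", "additive_genotype_only", "nonsignificant")
}

#' Partition genes by expression response class
#'
#' Cascade: (1) genes whose log2 expression variance across all libraries is
#' below `var_min` are `low_variance`; (2) of the rest, genes with Holm-
#' adjusted interaction p <= `p_cut` are non-additive candidates — those with
#' interaction-model r2 >= `r2_interaction` are `interaction`, the others are
#' `set_aside` (potential non-linear interactions, excluded from the additive
#' analysis); (3) remaining genes with adjusted additive-vs-null p < `p_cut`
#' and additive r2 >= `r2_additive` are factor-responsive, split by adjusted
#' per-term p < `p_cut` into `additive_both`, `additive_spatio_only` or
#' `additive_genotype_only`; (4) everything else is `nonsignificant`.
#'
#' Boundary conventions follow the wording of the selection rules: variance
#' and r2 cutoffs are inclusive minima (>=), the interaction p cutoff is
#' inclusive (<=, "0.01 or less"), all other p cutoffs strict (<).
#'
#' @param fits a `gene_fits` data.frame from [fit_all] (adjusted columns
#'   required).
#' @param var_min minimum log2 expression variance (default 0.2).
#' @param p_cut adjusted p-value cutoff (default 0.01).
#' @param r2_interaction minimum interaction-model r2 (default 0.9).
#' @param r2_additive minimum additive-model r2 (default 0.7).
#' @return data.frame of class `gene_classification` with columns `gene_id`
#'   and `status` (factor over [partition_statuses]), plus empty cluster
#'   label columns `cluster_G`, `cluster_C`, `cluster_I`, `cluster_E` to be
#'   filled by the clustering stage.
#' @export
partition <- function(fits, var_min = 0.2, p_cut = 0.01,
                      r2_interaction = 0.9, r2_additive = 0.7) {
  need <- c("adj_int_p_interaction", "adj_add_p_null", "adj_add_p_genotype",
            "adj_add_p_spatio", "variance", "int_r2", "add_r2")
  miss <- setdiff(need, names(fits))
  if (length(miss))
    stop("fits lack adjusted field(s): ", paste(miss, collapse = ", "))
  status <- rep("nonsignificant", nrow(fits))
  low <- fits$variance < var_min
  status[low] <- "low_variance"
  cand_int <- !low & fits$adj_int_p_interaction <= p_cut
  status[cand_int & fits$int_r2 >= r2_interaction] <- "interaction"
  status[cand_int & fits$int_r2 < r2_interaction] <- "set_aside"
  rest <- !low & !cand_int
  add_ok <- rest & fits$adj_add_p_null < p_cut & fits$add_r2 >= r2_additive
  g_sig <- fits$adj_add_p_genotype < p_cut
  s_sig <- fits$adj_add_p_spatio < p_cut
  status[add_ok & g_sig & s_sig] <- "additive_both"
  status[add_ok & !g_sig & s_sig] <- "additive_spatio_only"
  status[add_ok & g_sig & !s_sig] <- "additive_genotype_only"
  structure(data.frame(gene_id = fits$gene_id,
                       status = factor(status, levels = partition_statuses()),
                       cluster_G = NA_character_, cluster_C = NA_character_,
                       cluster_I = NA_character_, cluster_E = NA_character_,
                       row.names = NULL),
            class = c("gene_classification", "data.frame"))
}

#' Sensitivity and false-positive rate of the partition against known truth
#'
#' Convenience for simulation studies: compares assigned statuses with the
#' generator's truth classes. A truth class counts as recovered when the
#' assigned status is the matching one (`interaction` for interaction genes,
#' the corresponding `additive_*` status for additive genes).
#'
#' @param classification a `gene_classification`.
#' @param truth the generator truth table (columns `gene_id`, `class`).
#' @return data.frame with one row per truth class: `class`, `n`,
#'   `sensitivity` (effect classes) or `false_positive_rate` (null class,
#'   fraction assigned any significant status).
#' @export
partition_recovery <- function(classification, truth) {
  status <- classification$status[match(truth$gene_id, classification$gene_id)]
  expect <- c(genotype_additive = "additive_genotype_only",
              spatio_additive = "additive_spatio_only",
              both_additive = "additive_both",
              interaction = "interaction")
  sig <- !status %in% c("low_variance", "nonsignificant")
  do.call(rbind, lapply(split(seq_len(nrow(truth)), truth$class), function(idx) {
    cls <- truth$class[idx[1]]
    if (cls == "null") {
      data.frame(class = cls, n = length(idx),
                 sensitivity = NA_real_,
                 false_positive_rate = mean(sig[idx]))
    } else {
      data.frame(class = cls, n = length(idx),
                 sensitivity = mean(status[idx] == expect[[cls]]),
                 false_positive_rate = NA_real_)
    }
  }))
}
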