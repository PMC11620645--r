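# Orchestration of the full analysis: normalization -> per-gene ANOVA ->
# optional permutation FDR -> partition -> clustering (G/C/I/E) ->
# cluster-overlap statistics, with every intermediate table written as CSV
# and a run log recording versions, seed and a configuration hash.

#' Pipeline configuration
#'
#' Defaults are the study's analysis constants: variance filter 0.2,
#' adjusted-p cutoff 0.01, interaction r2 0.9, additive r2 0.7, prior count
#' 20, 100 permutations, cluster cuts k = 3 (genotype), 9 (interaction),
#' 5 (extracellular), complete linkage on Euclidean distance, gene universe
#' prefix "Y".
#'
#' @param counts_path,design_path input files (NULL when matrices are passed
#'   to [run_pipeline] directly).
#' @param dialect count-file dialect for [read_counts].
#' @param count_columns optional library column selection for [read_counts].
#' @param out_dir output directory for CSV artifacts and the run log.
#' @param gene_prefix gene-universe prefix (default "Y").
#' @param var_min,p_cut,r2_interaction,r2_additive,prior_count analysis
#'   thresholds (see [partition], [log_cpm]).
#' @param do_permutation run the permutation FDR stage (default FALSE; it
#'   dominates run time).
#' @param n_perm permutations for that stage (default 100).
#' @param k_genotype,k_interaction,k_extracellular cluster cuts.
#' @param linkage,distance clustering parameters (see [cluster_genes]).
#' @param extracellular_genes optional gene-id vector for the E clusters.
#' @param seed integer seed used for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, design_path = NULL,
                            dialect = "csv_matrix", count_columns = NULL,
                            out_dir = "results/pipeline", gene_prefix = "Y",
                            var_min = 0.2, p_cut = 0.01,
                            r2_interaction = 0.9, r2_additive = 0.7,
                            prior_count = 20, do_permutation = FALSE,
                            n_perm = 100, k_genotype = 3, k_interaction = 9,
                            k_extracellular = 5, linkage = "complete",
                            distance = "euclidean",
                            extracellular_genes = NULL, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(var_min >= 0, p_cut > 0, p_cut < 1,
            r2_interaction >= 0, r2_interaction <= 1,
            r2_additive >= 0, r2_additive <= 1,
            prior_count > 0, n_perm >= 1,
            k_genotype >= 1, k_interaction >= 1, k_extracellular >= 1)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config]; unknown keys are an
#' error, missing keys take the defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#' @param cfg a `pipeline_config`.
#' @param path output file.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Hash of the analysis-relevant configuration
#'
#' MD5 over the threshold, clustering and seed fields (not file paths), so
#' the hash changes exactly when an analysis constant changes.
#'
#' @param cfg a `pipeline_config`.
#' @return character MD5 hash.
#' @export
config_hash <- function(cfg) {
  keep <- c("gene_prefix", "var_min", "p_cut", "r2_interaction",
            "r2_additive", "prior_count", "do_permutation", "n_perm",
            "k_genotype", "k_interaction", "k_extracellular", "linkage",
            "distance", "seed")
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg[keep], tf)
  unname(tools::md5sum(tf))
}

#' Run the full classification pipeline
#'
#' Stages: TMM normalization on the full count table, gene-universe filter,
#' prior-damped log-CPM, per-gene additive and interaction ANOVA with Holm
#' adjustment, optional permutation FDR, the partition cascade, genotype
#' clusters (G), spatiotemporal template classes (C), interaction clusters
#' (I), optional extracellular clusters (E), the C x G cross-tabulation of
#' the both-responsive genes with an exact r x c Fisher test, and the 2x2
#' responder-overlap Fisher tests against both the full and the
#' variance-filtered gene universes.
#'
#' @param cfg a `pipeline_config` (or path to its YAML file).
#' @param counts optional in-memory [count_matrix] (otherwise read from
#'   `cfg$counts_path`).
#' @param design optional in-memory [sample_design].
#' @return (invisibly) list with every intermediate object; CSV artifacts
#'   and `run_log.txt` under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg, counts = NULL, design = NULL) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- "input"
  res <- tryCatch({
    cm <- counts %||% read_counts(cfg$counts_path, dialect = cfg$dialect,
                                  count_columns = cfg$count_columns)
    des <- design %||% read_design(cfg$design_path)
    cm <- join_counts_design(cm, des)

    stage <- "normalize"
    nf <- tmm_factors(cm)                      # on the full table
    cm_f <- filter_gene_universe(cm, cfg$gene_prefix)
    expr <- log_cpm(cm_f, nf, prior_count = cfg$prior_count)

    stage <- "fit"
    fits <- fit_all(expr, des)

    stage <- "permutation"
    perm <- if (isTRUE(cfg$do_permutation))
      permute_and_count(expr, des, cutoff = cfg$p_cut, n_perm = cfg$n_perm,
                        seed = cfg$seed)
    else NULL

    stage <- "partition"
    cls <- partition(fits, var_min = cfg$var_min, p_cut = cfg$p_cut,
                     r2_interaction = cfg$r2_interaction,
                     r2_additive = cfg$r2_additive)

    stage <- "clustering"
    sp_resp <- cls$gene_id[cls$status %in% c("additive_spatio_only",
                                             "additive_both")]
    g_resp <- cls$gene_id[cls$status %in% c("additive_genotype_only",
                                            "additive_both")]
    int_set <- cls$gene_id[cls$status == "interaction"]
    gcl <- ccl <- icl <- ecl <- NULL
    if (length(g_resp) >= cfg$k_genotype) {
      gcl <- genotype_clusters(expr, des, genes = g_resp, k = cfg$k_genotype)
      cls$cluster_G[match(g_resp, cls$gene_id)] <- gcl$assignments[g_resp]
    }
    if (length(sp_resp) >= 1) {
      iso <- isolate_factor(unclass(expr)[sp_resp, , drop = FALSE], des,
                            keep = "spatio")
      ccl <- template_classify(iso, des)
      cls$cluster_C[match(sp_resp, cls$gene_id)] <- ccl$template
    }
    if (length(int_set) >= cfg$k_interaction) {
      icl <- interaction_clusters(expr, des, genes = int_set,
                                  k = cfg$k_interaction)
      cls$cluster_I[match(int_set, cls$gene_id)] <- icl$assignments[int_set]
    }
    if (!is.null(cfg$extracellular_genes)) {
      ecl <- extracellular_clusters(expr, des, genes = cfg$extracellular_genes,
                                    k = cfg$k_extracellular)
      egenes <- names(ecl$assignments)
      cls$cluster_E[match(egenes, cls$gene_id)] <- ecl$assignments
    }

    stage <- "overlap"
    both <- cls$status == "additive_both"
    ct <- fisher_cg <- NULL
    if (sum(both) >= 1 && !is.null(gcl) && !is.null(ccl)) {
      a <- stats::setNames(cls$cluster_C, cls$gene_id)[both]
      b <- stats::setNames(cls$cluster_G, cls$gene_id)[both]
      ct <- crosstab(a, b)
      fisher_cg <- fisher_rxc(ct, seed = cfg$seed)
    }
    universe_all <- nrow(fits)
    universe_var <- sum(fits$variance >= cfg$var_min)
    overlap2 <- lapply(c(all_genes = universe_all,
                         variance_filtered = universe_var), function(N) {
      tab <- both_factor_table(length(sp_resp), length(g_resp), sum(both), N)
      list(table = tab,
           one_tailed = fisher_2x2(tab, "one_greater"),
           two_sided = fisher_2x2(tab, "two_sided"))
    })
    list(config = cfg, counts = cm, design = des, norm_factors = nf,
         expr = expr, fits = fits, permutation = perm,
         classification = cls, genotype_clusters = gcl,
         template_classes = ccl, interaction_clusters = icl,
         extracellular_clusters = ecl, crosstab_CG = ct,
         fisher_CG = fisher_cg, overlap_2x2 = overlap2)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  .write_pipeline_outputs(res)
  invisible(res)
}

.write_pipeline_outputs <- function(res) {
  cfg <- res$config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  utils::write.csv(res$norm_factors, out("normalization.csv"), row.names = FALSE)
  utils::write.csv(res$fits, out("gene_fits.csv"), row.names = FALSE)
  utils::write.csv(res$classification, out("classification.csv"),
                   row.names = FALSE)
  if (!is.null(res$permutation))
    utils::write.csv(res$permutation, out("permutation_fdr.csv"),
                     row.names = FALSE)
  if (!is.null(res$crosstab_CG)) {
    m <- as.data.frame.matrix(res$crosstab_CG)
    utils::write.csv(cbind(cluster = rownames(m), m),
                     out("contingency_CxG.csv"), row.names = FALSE)
    ft <- res$fisher_CG
    utils::write.csv(data.frame(test = "CxG_independence", p = ft$p_value,
                                method = ft$method, se = ft$se,
                                seed = ft$seed),
                     out("fisher_CxG.csv"), row.names = FALSE)
  }
  ov <- do.call(rbind, lapply(names(res$overlap_2x2), function(nm) {
    o <- res$overlap_2x2[[nm]]
    data.frame(universe = nm, n_universe = sum(o$table),
               n_both = o$table[1, 1],
               one_tailed_p = o$one_tailed$p_value,
               two_sided_p = o$two_sided$p_value,
               odds_ratio = o$one_tailed$odds_ratio)
  }))
  utils::write.csv(ov, out("overlap_2x2.csv"), row.names = FALSE)
  writeLines(c(sprintf("colonyexpr %s on R %s.%s",
                       as.character(utils::packageVersion("colonyexpr")),
                       R.version$major, R.version$minor),
               sprintf("seed: %d", cfg$seed),
               sprintf("config hash: %s", config_hash(cfg)),
               sprintf("libraries: %d, genes analyzed: %d",
                       nrow(res$design), nrow(res$fits))),
             out("run_log.txt"))
  invisible(NULL)
}
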