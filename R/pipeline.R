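#' Pipeline run configuration
#'
#' Aggregates every analysis setting. Defaults reproduce the reference
#' protocol: sparsity grid 0.05-0.4 in steps of 0.01, 10,000 permutations
#' for global/nodal AUC comparisons, 5,000 permutations for the NBS with
#' primary t threshold 3.2, and BH-FDR at q = 0.05.
#'
#' @param cohort_path,clinical_path input TSVs (ignored when `cohort` is
#'   given).
#' @param cohort optional in-memory `morph_cohort` (takes precedence).
#' @param out_dir output directory.
#' @param measure `"KLDs"` or `"JSDs"`.
#' @param grid sparsity grid.
#' @param pdf_grid PDF discretization spec.
#' @param n_null rewired nulls per threshold for gamma/lambda/sigma.
#' @param n_perm_global permutations for AUC group tests.
#' @param n_perm_nbs permutations for the NBS.
#' @param primary_t NBS primary threshold.
#' @param q_fdr FDR level for nodal metric discovery.
#' @param seed root seed; all stage seeds derive from it.
#' @return `run_config` list.
#' @export
run_config <- function(cohort_path = NULL, clinical_path = NULL,
                       cohort = NULL, out_dir = tempfile("morphnet_run_"),
                       measure = c("KLDs", "JSDs"),
                       grid = sparsity_grid(), pdf_grid = pdf_grid_spec(),
                       n_null = 100L, n_perm_global = 10000L,
                       n_perm_nbs = 5000L, primary_t = 3.2, q_fdr = 0.05,
                       seed = 1L) {
  measure <- match.arg(measure)
  stopifnot(n_null >= 0, n_perm_global >= 100, n_perm_nbs >= 100,
            primary_t > 0, q_fdr > 0, q_fdr < 1)
  structure(list(cohort_path = cohort_path, clinical_path = clinical_path,
                 cohort = cohort, out_dir = out_dir, measure = measure,
                 grid = grid, pdf_grid = pdf_grid, n_null = n_null,
                 n_perm_global = as.integer(n_perm_global),
                 n_perm_nbs = as.integer(n_perm_nbs),
                 primary_t = primary_t, q_fdr = q_fdr,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full individual morphological network analysis
#'
#' Orchestrates, in order: cohort loading, per-subject similarity-network
#' construction, metric curves and AUC summarization over the sparsity
#' grid, permutation tests of global and nodal AUC metrics with BH-FDR
#' over nodal metric families, node selection (FDR-significant in any
#' nodal metric) feeding two one-sided NBS runs, partial-correlation
#' clinical association for the significant region/metric pairs, and a
#' JSON run manifest. Fully deterministic for a fixed seed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- stage 1: inputs ------------------------------------------------
  if (!is.null(config$cohort)) {
    subjects <- config$cohort$subjects
    clinical <- config$cohort$clinical
  } else {
    if (is.null(config$cohort_path) || is.null(config$clinical_path)) {
      stop("stage input: provide `cohort` or both cohort_path/clinical_path",
           call. = FALSE)
    }
    subjects <- read_cohort_table(config$cohort_path)
    clinical <- read_clinical_table(config$clinical_path)
    for (s in names(subjects)) {
      subjects[[s]]$group <-
        clinical$group[match(s, clinical$subject_id)]
    }
  }
  groups <- vapply(subjects, `[[`, character(1), "group")
  is_pat <- groups == "patient"

  # -- stage 2: similarity networks -----------------------------------
  nets <- tryCatch(
    build_cohort_networks(subjects, measure = config$measure,
                          grid = config$pdf_grid),
    error = function(e) stop("stage similarity_network: ",
                             conditionMessage(e), call. = FALSE))
  mat_dir <- file.path(config$out_dir, "similarity")
  dir.create(mat_dir, showWarnings = FALSE)
  for (s in names(nets)) {
    write_similarity_matrix(nets[[s]], file.path(mat_dir,
                                                 paste0(s, ".tsv")))
  }

  # -- stage 3: metric curves and AUCs --------------------------------
  grid <- config$grid
  curve_seed <- derive_seed(config$seed, 1L)
  auc_global <- list(); auc_nodal <- list(); curves_all <- list()
  for (k in seq_along(nets)) {
    sid <- names(nets)[k]
    cv <- suppressMessages(
      metric_curves(nets[[k]], grid = grid, n_null = config$n_null,
                    seed = derive_seed(curve_seed, k)))
    sa <- summarize_auc(cv, grid)
    sa$global$subject_id <- sid; sa$nodal$subject_id <- sid
    auc_global[[sid]] <- sa$global
    auc_nodal[[sid]] <- sa$nodal
    cv$global$subject_id <- sid
    curves_all[[sid]] <- cv$global
  }
  auc_global <- do.call(rbind, auc_global)
  auc_nodal <- do.call(rbind, auc_nodal)
  write_tsv(do.call(rbind, curves_all),
            file.path(config$out_dir, "global_metric_curves.tsv"))
  write_tsv(auc_global, file.path(config$out_dir, "auc_global.tsv"))
  write_tsv(auc_nodal, file.path(config$out_dir, "auc_nodal.tsv"))

  # -- stage 4: group comparison of AUCs ------------------------------
  perm_seed <- derive_seed(config$seed, 2L)
  global_metrics <- unique(auc_global$metric)
  gm_mat <- sapply(global_metrics, function(m) {
    v <- auc_global$auc[auc_global$metric == m]
    names(v) <- auc_global$subject_id[auc_global$metric == m]
    v[names(subjects)]
  })
  keep_gm <- colSums(!is.finite(gm_mat)) == 0
  global_test <- permutation_test_auc(
    gm_mat[is_pat, keep_gm, drop = FALSE],
    gm_mat[!is_pat, keep_gm, drop = FALSE],
    n_perm = config$n_perm_global, seed = perm_seed)
  global_res <- data.frame(metric = colnames(gm_mat)[keep_gm],
                           observed_diff = global_test$observed,
                           p_value = global_test$p_value,
                           crit95 = global_test$crit95,
                           row.names = NULL)
  write_tsv(global_res, file.path(config$out_dir, "global_auc_tests.tsv"))

  nodal_metrics <- unique(auc_nodal$metric)
  regions <- unique(auc_nodal$region)
  nodal_res <- list()
  for (m in nodal_metrics) {
    sub <- auc_nodal[auc_nodal$metric == m, ]
    M <- sapply(regions, function(r) {
      v <- sub$auc[sub$region == r]
      names(v) <- sub$subject_id[sub$region == r]
      v[names(subjects)]
    })
    tst <- permutation_test_auc(M[is_pat, , drop = FALSE],
                                M[!is_pat, , drop = FALSE],
                                n_perm = config$n_perm_global,
                                seed = derive_seed(perm_seed, match(m, nodal_metrics)))
    fdr <- bh_fdr(tst$p_value, q = config$q_fdr)
    nodal_res[[m]] <- data.frame(metric = m, region = regions,
                                 observed_diff = tst$observed,
                                 p_value = tst$p_value,
                                 p_adjusted = fdr$adjusted,
                                 significant = fdr$significant,
                                 row.names = NULL)
  }
  nodal_res <- do.call(rbind, nodal_res)
  write_tsv(nodal_res, file.path(config$out_dir, "nodal_auc_tests.tsv"))

  # -- stage 5: NBS ---------------------------------------------------
  sig_nodes <- unique(nodal_res$region[nodal_res$significant])
  nbs_seed <- derive_seed(config$seed, 3L)
  nbs_res <- list()
  if (length(sig_nodes) >= 2) {
    labels <- factor(groups, levels = c("patient", "control"))
    for (dir in c("greater", "less")) {
      nbs_res[[dir]] <- nbs(nets, labels, node_mask = sig_nodes,
                            primary_t = config$primary_t,
                            n_perm = config$n_perm_nbs, direction = dir,
                            seed = derive_seed(nbs_seed,
                                               if (dir == "greater") 1L else 2L))
    }
    nbs_json <- lapply(nbs_res, function(r) {
      list(direction = r$direction, primary_t = r$primary_t,
           n_perm = r$n_perm,
           components = lapply(r$components, function(c) {
             list(nodes = c$nodes, n_edges = c$n_edges,
                  corrected_p = c$corrected_p,
                  edges = c$edges)
           }))
    })
    jsonlite::write_json(nbs_json, file.path(config$out_dir, "nbs.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  # -- stage 6: clinical association ----------------------------------
  assoc <- NULL
  sig_pairs <- nodal_res[nodal_res$significant, c("region", "metric")]
  clin_vars <- intersect(c("duration", "hfmse"), names(clinical))
  if (nrow(sig_pairs) && length(clin_vars) &&
      sum(clinical$group == "patient") > 4) {
    targets <- merge(sig_pairs, data.frame(variable = clin_vars))
    # a target can be degenerate (constant AUC across patients); keep the
    # remaining targets rather than aborting the stage
    rows <- lapply(seq_len(nrow(targets)), function(i) {
      tryCatch(associate_metrics(auc_nodal, clinical,
                                 targets[i, , drop = FALSE]),
               error = function(e) NULL)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      assoc <- do.call(rbind, rows)
      attr(assoc, "correction") <- "uncorrected"
      write_tsv(assoc, file.path(config$out_dir, "clinical_association.tsv"))
    }
  }

  demo <- compare_demographics(clinical)
  write_tsv(demo, file.path(config$out_dir, "demographics.tsv"))

  manifest <- list(
    measure = config$measure,
    sparsity_grid = list(start = min(grid), stop = max(grid),
                         n_thresholds = length(grid)),
    pdf_grid = config$pdf_grid[c("n_points", "padding", "epsilon")],
    n_null = config$n_null, n_perm_global = config$n_perm_global,
    n_perm_nbs = config$n_perm_nbs, primary_t = config$primary_t,
    q_fdr = config$q_fdr, seed = config$seed,
    n_subjects = length(subjects),
    significant_nodes = sig_nodes,
    conventions = list(
      path_length = "Lp = 1/Eg (harmonic-mean convention)",
      edge_count = "floor(S * N(N-1)/2), ties by ascending pair order",
      p_values = "raw permutation proportions, no smoothing",
      fdr_family = "within each nodal metric across regions"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(out_dir = config$out_dir, networks = nets,
                 auc_global = auc_global, auc_nodal = auc_nodal,
                 global_tests = global_res, nodal_tests = nodal_res,
                 significant_nodes = sig_nodes, nbs = nbs_res,
                 association = assoc, demographics = demo))
}
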