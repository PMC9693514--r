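#' Build a pipeline run configuration
#'
#' Inputs may be file paths (trait CSV, newick tree, records CSV) or
#' in-memory objects (`trait_tbl`, `phylo`, tibble). Tree and records are
#' optional; their stages degrade gracefully.
#'
#' @param traits Trait table or CSV path (required).
#' @param tree Phylogeny, newick path, or `NULL`.
#' @param records Occurrence records, CSV path, or `NULL`.
#' @param registry Trait registry tibble.
#' @param transform_spec Transformation table or `NULL` for defaults.
#' @param thresholds Rule thresholds.
#' @param k Number of clusters to cut, default 5.
#' @param alpha Significance level, default 0.05.
#' @param min_traits Sparse-species floor, default 5.
#' @param min_frac Coverage-filter fraction, default 0.70.
#' @param seed Integer seed (reserved for stochastic stages).
#' @param out_dir Output directory or `NULL` for no artifacts.
#' @return A `run_config` list (validated on use).
#' @export
run_config <- function(traits, tree = NULL, records = NULL,
                       registry = default_registry(), transform_spec = NULL,
                       thresholds = default_thresholds(), k = 5, alpha = 0.05,
                       min_traits = 5, min_frac = 0.70, seed = 1,
                       out_dir = NULL) {
  if (k < 2) rlang::abort("run_config: k must be >= 2")
  if (alpha <= 0 || alpha >= 1) rlang::abort("run_config: alpha must be in (0,1)")
  structure(list(traits = traits, tree = tree, records = records,
                 registry = registry, transform_spec = transform_spec,
                 thresholds = thresholds, k = k, alpha = alpha,
                 min_traits = min_traits, min_frac = min_frac, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `traits`, `tree`, `records` (paths), `k`, `alpha`,
#' `min_traits`, `min_frac`, `seed`, `out_dir`, and a `thresholds` mapping.
#' Referenced files must exist.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("traits", "tree", "records")) {
    if (!is.null(y[[f]]) && !file.exists(y[[f]])) {
      rlang::abort(paste0("run config references missing file: ", y[[f]]))
    }
  }
  thr <- utils::modifyList(default_thresholds(), y$thresholds %||% list())
  run_config(traits = y$traits, tree = y$tree, records = y$records,
             thresholds = thr, k = y$k %||% 5, alpha = y$alpha %||% 0.05,
             min_traits = y$min_traits %||% 5, min_frac = y$min_frac %||% 0.70,
             seed = y$seed %||% 1, out_dir = y$out_dir)
}

resolve_input <- function(x, reader) {
  if (is.null(x)) NULL
  else if (is.character(x) && length(x) == 1) reader(x)
  else x
}

stage_log <- function(stages, name, n_in, n_out, note = "") {
  rlang::inform(sprintf("[%s] %d -> %d %s", name, n_in, n_out, note))
  dplyr::bind_rows(stages, tibble::tibble(stage = name, n_in = n_in,
                                          n_out = n_out, note = note))
}

#' Run the end-to-end functional-group pipeline
#'
#' Stages, in fixed order: ingest, derived-trait fill, sparse-species drop,
#' clustering-trait restriction, coverage filter, gap-fill (phylogenetic
#' Brownian-motion imputation when a tree is available, genus means
#' otherwise), transformation to the 0-1 scale, two-way Ward clustering and
#' k-group cut, reconciliation of clusters with the rule engine,
#' discriminant validation with the squared-Mahalanobis separation matrix,
#' rule classification of every ingested species, group composition, trait
#' and (when records are available) environmental comparisons with
#' ecological-zone presence. Every stage logs its input/output sizes;
#' species left with empty cells after gap-filling are dropped from the
#' clustering set with a warning.
#'
#' @param cfg A [run_config()].
#' @return A `pipeline_result` list: `stages` (size accounting), `table`
#'   (derived full table), `cluster_table`, `matrix`, `two_way`,
#'   `cluster_map`, `labels`, `changes`, `da`, `mahalanobis`,
#'   `rule_labels`, `composition`, `correlations`, `trait_tests`,
#'   `env_tests`, `ecozone_richness`, `impute_report`, `summary` (the
#'   machine-readable summary written as JSON when `out_dir` is set).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) rlang::abort("cfg must be a run_config")
  tt <- resolve_input(cfg$traits, function(p) read_trait_table(p, cfg$registry))
  if (is.null(tt)) rlang::abort("pipeline aborted at validation: no trait input")
  tree <- resolve_input(cfg$tree, read_newick)
  records <- resolve_input(cfg$records, read_env_records)
  stages <- tibble::tibble(stage = character(), n_in = integer(),
                           n_out = integer(), note = character())

  n0 <- nrow(tt)
  tt <- fill_derived_traits(tt)
  stages <- stage_log(stages, "derive", n0, nrow(tt), "derived traits filled")

  tt2 <- drop_sparse_species(tt, min_traits = cfg$min_traits)
  stages <- stage_log(stages, "sparse_filter", nrow(tt), nrow(tt2),
                      sprintf("species with < %d traits removed", cfg$min_traits))

  ct <- select_traits(tt2, clustering_traits(cfg$registry))
  ct <- coverage_filter(ct, min_frac = cfg$min_frac)
  stages <- stage_log(stages, "coverage_filter", nrow(tt2), nrow(ct),
                      sprintf("%d clustering traits retained", length(trait_cols(ct))))

  if (is.null(tree)) {
    rlang::warn("no tree supplied; imputation falls through to genus means")
  }
  imp <- if (is.null(tree)) impute_traits(ct, NULL, min_frac = cfg$min_frac)
         else impute_traits(ct, tree, min_frac = cfg$min_frac)
  ct <- imp$table
  cont <- continuous_traits(ct)
  left <- rowSums(is.na(as.data.frame(ct[trait_cols(ct)]))) > 0
  if (any(left)) {
    rlang::warn(paste0("dropping species with unfillable cells: ",
                       paste(ct$species[left], collapse = ", ")))
    ct <- rebuild_trait_tbl(ct[!left, ], ct, provenance_of(ct)[!left, ])
  }
  stages <- stage_log(stages, "impute", nrow(imp$table), nrow(ct),
                      sprintf("%d phylo, %d genus-mean, %d rejected",
                              imp$report$n_imputed_phylo,
                              imp$report$n_imputed_genus,
                              imp$report$n_rejected))

  mat <- transform_traits(ct, cfg$transform_spec)
  tw <- two_way_cluster(mat)
  cluster_map <- cut_tree(tw$species_tree, cfg$k)
  rec <- reconcile_with_clusters(cluster_map, ct, cfg$thresholds)
  stages <- stage_log(stages, "cluster", nrow(ct), nrow(cluster_map),
                      sprintf("k = %d, %d reconciliation moves", cfg$k,
                              nrow(rec$changes)))

  da <- NULL; maha <- NULL
  lab_counts <- table(rec$labels$label)
  if (length(lab_counts) >= 2 && all(lab_counts >= 2)) {
    da <- fit_discriminant(mat, rec$labels$label)
    maha <- mahalanobis_matrix(da)
  } else {
    rlang::warn("discriminant stage skipped: a group has < 2 members")
  }

  rule_labels <- classify_species(tt, cfg$thresholds)
  composition <- group_composition(rule_labels)
  stages <- stage_log(stages, "classify", nrow(tt),
                      sum(!is.na(rule_labels$label)), "rule labels assigned")

  correlations <- spearman_matrix(tt, alpha = cfg$alpha)
  trait_tests <- list()
  lab_for_stats <- stats::setNames(rule_labels$label, rule_labels$species)
  for (tr in cont) {
    vals <- tt2[[tr]]
    grp <- lab_for_stats[tt2$species]
    usable <- names(which(table(grp[!is.na(vals)]) >= 2))
    if (length(usable) < 2) next
    trait_tests[[tr]] <- if (tr == "LWA") {
      anova_tukey(vals, grp, alpha = cfg$alpha, variable = tr)
    } else {
      kw_posthoc(vals, grp, alpha = cfg$alpha, variable = tr)
    }
  }

  env_tests <- NULL; richness <- NULL
  if (!is.null(records)) {
    lbl <- rule_labels[!is.na(rule_labels$label), c("species", "label")]
    env_tests <- env_group_compare(records, lbl, alpha = cfg$alpha)
    richness <- ecozone_presence(records[records$species %in% lbl$species, ], lbl)
  } else {
    rlang::inform("no records supplied; environmental stages skipped")
  }

  summary <- list(
    n_species_in = n0,
    n_species_clustered = nrow(ct),
    n_traits_clustered = length(trait_cols(ct)),
    stages = as.data.frame(stages),
    impute = imp$report[c("n_missing_before", "n_imputed_phylo", "n_rejected",
                          "n_imputed_genus", "n_left_empty")],
    k = cfg$k,
    group_sizes = as.list(table(rec$labels$label)),
    reconciliation_moves = nrow(rec$changes),
    mahalanobis = if (!is.null(maha)) as.data.frame(maha) else NULL,
    composition = as.data.frame(composition),
    letters = lapply(trait_tests, function(x) {
      stats::setNames(as.list(x$summary$letters), x$summary$group)
    }),
    env_letters = if (!is.null(env_tests)) {
      lapply(env_tests, function(x) {
        stats::setNames(as.list(x$summary$letters), x$summary$group)
      })
    } else NULL
  )

  res <- structure(
    list(stages = stages, table = tt, cluster_table = ct, matrix = mat,
         two_way = tw, cluster_map = cluster_map, labels = rec$labels,
         changes = rec$changes, da = da, mahalanobis = maha,
         rule_labels = rule_labels, composition = composition,
         correlations = correlations, trait_tests = trait_tests,
         env_tests = env_tests, ecozone_richness = richness,
         impute_report = imp$report, summary = summary, config = cfg),
    class = "pipeline_result"
  )
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(res, cfg$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Functional-group pipeline result\n")
  print(x$stages)
  cat("\nGroup composition (rule engine):\n")
  print(x$composition)
  if (!is.null(x$mahalanobis)) {
    cat("\nSquared Mahalanobis separations:\n")
    print(round(x$mahalanobis, 1))
  }
  invisible(x)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_trait_table(res$table, p("traits_derived.csv"))
  write_transformed(res$matrix, p("traits_transformed.csv"))
  write_linkage(res$two_way$species_tree, p("species_linkage.csv"),
                p("species_linkage.nwk"))
  if (!is.null(res$two_way$trait_tree)) {
    write_linkage(res$two_way$trait_tree, p("trait_linkage.csv"),
                  p("trait_linkage.nwk"))
  }
  readr::write_csv(res$cluster_map, p("clusters.csv"))
  readr::write_csv(res$labels, p("labels.csv"))
  readr::write_csv(res$rule_labels, p("rule_labels.csv"))
  readr::write_csv(res$composition, p("composition.csv"))
  readr::write_csv(tidy(res$correlations), p("correlations.csv"))
  if (!is.null(res$mahalanobis)) {
    readr::write_csv(tibble::as_tibble(res$mahalanobis, rownames = "group"),
                     p("mahalanobis.csv"))
  }
  if (!is.null(res$ecozone_richness)) {
    readr::write_csv(tibble::as_tibble(res$ecozone_richness, rownames = "group"),
                     p("ecozone_richness.csv"))
  }
  write_impute_report(res$impute_report, p("impute_cells.csv"),
                      p("impute_summary.json"))
  jsonlite::write_json(res$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
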