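#' Merge a chip SNP panel with a selected SNP set
#'
#' Returns the duplicate-free union together with the overlap count, and —
#' for the two-relationship-matrix model — the chip panel with overlapping
#' SNPs removed (the selected set keeps them, as the selected markers carry
#' the feature signal). The identity
#' `|union| = |chip| + |selected| - |overlap|` always holds.
#'
#' @param chip_set Character vector of chip SNP ids.
#' @param selected_set Character vector of selected SNP ids.
#' @return List: `union`, `chip_minus_overlap`, `selected`, `n_overlap`,
#'   `n_union`.
#' @export
#' @examples
#' merge_snp_sets(c("a", "b"), c("b", "c"))
merge_snp_sets <- function(chip_set, selected_set) {
  chip <- unique(as.character(chip_set))
  sel <- unique(as.character(selected_set))
  overlap <- intersect(chip, sel)
  u <- union(chip, sel)
  if (!length(u)) stop_gsfs("union of SNP sets is empty", class = "gsfs_empty_result")
  list(union = u,
       chip_minus_overlap = setdiff(chip, overlap),
       selected = sel,
       n_overlap = length(overlap),
       n_union = length(u))
}

#' Draw a fixed pseudo-chip panel from simulated markers
#'
#' Synthetic populations have no array manifest; the "50K chip" is emulated
#' as a fixed, seeded random subsample of the simulated SNPs, preserving
#' map order, so chip and whole-sequence panels nest the way real data do.
#'
#' @param geno A `geno_matrix`.
#' @param size Panel size.
#' @param seed Seed for the subsample.
#' @return Character vector of SNP ids in map order.
#' @export
make_chip_panel <- function(geno, size, seed = 1L) {
  stopifnot(inherits(geno, "geno_matrix"))
  m <- ncol(geno$codes)
  size <- as.integer(size)
  if (size < 1L || size > m) stop_gsfs("chip panel size out of range")
  withr::with_seed(as.integer(seed), {
    colnames(geno$codes)[sort(sample.int(m, size))]
  })
}

# genotype matrix restricted to a set of individuals
.subset_individuals <- function(geno, ids) {
  idx <- match(ids, rownames(geno$codes))
  if (anyNA(idx)) stop_gsfs("unknown individual id(s)")
  geno_matrix(geno$codes[idx, , drop = FALSE], geno$map)
}

#' Fit and evaluate GBLUP on explicit SNP sets
#'
#' The workhorse behind every scenario: builds one VanRaden-1 relationship
#' matrix per supplied SNP set over all individuals, fits reliability-
#' weighted AI-REML GBLUP on the reference population, projects GEBVs onto
#' the validation population and computes accuracy and dispersion bias.
#' Useful directly for comparator sets (e.g. a random panel matched in
#' size to a selected set).
#'
#' @param geno A `geno_matrix` (already quality-controlled).
#' @param pheno Phenotype tibble (`id`, `drp`, `reliability`, `birth_year`).
#' @param snp_sets Named list of SNP-id vectors; one element gives the
#'   single-matrix model, two give the two-matrix model.
#' @param label Scenario label recorded in the report.
#' @param split Optional precomputed [partition_population()] result.
#' @param cutoff_year,min_reliability Split parameters when `split` is NULL.
#' @param max_iter AI-REML iteration cap.
#' @param force_accuracy Report accuracy even when REML did not converge
#'   (default FALSE: unconverged fits report `NA` accuracy/bias, mirroring
#'   practice of excluding unconverged models from comparison).
#' @return List: `fit` (`gblup_fit`), `prediction` (validation GEBVs),
#'   `report` (one-row tibble: label, SNP counts, accuracy, bias,
#'   convergence, variance components).
#' @export
evaluate_snp_set <- function(geno, pheno, snp_sets, label = "custom",
                             split = NULL, cutoff_year = 2013L,
                             min_reliability = 0.40, max_iter = 1000L,
                             force_accuracy = FALSE) {
  stopifnot(inherits(geno, "geno_matrix"), is.data.frame(pheno))
  if (!is.list(snp_sets)) snp_sets <- list(set = snp_sets)
  if (is.null(names(snp_sets))) names(snp_sets) <- sprintf("g%d", seq_along(snp_sets))
  pheno <- dplyr::filter(pheno, .data$id %in% rownames(geno$codes))
  split <- split %||% partition_population(pheno, cutoff_year, min_reliability)

  grms <- lapply(snp_sets, function(s) grm_vanraden1(geno, s))
  ref <- split$reference
  ref_ph <- pheno[match(ref, pheno$id), ]
  y <- setNames(ref_ph$drp, ref_ph$id)
  w <- residual_weights(ref_ph$reliability)
  grms_ref <- lapply(grms, function(g) {
    g$matrix <- g$matrix[ref, ref, drop = FALSE]
    g
  })
  names(grms_ref) <- names(snp_sets)
  fit <- aireml_fit(y, grms_ref, weights = w, max_iter = max_iter)
  pred <- predict(fit, setNames(grms, names(snp_sets)), split$validation)

  if (fit$converged || force_accuracy) {
    ev <- evaluate_predictions(pheno, pred, split$validation)
  } else {
    ev <- tibble(accuracy = NA_real_, bias = NA_real_,
                 n_validation = length(split$validation),
                 mean_reliability = mean(pheno$reliability[pheno$id %in% split$validation]))
  }
  report <- dplyr::bind_cols(
    tibble(scenario = label,
           n_snps = length(unique(unlist(snp_sets))),
           n_reference = length(ref)),
    ev,
    tibble(converged = fit$converged, n_iter = fit$n_iter,
           sigma2_e = fit$sigma2_e)
  )
  for (k in seq_along(fit$components)) {
    report[[paste0("sigma2_", names(fit$components)[k])]] <- fit$components[k]
  }
  list(fit = fit, prediction = pred, report = report, split = split)
}

.scenarios <- c("selected_only", "chip_only", "wgs_all",
                "chip_plus_selected_oneG", "chip_plus_selected_twoG")

# shared-stage computation, memoized in `cache` (an environment) so a grid
# of scenarios runs QC, the scan and each selection once
.stage <- function(cache, key, fn) {
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  val <- fn()
  if (!is.null(cache)) cache[[key]] <- val
  val
}

.run_selection <- function(strategy, geno_ref, y_ref, gwas_res, preselect_p,
                           reg_config, cache) {
  pre <- .stage(cache, "preselected", function() {
    preselect_by_threshold(gwas_res, preselect_p)
  })
  base <- sub("^LMM_", "", strategy)
  sel_key <- paste0("sel_", base)
  sel <- .stage(cache, sel_key, function() {
    if (!length(pre)) return(tibble(snp_id = character()))
    X <- geno_ref$codes[, pre, drop = FALSE]
    X[is.na(X)] <- 0
    tidy(cv_select_1se(X, y_ref, reg_config,
                       mode = if (base == "LASSO") "lasso" else "en"))
  })
  if (strategy %in% c("EN", "LASSO")) return(sel$snp_id)
  n_matched <- nrow(sel)
  if (n_matched == 0L) return(character())
  top_n_by_pvalue(gwas_res, n_matched,
                  strategy = paste0("LMM_", base))$snp_id
}

#' Run one genomic-selection scenario end to end
#'
#' Executes quality control, the reference/validation split, (when the
#' strategy calls for it) the leave-one-chromosome-out mixed-model scan and
#' feature selection, relationship-matrix construction, reliability-weighted
#' GBLUP and validation metrics. Scenarios:
#' \describe{
#'   \item{selected_only}{GBLUP on the selected whole-sequence SNPs only.}
#'   \item{chip_only}{GBLUP on the chip panel (no scan or selection).}
#'   \item{wgs_all}{GBLUP on every SNP passing QC.}
#'   \item{chip_plus_selected_oneG}{One relationship matrix on the
#'     duplicate-free union of chip and selected SNPs.}
#'   \item{chip_plus_selected_twoG}{Two relationship matrices: selected
#'     SNPs, and chip SNPs with the overlap removed.}
#' }
#'
#' @param data List with `geno` (`geno_matrix`) and `pheno` (tibble), e.g.
#'   from [simulate_population()].
#' @param scenario One of the five scenario names.
#' @param strategy Feature-selection strategy: `"EN"`, `"LASSO"`,
#'   `"LMM_EN"`, `"LMM_LASSO"`, or `"none"` (only valid for `chip_only` /
#'   `wgs_all`). The `LMM_*` strategies select the top SNPs by scan p-value,
#'   with the count matched to the corresponding regularized selection.
#' @param chip_snps Chip panel SNP ids; if NULL, a seeded subsample of size
#'   `chip_size` is drawn (see [make_chip_panel()]).
#' @param chip_size,chip_seed Pseudo-chip subsample controls.
#' @param thresholds QC thresholds ([qc_thresholds()]).
#' @param reg_config Feature-selection settings ([regularization_config()]).
#' @param preselect_p Scan p-value threshold for pre-selection (default
#'   0.05).
#' @param cutoff_year,min_reliability Reference/validation split settings.
#' @param max_iter AI-REML iteration cap.
#' @param cache Environment memoizing shared stages across scenarios (used
#'   by [run_scenario_grid()]).
#' @param out_dir Optional directory; when given, the report, validation
#'   GEBVs, selected features and a manifest (input hash, seeds, package
#'   version) are written there.
#' @return List: `report` (one-row tibble), `fit`, `prediction`, `split`,
#'   `features` (selected SNP ids or NULL), `n_overlap` (merged scenarios).
#' @export
run_scenario <- function(data,
                         scenario = .scenarios,
                         strategy = c("none", "EN", "LASSO", "LMM_EN", "LMM_LASSO"),
                         chip_snps = NULL, chip_size = NULL, chip_seed = 1L,
                         thresholds = qc_thresholds(),
                         reg_config = regularization_config(),
                         preselect_p = 0.05,
                         cutoff_year = 2013L, min_reliability = 0.40,
                         max_iter = 1000L,
                         cache = NULL, out_dir = NULL) {
  scenario <- match.arg(scenario)
  strategy <- match.arg(strategy)
  needs_sel <- !scenario %in% c("chip_only", "wgs_all")
  if (needs_sel && strategy == "none") {
    stop_gsfs("scenario '", scenario, "' requires a feature-selection strategy")
  }
  if (!needs_sel && strategy != "none") {
    stop_gsfs("strategy must be 'none' for scenario '", scenario, "'")
  }

  qc <- .stage(cache, "qc", function() run_qc(data$geno, thresholds))
  geno <- qc$geno
  pheno <- dplyr::filter(data$pheno, .data$id %in% rownames(geno$codes))
  split <- .stage(cache, "split", function() {
    partition_population(pheno, cutoff_year, min_reliability)
  })

  all_snps <- colnames(geno$codes)
  chip <- NULL
  if (scenario != "selected_only" && scenario != "wgs_all") {
    chip <- chip_snps %||% .stage(cache, "chip", function() {
      make_chip_panel(geno, chip_size %||% max(1L, ncol(geno$codes) %/% 5L), chip_seed)
    })
    chip <- intersect(chip, all_snps)
  }

  features <- NULL
  if (needs_sel) {
    geno_ref <- .stage(cache, "geno_ref", function() {
      .subset_individuals(geno, split$reference)
    })
    ref_ph <- pheno[match(split$reference, pheno$id), ]
    y_ref <- setNames(ref_ph$drp, ref_ph$id)
    gwas_res <- .stage(cache, "gwas", function() {
      wald_scan(geno_ref, y_ref, fit_loco_nulls(geno_ref, y_ref))
    })
    features <- .run_selection(strategy, geno_ref, y_ref, gwas_res,
                               preselect_p, reg_config, cache)
  }

  n_overlap <- NA_integer_
  snp_sets <- switch(
    scenario,
    selected_only = {
      if (!length(features)) stop_gsfs("empty selected set", class = "gsfs_empty_result")
      list(selected = features)
    },
    chip_only = list(chip = chip),
    wgs_all = list(wgs = all_snps),
    chip_plus_selected_oneG = {
      mg <- merge_snp_sets(chip, features)
      n_overlap <- mg$n_overlap
      list(combined = mg$union)
    },
    chip_plus_selected_twoG = {
      mg <- merge_snp_sets(chip, features)
      n_overlap <- mg$n_overlap
      if (!length(mg$selected)) stop_gsfs("empty selected set", class = "gsfs_empty_result")
      list(fs = mg$selected, chip = mg$chip_minus_overlap)
    }
  )

  res <- evaluate_snp_set(geno, pheno, snp_sets, label = scenario,
                          split = split, max_iter = max_iter)
  res$report <- dplyr::mutate(res$report, strategy = strategy,
                              n_overlap = n_overlap, .after = "scenario")
  res$features <- features
  res$n_overlap <- n_overlap
  if (!is.null(out_dir)) .write_scenario_artifacts(res, data, out_dir, scenario, strategy)
  res
}

.write_scenario_artifacts <- function(res, data, out_dir, scenario, strategy) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(out_dir, paste0(scenario, if (strategy != "none") paste0("_", strategy)))
  utils::write.table(res$report, paste0(stem, "_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$prediction, paste0(stem, "_gebv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$features)) {
    utils::write.table(data.frame(snp_id = res$features), paste0(stem, "_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(
      scenario = scenario, strategy = strategy,
      input_hash = rlang::hash(list(data$geno$codes, data$pheno)),
      package_version = as.character(utils::packageVersion("gsfs")),
      timestamp = format(Sys.time(), tz = "UTC"),
      converged = res$report$converged,
      n_snps = res$report$n_snps
    )
    jsonlite::write_json(manifest, paste0(stem, "_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(NULL)
}

#' Run the full scenario grid with shared stages
#'
#' Runs every scenario/strategy combination, computing the expensive shared
#' stages (QC, the association scan, each feature selection) once. The five
#' canonical scenarios with one strategy yield a five-row report.
#'
#' @inheritParams run_scenario
#' @param scenarios Scenario names to run.
#' @param strategy Strategy used by the selection-based scenarios.
#' @return List with `report` (one row per run) and `runs` (named list of
#'   [run_scenario()] results).
#' @export
run_scenario_grid <- function(data, scenarios = .scenarios, strategy = "EN",
                              chip_snps = NULL, chip_size = NULL, chip_seed = 1L,
                              thresholds = qc_thresholds(),
                              reg_config = regularization_config(),
                              preselect_p = 0.05,
                              cutoff_year = 2013L, min_reliability = 0.40,
                              max_iter = 1000L, out_dir = NULL) {
  cache <- new.env(parent = emptyenv())
  runs <- list()
  for (sc in scenarios) {
    st <- if (sc %in% c("chip_only", "wgs_all")) "none" else strategy
    runs[[sc]] <- run_scenario(data, sc, st,
                               chip_snps = chip_snps, chip_size = chip_size,
                               chip_seed = chip_seed, thresholds = thresholds,
                               reg_config = reg_config, preselect_p = preselect_p,
                               cutoff_year = cutoff_year,
                               min_reliability = min_reliability,
                               max_iter = max_iter, cache = cache,
                               out_dir = out_dir)
  }
  list(report = dplyr::bind_rows(lapply(runs, `[[`, "report")), runs = runs)
}
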