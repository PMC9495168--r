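#' Split a population into reference and validation sets by birth year
#'
#' Individuals born strictly before the cutoff year form the reference
#' (training) population; individuals born in or after the cutoff form the
#' validation population, after removing validation candidates whose DRP
#' reliability falls below `min_reliability`. The reliability filter applies
#' to the validation set only: low-reliability proofs still contribute
#' information on the reference side, but make validation benchmarks
#' unreliable.
#'
#' @param pheno Tibble with columns `id`, `reliability`, `birth_year`.
#' @param cutoff_year Birth-year cutoff (default 2013).
#' @param min_reliability Minimum validation reliability (default 0.40,
#'   inclusive).
#' @return List with character vectors `reference` and `validation` (always
#'   disjoint), plus `n_dropped` (validation candidates failing the
#'   reliability filter).
#' @export
partition_population <- function(pheno, cutoff_year = 2013L, min_reliability = 0.40) {
  stopifnot(is.data.frame(pheno),
            all(c("id", "reliability", "birth_year") %in% names(pheno)))
  if (anyDuplicated(pheno$id)) stop_gsfs("duplicate individual ids")
  ref <- pheno$id[pheno$birth_year < cutoff_year]
  cand <- pheno$birth_year >= cutoff_year
  val <- pheno$id[cand & pheno$reliability >= min_reliability]
  if (!length(ref)) stop_gsfs("empty reference population", class = "gsfs_empty_result")
  if (!length(val)) stop_gsfs("empty validation population", class = "gsfs_empty_result")
  list(reference = as.character(ref), validation = as.character(val),
       n_dropped = sum(cand) - length(val))
}

#' Reliability-corrected prediction accuracy
#'
#' The Pearson correlation between DRP and GEBV in the validation set,
#' divided by the square root of the mean DRP reliability: because the DRP
#' is itself a noisy proxy of the true breeding value, the raw correlation
#' understates accuracy by about `sqrt(mean(r2))`.
#'
#' @param drp,gebv Validation DRPs and predicted breeding values.
#' @param reliabilities Validation DRP reliabilities.
#' @return Corrected accuracy (scalar).
#' @export
prediction_accuracy <- function(drp, gebv, reliabilities) {
  drp <- as.numeric(drp); gebv <- as.numeric(gebv)
  if (length(drp) < 2L || length(drp) != length(gebv)) {
    stop_gsfs("need at least two paired observations")
  }
  if (sd(drp) == 0 || sd(gebv) == 0) stop_gsfs("zero variance in DRP or GEBV")
  r2 <- as.numeric(reliabilities)
  if (any(r2 <= 0 | r2 > 1)) stop_gsfs("reliabilities must lie in (0, 1]")
  cor(drp, gebv) / sqrt(mean(r2))
}

#' Dispersion bias of genomic predictions
#'
#' Ordinary least-squares slope of DRP regressed on GEBV. A slope of 1
#' means predictions are correctly dispersed; below 1, GEBVs are
#' over-dispersed (inflated), above 1 under-dispersed.
#'
#' @param drp,gebv Validation DRPs and predicted breeding values.
#' @return Regression slope (scalar).
#' @export
prediction_bias <- function(drp, gebv) {
  drp <- as.numeric(drp); gebv <- as.numeric(gebv)
  if (length(drp) != length(gebv) || length(drp) < 2L) {
    stop_gsfs("need at least two paired observations")
  }
  if (sd(gebv) == 0) stop_gsfs("GEBV has zero variance")
  unname(coef(lm(drp ~ gebv))[2L])
}

#' Evaluate genomic predictions on a validation set
#'
#' @param pheno Phenotype tibble (`id`, `drp`, `reliability`).
#' @param gebv Tibble with `id` and `gebv` (e.g. from
#'   [predict.gblup_fit()]).
#' @param validation_ids Ids of the validation individuals.
#' @return One-row tibble: `accuracy`, `bias`, `n_validation`,
#'   `mean_reliability`.
#' @export
evaluate_predictions <- function(pheno, gebv, validation_ids) {
  stopifnot(is.data.frame(pheno), is.data.frame(gebv))
  df <- dplyr::inner_join(
    dplyr::filter(pheno, .data$id %in% validation_ids),
    dplyr::select(gebv, "id", "gebv"), by = "id")
  if (nrow(df) < 2L) stop_gsfs("fewer than two validation individuals with predictions")
  tibble(
    accuracy = prediction_accuracy(df$drp, df$gebv, df$reliability),
    bias = prediction_bias(df$drp, df$gebv),
    n_validation = nrow(df),
    mean_reliability = mean(df$reliability)
  )
}
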