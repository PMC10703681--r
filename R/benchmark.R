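#' Run the simulated-missingness accuracy benchmark
#'
#' The package's standard evaluation protocol on one synthetic dataset:
#' split individuals 50/50 into train and test, fit the autoencoder on the
#' training half, withhold a fraction of the test half's observed entries by
#' copy-masking, impute, and score against the withheld truth. Training uses
#' mini-batches of 512 rows, learning rate 0.05 and up to 400 epochs —
#' settings matched to the benchmark's few-thousand-row training sets (the
#' biobank-scale defaults of [train_config()] assume hundreds of thousands
#' of rows).
#'
#' @param config a [synth_config()]; its seed drives data generation.
#' @param seed seed for the split, training and evaluation mask.
#' @param target_fraction fraction of observed test entries withheld.
#' @param mask_mode training augmentation mode, `"copy"` or `"uniform"`.
#' @param epochs,batch_size,learning_rate training settings (see Details).
#' @param B,B_ci bootstrap replicates for the metric report.
#' @return list with `report` (a `metric_report`), `fit`, `eval_mask`,
#'   `test_masked` and the column-mean baseline report `baseline_report`
#'   (column means have zero variance, so their r-squared is undefined and
#'   scored 0).
#' @export
run_accuracy_benchmark <- function(config = synth_config(), seed = 1,
                                   target_fraction = 0.1,
                                   mask_mode = c("copy", "uniform"),
                                   epochs = 400, batch_size = 512,
                                   learning_rate = 0.05, B = 20, B_ci = 20) {
  mask_mode <- match.arg(mask_mode)
  syn <- generate_phenotypes(config)
  sp <- split_individuals(syn$masked, test_fraction = 0.5,
                          validation_fraction = 0, seed = seed)
  fit <- phenocomplete(sp$train, epochs = epochs, batch_size = batch_size,
                       learning_rate = learning_rate, mask_mode = mask_mode,
                       seed = seed, keep_data = FALSE)
  em <- simulate_missingness_copy(sp$test, target_fraction, seed = seed)
  tm <- apply_evaluation_mask(sp$test, em)
  imp <- impute_matrix(tm, fit)
  report <- evaluate_imputation(imp, em, B = B, B_ci = B_ci, seed = seed)

  # column-mean baseline: constant imputations per phenotype
  base_vals <- imp$values
  for (j in seq_len(ncol(base_vals))) {
    obs <- tm$mask[, j] == 1L
    base_vals[!obs, j] <- if (any(obs)) mean(tm$values[obs, j]) else 0
  }
  baseline <- evaluate_imputation(
    structure(list(values = base_vals, ids = imp$ids, schema = imp$schema,
                   observed_mask = tm$mask), class = "imputed_pheno"),
    em, B = 2, B_ci = 2, seed = seed)
  list(report = report, fit = fit, eval_mask = em, test_masked = tm,
       baseline_report = baseline, data = syn)
}
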