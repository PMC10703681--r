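#' Squared Pearson correlation
#'
#' The primary imputation-accuracy metric: the square of the Pearson
#' correlation between imputed and true values at withheld cells. For binary
#' phenotypes it is computed between the predicted probability and the 0/1
#' truth. Invariant to affine transformation of either argument.
#'
#' @param imputed numeric vector of imputed values / probabilities.
#' @param truth numeric vector of true values at the same cells.
#' @return r-squared in `[0,1]`, or `NA` when fewer than two cells or either
#'   vector has zero variance (the metric is then undefined and the phenotype
#'   is excluded from aggregates).
#' @export
r2_score <- function(imputed, truth) {
  ok <- is.finite(imputed) & is.finite(truth)
  imputed <- imputed[ok]; truth <- truth[ok]
  if (length(truth) < 2L) return(NA_real_)
  if (stats::sd(truth) == 0 || stats::sd(imputed) == 0) return(NA_real_)
  stats::cor(imputed, truth)^2
}

#' Ranking metrics for binary phenotypes
#'
#' AUROC is computed in its Mann-Whitney form: the probability that a random
#' positive outranks a random negative, with ties counted one half. AUPR is
#' the area under the step-wise precision-recall curve (precision held
#' constant between recall points; tied scores grouped), equivalently the
#' average precision over descending score thresholds.
#'
#' @param scores predicted probabilities (any monotone score works).
#' @param labels 0/1 truth.
#' @return A list with elements `aupr` and `auroc`; both `NA` when only one
#'   class is present.
#' @export
binary_rank_metrics <- function(scores, labels) {
  ok <- is.finite(scores) & is.finite(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop_pc("labels must be 0/1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    return(list(aupr = NA_real_, auroc = NA_real_))
  }
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # step-wise PR area: group tied scores, precision at each threshold
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  grp_end <- cumsum(rle(sc)$lengths)  # last index of each tied group
  tp <- cumsum(lab)[grp_end]
  fp <- (grp_end) - tp
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  dr <- diff(c(0, recall))
  aupr <- sum(precision * dr)
  list(aupr = aupr, auroc = auroc)
}

#' Bootstrap uncertainty for a metric
#'
#' Resamples the evaluated cells with replacement and recomputes the metric.
#' The standard error is the standard deviation over `B` resamples (default
#' 50); the confidence interval uses the 2.5/97.5 percentiles over `B_ci`
#' resamples (default 100).
#'
#' @param metric_fn function of `(imputed, truth)` returning a scalar.
#' @param imputed,truth the evaluated cells.
#' @param B replicates for the standard error.
#' @param B_ci replicates for the percentile CI.
#' @param seed integer seed.
#' @return list with `se`, `ci` (length 2) and `failed` (TRUE when the
#'   metric was undefined on more than half the resamples).
#' @export
bootstrap_uncertainty <- function(metric_fn, imputed, truth, B = 50,
                                  B_ci = 100, seed = 1) {
  if (B < 2) stop_pc("B must be >= 2")
  n <- length(truth)
  draw <- function(nrep) {
    vapply(seq_len(nrep), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric_fn(imputed[idx], truth[idx])
    }, numeric(1))
  }
  with_seed(derive_seed(seed, 9L), {
    vals_se <- draw(B)
    vals_ci <- draw(B_ci)
  })
  failed <- mean(is.na(vals_se)) > 0.5
  list(se = stats::sd(vals_se, na.rm = TRUE),
       ci = stats::quantile(vals_ci, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE),
       failed = failed)
}

#' Evaluate imputation accuracy against withheld truth
#'
#' Scores a completed matrix at the cells withheld by an evaluation mask:
#' per-phenotype r-squared (all phenotypes), AUPR and AUROC (binary
#' phenotypes), each with bootstrap standard errors and percentile
#' confidence intervals, plus unweighted aggregate means. Aggregate
#' standard errors use a shared replicate index: within each replicate,
#' cells are resampled within every phenotype and the per-phenotype metrics
#' averaged.
#'
#' @param imputed an `imputed_pheno` (from [predict.phenocomplete()]) or a
#'   numeric matrix aligned with the mask's source data.
#' @param eval_mask an `evaluation_mask` from [simulate_missingness_copy()]
#'   or [simulate_missingness_uniform()].
#' @param B,B_ci bootstrap replicate counts for SEs and CIs.
#' @param seed integer seed for the bootstrap.
#' @return An object of class `metric_report`: `per_phenotype` data frame,
#'   `aggregate` list (`mean_r2`, `mean_r2_binary`, with SEs and CIs),
#'   `undefined` (phenotypes excluded from aggregates), `n_cells`.
#' @export
evaluate_imputation <- function(imputed, eval_mask, B = 50, B_ci = 100,
                                seed = 1) {
  vals <- if (is.matrix(imputed)) imputed else imputed$values
  schema <- if (is.matrix(imputed)) NULL else imputed$schema
  cells <- eval_mask$cells
  pred <- vals[cbind(cells$row, cells$col)]
  phenos <- unique(cells$phenotype)
  is_bin <- function(ph) {
    if (is.null(schema)) FALSE else schema$kind[match(ph, schema$name)] == "binary"
  }
  rows <- lapply(seq_along(phenos), function(k) {
    ph <- phenos[k]
    sel <- cells$phenotype == ph
    p <- pred[sel]; t <- cells$true_value[sel]
    r2 <- r2_score(p, t)
    bs <- if (!is.na(r2)) {
      bootstrap_uncertainty(r2_score, p, t, B, B_ci,
                            seed = derive_seed(seed, 100L + k))
    } else list(se = NA_real_, ci = c(NA_real_, NA_real_))
    out <- data.frame(phenotype = ph,
                      kind = if (is.null(schema)) NA_character_ else
                        schema$kind[match(ph, schema$name)],
                      n_cells = sum(sel), r2 = r2, r2_se = bs$se,
                      r2_lo = bs$ci[1], r2_hi = bs$ci[2],
                      aupr = NA_real_, aupr_se = NA_real_,
                      auroc = NA_real_, auroc_se = NA_real_,
                      stringsAsFactors = FALSE)
    if (is_bin(ph)) {
      rm <- binary_rank_metrics(p, t)
      out$aupr <- rm$aupr
      out$auroc <- rm$auroc
      if (!is.na(rm$auroc)) {
        bs_roc <- bootstrap_uncertainty(
          function(pp, tt) binary_rank_metrics(pp, tt)$auroc, p, t, B, B_ci,
          seed = derive_seed(seed, 200L + k))
        bs_pr <- bootstrap_uncertainty(
          function(pp, tt) binary_rank_metrics(pp, tt)$aupr, p, t, B, B_ci,
          seed = derive_seed(seed, 300L + k))
        out$auroc_se <- bs_roc$se
        out$aupr_se <- bs_pr$se
      }
    }
    out
  })
  per <- do.call(rbind, rows)
  defined <- !is.na(per$r2)
  binary <- !is.na(per$kind) & per$kind == "binary"

  # aggregate SE: shared replicate index across phenotypes
  agg_boot <- function(sel, B) {
    with_seed(derive_seed(seed, 400L), {
      vapply(seq_len(B), function(b) {
        vals_b <- vapply(which(sel), function(k) {
          s <- cells$phenotype == phenos[k]
          idx <- sample.int(sum(s), sum(s), replace = TRUE)
          r2_score(pred[s][idx], cells$true_value[s][idx])
        }, numeric(1))
        mean(vals_b, na.rm = TRUE)
      }, numeric(1))
    })
  }
  mean_r2 <- if (any(defined)) mean(per$r2[defined]) else NA_real_
  mean_r2_bin <- if (any(defined & binary)) {
    mean(per$r2[defined & binary])
  } else NA_real_
  reps_all <- if (any(defined)) agg_boot(defined, B) else NA_real_
  reps_bin <- if (any(defined & binary)) agg_boot(defined & binary, B) else NA_real_
  aggregate <- list(
    mean_r2 = mean_r2,
    mean_r2_se = if (all(is.na(reps_all))) NA_real_ else stats::sd(reps_all),
    mean_r2_binary = mean_r2_bin,
    mean_r2_binary_se = if (all(is.na(reps_bin))) NA_real_ else
      stats::sd(reps_bin),
    mean_aupr = if (any(!is.na(per$aupr))) mean(per$aupr, na.rm = TRUE)
      else NA_real_,
    mean_auroc = if (any(!is.na(per$auroc))) mean(per$auroc, na.rm = TRUE)
      else NA_real_)
  structure(list(per_phenotype = per, aggregate = aggregate,
                 undefined = per$phenotype[!defined],
                 n_cells = nrow(cells),
                 target_fraction = eval_mask$target_fraction,
                 achieved_fraction = eval_mask$achieved_fraction),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Imputation accuracy on %d withheld cells (%.1f%% of observed)\n",
              x$n_cells, 100 * x$achieved_fraction))
  cat(sprintf("  mean r2            %.4f (SE %.4f)\n",
              x$aggregate$mean_r2, x$aggregate$mean_r2_se))
  if (!is.na(x$aggregate$mean_r2_binary)) {
    cat(sprintf("  mean r2 (binary)   %.4f (SE %.4f)\n",
                x$aggregate$mean_r2_binary, x$aggregate$mean_r2_binary_se))
    cat(sprintf("  mean AUPR %.4f, mean AUROC %.4f\n",
                x$aggregate$mean_aupr, x$aggregate$mean_auroc))
  }
  if (length(x$undefined)) {
    cat("  undefined for:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare two methods' accuracy reports
#'
#' Per-phenotype two-tailed z-test on the difference in r-squared using the
#' bootstrap standard errors, `z = (a - b) / sqrt(se_a^2 + se_b^2)`, with a
#' Bonferroni threshold `alpha / P_tests`; plus the same test on the
#' aggregate means.
#'
#' @param report_a,report_b `metric_report`s evaluated on identical withheld
#'   cells (method A and method B).
#' @param alpha significance level before correction.
#' @param P_tests number of tests for the Bonferroni correction; defaults to
#'   the number of comparable phenotypes.
#' @return A list: `per_phenotype` data frame (difference, z, p, call in
#'   {"better","worse","ns"}), `n_better`, `n_worse`, `threshold`, and the
#'   aggregate z and p.
#' @export
compare_methods <- function(report_a, report_b, alpha = 0.05,
                            P_tests = NULL) {
  a <- report_a$per_phenotype
  b <- report_b$per_phenotype
  if (!identical(a$phenotype, b$phenotype) ||
      !identical(a$n_cells, b$n_cells)) {
    stop_pc("reports were not evaluated on identical withheld cells")
  }
  P_tests <- P_tests %||% nrow(a)
  thr <- alpha / P_tests
  diff <- a$r2 - b$r2
  se <- sqrt(a$r2_se^2 + b$r2_se^2)
  z <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- 2 * stats::pnorm(-abs(z))
  call <- ifelse(is.na(p) | p >= thr, "ns",
                 ifelse(diff > 0, "better", "worse"))
  agg_diff <- report_a$aggregate$mean_r2 - report_b$aggregate$mean_r2
  agg_se <- sqrt(report_a$aggregate$mean_r2_se^2 +
                 report_b$aggregate$mean_r2_se^2)
  agg_z <- if (is.finite(agg_se) && agg_se > 0) agg_diff / agg_se else
    if (isTRUE(agg_diff == 0)) 0 else NA_real_
  list(per_phenotype = data.frame(
         phenotype = a$phenotype, r2_a = a$r2, r2_b = b$r2,
         difference = diff, z = z, p = p, call = call,
         stringsAsFactors = FALSE),
       n_better = sum(call == "better"), n_worse = sum(call == "worse"),
       threshold = thr,
       aggregate = list(difference = agg_diff, z = agg_z,
                        p = 2 * stats::pnorm(-abs(agg_z))))
}

#' Variance-ratio imputation quality control
#'
#' The ratio of the variance of the imputed portion of a phenotype to the
#' variance of its observed portion, analogous to genotype-imputation INFO
#' metrics. Over-shrunk, low-information imputations give small ratios; a
#' ratio above 0.2 is the recommended starting threshold for trusting a
#' phenotype's imputations in downstream analysis.
#'
#' @param imputed_values values filled in at originally missing cells.
#' @param observed_values originally observed values of the same phenotype.
#' @param threshold PASS/FAIL threshold on the ratio.
#' @return list with `ratio`, `pass`, `threshold`.
#' @export
variance_ratio_qc <- function(imputed_values, observed_values,
                              threshold = 0.2) {
  if (length(imputed_values) < 2L || length(observed_values) < 2L) {
    stop_pc("both portions need at least 2 values")
  }
  v_obs <- stats::var(observed_values)
  if (v_obs == 0) stop_pc("observed portion has zero variance")
  ratio <- stats::var(imputed_values) / v_obs
  list(ratio = ratio, pass = ratio > threshold, threshold = threshold)
}
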