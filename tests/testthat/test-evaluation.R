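test_that("r2 matches the definitional Pearson formula and its invariances", {
  truth <- c(1, 2, 3, 4)
  imputed <- c(1.1, 2.3, 2.6, 4.4)
  # brute-force covariance/SD computation
  cv <- mean((imputed - mean(imputed)) * (truth - mean(truth)))
  oracle <- (cv / (sqrt(mean((imputed - mean(imputed))^2)) *
                   sqrt(mean((truth - mean(truth))^2))))^2
  expect_equal(r2_score(imputed, truth), oracle)
  expect_equal(r2_score(truth, truth), 1)
  expect_equal(r2_score(3 - 2 * truth, truth), 1)  # affine invariance
  for (s in 1:10) {
    x <- withr::with_seed(s, rnorm(30))
    y <- withr::with_seed(s + 100, rnorm(30))
    expect_equal(r2_score(2 * x + 1, y), r2_score(x, y))
  }
  expect_true(is.na(r2_score(rep(1, 5), 1:5)))
  expect_true(is.na(r2_score(1, 1)))
})

test_that("AUROC equals brute-force pairwise concordance, ties counted half", {
  brute_auroc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (n in neg) {
      tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
    }
    tot / (length(pos) * length(neg))
  }
  expect_equal(binary_rank_metrics(c(0.9, 0.8, 0.7, 0.6),
                                   c(1, 0, 1, 0))$auroc, 3 / 4)
  for (s in 1:100) {
    n <- withr::with_seed(s, sample(5:200, 1))
    scores <- withr::with_seed(s + 1000,
                               round(runif(n), 1))  # coarse grid forces ties
    labels <- withr::with_seed(s + 2000, rbinom(n, 1, 0.4))
    if (length(unique(labels)) < 2) next
    expect_equal(binary_rank_metrics(scores, labels)$auroc,
                 brute_auroc(scores, labels))
  }
})

test_that("degenerate ranking cases follow the declared conventions", {
  perfect <- binary_rank_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$aupr, 1)
  ties <- binary_rank_metrics(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(ties$auroc, 0.5)
  expect_equal(ties$aupr, 0.5)  # precision = prevalence at the single threshold
  one_class <- binary_rank_metrics(runif(5), rep(1, 5))
  expect_true(is.na(one_class$auroc) && is.na(one_class$aupr))
})

test_that("AUPR agrees with a step-curve oracle and is bounded by prevalence", {
  step_aupr <- function(scores, labels) {
    thr <- sort(unique(scores), decreasing = TRUE)
    rec <- 0; area <- 0
    for (t in thr) {
      sel <- scores >= t
      prec <- sum(labels[sel]) / sum(sel)
      r <- sum(labels[sel]) / sum(labels)
      area <- area + prec * (r - rec)
      rec <- r
    }
    area
  }
  for (s in 1:25) {
    scores <- withr::with_seed(s, round(runif(40), 1))
    labels <- withr::with_seed(s + 50, rbinom(40, 1, 0.3))
    if (length(unique(labels)) < 2) next
    got <- binary_rank_metrics(scores, labels)$aupr
    expect_equal(got, step_aupr(scores, labels))
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
})

test_that("rank metrics agree with pROC on random instances", {
  skip_if_not_installed("pROC")
  for (s in 1:10) {
    scores <- withr::with_seed(s, runif(60))
    labels <- withr::with_seed(s + 10, rbinom(60, 1, 0.5))
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(binary_rank_metrics(scores, labels)$auroc, ref)
  }
})

test_that("bootstrap SE tracks the analytic SE of a mean and converges in B", {
  x <- withr::with_seed(1, rnorm(10000))
  got <- bootstrap_uncertainty(function(p, t) mean(t), x, x, B = 50,
                               seed = 2)
  expect_lt(abs(got$se - 0.01) / 0.01, 0.30)
  const <- bootstrap_uncertainty(function(p, t) 42, x[1:50], x[1:50],
                                 B = 50, seed = 3)
  expect_equal(const$se, 0)
  big <- withr::with_seed(4, rnorm(5000))
  se_b <- bootstrap_uncertainty(function(p, t) mean(t), big, big, B = 100,
                                seed = 5)$se
  se_2b <- bootstrap_uncertainty(function(p, t) mean(t), big, big, B = 200,
                                 seed = 5)$se
  expect_lt(abs(se_2b - se_b) / se_b, 0.10)
})

test_that("metric reports aggregate per-phenotype values consistently", {
  s <- small_fit_setup()
  em <- simulate_missingness_copy(s$split$test, 0.15, seed = 2)
  tm <- apply_evaluation_mask(s$split$test, em)
  rep <- evaluate_imputation(predict(s$fit, tm), em, B = 10, B_ci = 10)
  per <- rep$per_phenotype
  defined <- !is.na(per$r2)
  expect_equal(rep$aggregate$mean_r2, mean(per$r2[defined]))
  bin <- defined & per$kind == "binary"
  if (any(bin)) {
    expect_equal(rep$aggregate$mean_r2_binary, mean(per$r2[bin]))
  }
  expect_true(all(per$r2[defined] >= 0 & per$r2[defined] <= 1))
  expect_equal(sum(per$n_cells), nrow(em$cells))
})

test_that("method comparison reproduces the hand z-test and Bonferroni rule", {
  # z = (0.30 - 0.25) / sqrt(2) * 100 -> 3.54; p from the normal tail
  z <- (0.30 - 0.25) / sqrt(0.01^2 + 0.01^2)
  expect_equal(z, 3.5355, tolerance = 1e-4)
  expect_equal(2 * pnorm(-z), 4.06e-4, tolerance = 0.01)
  expect_equal(0.05 / 230, 2.17e-4, tolerance = 0.01)

  mk_report <- function(r2s, ses) {
    per <- data.frame(phenotype = paste0("p", seq_along(r2s)),
                      kind = "continuous", n_cells = 100L, r2 = r2s,
                      r2_se = ses, r2_lo = NA, r2_hi = NA, aupr = NA,
                      aupr_se = NA, auroc = NA, auroc_se = NA)
    structure(list(per_phenotype = per,
                   aggregate = list(mean_r2 = mean(r2s),
                                    mean_r2_se = mean(ses)),
                   undefined = character(0), n_cells = 100L,
                   target_fraction = 0.1, achieved_fraction = 0.1),
              class = "metric_report")
  }
  a <- mk_report(c(0.30, 0.20), c(0.01, 0.01))
  b <- mk_report(c(0.25, 0.20), c(0.01, 0.01))
  cmp <- compare_methods(a, b, alpha = 0.05, P_tests = 2)
  expect_equal(cmp$per_phenotype$z[1], z)
  expect_equal(cmp$per_phenotype$p[2], 1)
  expect_equal(cmp$n_better, 1L)
  expect_equal(cmp$threshold, 0.025)
  same <- compare_methods(a, a)
  expect_true(all(same$per_phenotype$p == 1))
  expect_equal(same$n_better + same$n_worse, 0L)
  expect_error(compare_methods(a, mk_report(0.1, 0.01)), "identical")
})

test_that("variance-ratio QC flags over-shrunk imputations", {
  obs <- withr::with_seed(6, rnorm(500))
  shuffled <- withr::with_seed(7, sample(obs))
  qc <- variance_ratio_qc(shuffled, obs)
  expect_equal(qc$ratio, 1, tolerance = 1e-10)
  expect_true(qc$pass)
  flat <- variance_ratio_qc(rep(0.31, 100) + 1e-9 * seq_len(100), obs)
  expect_lt(flat$ratio, 0.001)
  expect_false(flat$pass)
  expect_equal(qc$threshold, 0.2)
  expect_error(variance_ratio_qc(rnorm(10), rep(1, 10)), "zero variance")
})
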