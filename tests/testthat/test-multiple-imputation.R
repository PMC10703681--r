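test_that("Rubin pooling reproduces the two-imputation worked example", {
  pe <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(pe$Q_bar, 2)
  expect_equal(pe$W_bar, 1)
  expect_equal(pe$B, 2)
  expect_equal(pe$T, 1 + 1.5 * 2)
  expect_equal(pe$se, 2)
})

test_that("pooling degenerate cases: agreement and single imputation", {
  same <- rubin_pool(rep(0.7, 5), rep(0.2, 5))
  expect_equal(same$B, 0)
  expect_equal(same$se, 0.2)
  expect_equal(same$Q_bar, 0.7)
  one <- rubin_pool(1.5, 0.5)
  expect_equal(one$Q_bar, 1.5)
  expect_equal(one$se, 0.5)
  expect_equal(one$p, 2 * pnorm(-3))
  expect_error(rubin_pool(numeric(0), numeric(0)), "at least one")
  expect_error(rubin_pool(c(1, 2), c(1, -1)), "positive")
  expect_error(rubin_pool(c(1, NA), c(1, 1)), "finite")
})

test_that("pooled variance dominates the within-imputation variance", {
  for (s in 1:20) {
    m <- withr::with_seed(s, sample(2:10, 1))
    est <- withr::with_seed(s + 20, rnorm(m))
    ses <- withr::with_seed(s + 40, runif(m, 0.1, 2))
    pe <- rubin_pool(est, ses)
    expect_gte(pe$T, pe$W_bar)
    expect_equal(pe$Q_bar, mean(est))
    expect_gte(pe$se, sqrt(pe$W_bar))
  }
})

test_that("association files pool per variant and catch mismatches", {
  t1 <- data.frame(SNP = c("rs1", "rs2"), CHR = c(1, 2),
                   BP = c(1000, 2000), BETA = c(1, 0.5), SE = c(1, 0.2),
                   P = c(0.3, 0.01))
  t2 <- data.frame(SNP = c("rs2", "rs1"), CHR = c(2, 1),
                   BP = c(2000, 1000), BETA = c(0.7, 3), SE = c(0.2, 1),
                   P = c(0.005, 0.002))
  pooled <- pool_association_files(list(t1, t2))
  by_hand_rs1 <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(pooled$BETA[pooled$SNP == "rs1"], by_hand_rs1$Q_bar)
  expect_equal(pooled$SE[pooled$SNP == "rs1"], by_hand_rs1$se)
  expect_equal(pooled$P[pooled$SNP == "rs1"], by_hand_rs1$p)
  # identical tables pool to themselves with p recomputed
  pid <- pool_association_files(list(t1, t1))
  expect_equal(pid$BETA, t1$BETA)
  expect_equal(pid$SE, t1$SE)
  t3 <- t1[1, ]
  expect_error(pool_association_files(list(t1, t3)), "rs2")
  t4 <- t2; t4$BP[1] <- 9999
  expect_error(pool_association_files(list(t1, t4)), "rs2")
})

test_that("association tables round-trip through TSV files", {
  t1 <- data.frame(SNP = "rs9", CHR = 3, BP = 500, BETA = 0.1, SE = 0.05,
                   P = 0.04)
  paths <- sapply(1:2, function(i) {
    p <- withr::local_tempfile(fileext = ".tsv",
                               .local_envir = parent.frame(3))
    write.table(t1, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })
  pooled <- pool_association_files(paths)
  expect_equal(pooled$BETA, 0.1)
  expect_equal(pooled$SE, 0.05)
})

test_that("effective sample size matches the worked bilirubin example", {
  ess <- effective_sample_size(226876, 0.510, 58531)
  expect_equal(ess$n_effective, 226876 + 0.510 * 58531)
  expect_equal(round(ess$fold_increase, 2), 0.13)
  expect_equal(effective_sample_size(100, 0, 50)$n_effective, 100)
  expect_equal(effective_sample_size(100, 1, 50)$n_effective, 150)
  # monotone in every argument
  base <- effective_sample_size(1000, 0.4, 500)$n_effective
  expect_gte(effective_sample_size(1100, 0.4, 500)$n_effective, base)
  expect_gte(effective_sample_size(1000, 0.5, 500)$n_effective, base)
  expect_gte(effective_sample_size(1000, 0.4, 600)$n_effective, base)
  expect_error(effective_sample_size(10, 1.2, 5), "r2")
})

test_that("sign-concordance test equals full binomial enumeration", {
  enum_p <- function(k, n) {
    probs <- dbinom(0:n, n, 0.5)
    sum(probs[probs <= dbinom(k, n, 0.5) + 1e-12])
  }
  for (n in c(1:12, 20)) {
    for (k in 0:n) {
      expect_equal(sign_concordance_test(k, n), min(1, enum_p(k, n)),
                   tolerance = 1e-10)
    }
  }
  expect_equal(sign_concordance_test(1, 2), 1)
  expect_error(sign_concordance_test(5, 3), "n_matching")
})

test_that("locus clumping absorbs neighbours within the window", {
  rec <- data.frame(SNP = c("a", "b", "c"), CHR = 1,
                    BP = c(1e6, 1.5e6, 3e6), P = c(1e-10, 1e-9, 1e-8 / 2))
  loci <- clump_loci(rec, threshold = 5e-8, window = 1e6)
  expect_equal(loci$SNP, c("a", "c"))  # b absorbed, c independent
  expect_equal(nrow(clump_loci(rec, threshold = 1e-12)), 0L)
  one <- clump_loci(rec[2, ], threshold = 5e-8)
  expect_equal(one$BP, 1.5e6)
  expect_equal(nrow(clump_loci(rec[0, ], 5e-8)), 0L)
})

test_that("clumping is order-independent and loci are mutually distant", {
  for (s in 1:10) {
    n <- 40
    rec <- withr::with_seed(s, data.frame(
      SNP = sprintf("rs%03d", 1:n),
      CHR = sample(1:3, n, replace = TRUE),
      BP = sample.int(1e7, n),
      P = 10^-runif(n, 4, 12)))
    loci <- clump_loci(rec, threshold = 5e-8, window = 1e6)
    shuffled <- withr::with_seed(s + 10, rec[sample.int(n), ])
    loci2 <- clump_loci(shuffled, threshold = 5e-8, window = 1e6)
    expect_equal(loci, loci2, ignore_attr = TRUE)
    # brute-force pairwise-distance check within chromosomes
    for (chr in unique(loci$CHR)) {
      bp <- loci$BP[loci$CHR == chr]
      if (length(bp) > 1) {
        expect_true(all(abs(outer(bp, bp, "-"))[lower.tri(diag(length(bp)))] >
                          1e6))
      }
    }
    # every significant variant is within the window of some locus
    sig <- rec[rec$P < 5e-8, ]
    covered <- mapply(function(chr, bp) {
      any(loci$CHR == chr & abs(loci$BP - bp) <= 1e6)
    }, sig$CHR, sig$BP)
    expect_true(all(covered))
  }
})

test_that("bootstrap multiple imputation varies only the imputed cells", {
  syn <- generate_phenotypes(synth_config(N = 500, P_cont = 8, P_bin = 2,
                                          k = 2, seed = 17))
  set <- multiple_impute(syn$masked, m = 3, seed = 4, epochs = 15,
                         batch_size = 128, learning_rate = 0.05)
  expect_equal(set$m, 3L)
  expect_length(set$failed, 0)
  v1 <- set$imputations[[1]]$values
  obs <- syn$masked$mask == 1L
  for (r in 2:3) {
    vr <- set$imputations[[r]]$values
    expect_identical(vr[obs], v1[obs])     # observed cells passthrough
    expect_identical(set$imputations[[r]]$ids, syn$masked$ids)
  }
  stacked <- sapply(set$imputations, function(im) im$values[!obs])
  between_var <- mean(apply(stacked, 1, var))
  expect_gt(between_var, 0)
  # bootstrap draws differ across replicates and are recorded
  expect_false(identical(set$boot_rows[[1]], set$boot_rows[[2]]))
})
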