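# Shared fixtures, all generated in code.

# A tiny handmade mixed-type matrix: 4 individuals, 2 continuous + 2 binary.
tiny_matrix <- function() {
  sch <- pheno_schema(c("height", "weight", "smoker", "diabetic"),
                      c("continuous", "continuous", "binary", "binary"))
  vals <- matrix(c(170, 60, 1, 0,
                   180, NA, 0, 1,
                   165, 55, NA, 0,
                   NA, 70, 1, NA),
                 nrow = 4, byrow = TRUE)
  pheno_matrix(vals, paste0("id", 1:4), sch)
}

# Random mixed matrix with uniform missingness, for property-style loops.
random_matrix <- function(N, P_cont, P_bin, miss = 0.2, seed = 1) {
  withr::with_seed(seed, {
    P <- P_cont + P_bin
    sch <- pheno_schema(sprintf("p%02d", seq_len(P)),
                        c(rep("continuous", P_cont), rep("binary", P_bin)))
    vals <- cbind(matrix(rnorm(N * P_cont), N, P_cont),
                  matrix(rbinom(N * P_bin, 1, 0.4), N, P_bin))
    drop <- matrix(runif(N * P) < miss, N, P)
    # keep at least 2 observed per column so normalization is defined
    for (j in seq_len(P)) {
      keep <- order(drop[, j])[1:2]
      drop[keep, j] <- FALSE
    }
    vals[drop] <- NA
    pheno_matrix(vals, sprintf("s%04d", seq_len(N)), sch)
  })
}

# Block-missing matrix: two questionnaire blocks skipped independently.
block_missing_matrix <- function(N = 200, seed = 1) {
  withr::with_seed(seed, {
    sch <- pheno_schema(sprintf("q%02d", 1:8), rep("continuous", 8))
    vals <- matrix(rnorm(N * 8), N, 8)
    skip1 <- runif(N) < 0.3
    skip2 <- runif(N) < 0.4
    vals[skip1, 1:4] <- NA
    vals[skip2, 5:8] <- NA
    pheno_matrix(vals, sprintf("b%04d", seq_len(N)), sch)
  })
}

# Small trained model on low-rank synthetic data, shared by slow tests.
small_fit_setup <- function(seed = 11) {
  syn <- generate_phenotypes(synth_config(N = 1200, P_cont = 12, P_bin = 4,
                                          k = 2, seed = seed))
  sp <- split_individuals(syn$masked, test_fraction = 0.4,
                          validation_fraction = 0, seed = seed)
  fit <- phenocomplete(sp$train, epochs = 60, batch_size = 256,
                       learning_rate = 0.05, seed = seed)
  list(syn = syn, split = sp, fit = fit)
}
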