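zeroed_params <- function(spec) {
  p <- init_params(spec, seed = 1)
  for (l in seq_along(p)) {
    p[[l]]$W[] <- 0
    p[[l]]$b[] <- 0
  }
  p
}

test_that("all-zero parameters give 0 for continuous and 0.5 for binary outputs", {
  spec <- model_spec(P = 5, C = 3)
  y <- autoencoder_forward(rnorm(5), zeroed_params(spec), spec)
  expect_equal(y[1:3], rep(0, 3))
  expect_equal(y[4:5], rep(0.5, 2))
})

test_that("forward pass matches a hand-computed trace on a 2-feature net", {
  spec <- model_spec(P = 2, C = 1, hidden = 1, leaky_slope = 0.01)
  p <- zeroed_params(spec)
  p[[1]]$W <- matrix(c(0.5, -0.3), 1, 2)
  p[[1]]$b <- 0.1
  p[[2]]$W <- matrix(c(1.2, -0.7), 2, 1)
  p[[2]]$b <- c(0.05, -0.2)
  x <- c(2, 1)
  # manual arithmetic: affine -> leaky rectifier -> affine -> (identity, sigmoid)
  z1 <- 0.5 * 2 + (-0.3) * 1 + 0.1            # 0.8, positive
  a1 <- z1
  o1 <- 1.2 * a1 + 0.05
  o2 <- -0.7 * a1 - 0.2
  expect_equal(autoencoder_forward(x, p, spec),
               c(o1, 1 / (1 + exp(-o2))))
  # negative pre-activation engages the slope
  x2 <- c(-2, 1)
  z1n <- 0.5 * -2 - 0.3 * 1 + 0.1             # -1.2, negative
  a1n <- 0.01 * z1n
  expect_equal(autoencoder_forward(x2, p, spec)[1], 1.2 * a1n + 0.05)
})

test_that("the printed rectifier variant maps negatives to positive values", {
  spec_std <- model_spec(P = 2, C = 2, hidden = 1, phi_variant = "standard")
  spec_prt <- model_spec(P = 2, C = 2, hidden = 1, phi_variant = "printed")
  expect_equal(phenocomplete:::phi_fun(-3, spec_std), -0.03)
  expect_equal(phenocomplete:::phi_fun(-3, spec_prt), 0.03)
  expect_equal(phenocomplete:::phi_fun(2, spec_std), 2)
  expect_equal(phenocomplete:::phi_fun(2, spec_prt), 2)
})

test_that("binary outputs lie strictly inside (0,1) for finite parameters", {
  spec <- model_spec(P = 4, C = 2, hidden = 3)
  for (s in 1:5) {
    y <- autoencoder_forward(matrix(rnorm(40, sd = 3), 10, 4),
                             init_params(spec, s), spec)
    expect_true(all(y[, 3:4] > 0 & y[, 3:4] < 1))
  }
})

test_that("joint loss matches a cell-by-cell hand sum on a 3x4 toy matrix", {
  spec <- model_spec(P = 4, C = 2, hidden = 2)
  y <- matrix(c(0.5, 1.0, 0.8, 0.3,
                -0.2, 0.4, 0.6, 0.9,
                1.5, -1.0, 0.2, 0.5), 3, 4, byrow = TRUE)
  t <- matrix(c(0.7, 1.2, 1, 0,
                0.0, 0.4, 0, 1,
                2.0, -0.5, 1, 1), 3, 4, byrow = TRUE)
  M <- matrix(1L, 3, 4)
  M[1, 2] <- 0L  # two masked cells
  M[3, 3] <- 0L
  # independent oracle: explicit loop over cells
  expected <- 0
  for (i in 1:3) for (j in 1:4) {
    if (M[i, j] == 0) next
    expected <- expected + if (j <= 2) (y[i, j] - t[i, j])^2 else
      -(t[i, j] * log(y[i, j]) + (1 - t[i, j]) * log(1 - y[i, j]))
  }
  expect_equal(joint_loss(y, t, M, spec), expected)
})

test_that("canonical loss values: perfect continuous 0, binary 0.5 vs 1 gives log 2", {
  spec <- model_spec(P = 1, C = 1, hidden = 1)
  expect_equal(joint_loss(matrix(3.7), matrix(3.7), matrix(1L), spec), 0)
  spec_b <- model_spec(P = 1, C = 0, hidden = 1)
  expect_equal(joint_loss(matrix(0.5), matrix(1), matrix(1L), spec_b), log(2))
  expect_error(joint_loss(matrix(1.2), matrix(1), matrix(1L), spec_b),
               "inside")
  expect_error(joint_loss(matrix(0.5), matrix(0.3), matrix(1L), spec_b),
               "targets")
})

test_that("analytic gradients match central finite differences", {
  spec <- model_spec(P = 4, C = 2, hidden = 3, leaky_slope = 0.01)
  params <- init_params(spec, seed = 2)
  X <- withr::with_seed(3, matrix(rnorm(24), 6, 4))
  Tg <- withr::with_seed(4, cbind(matrix(rnorm(12), 6, 2),
                                  matrix(rbinom(12, 1, 0.5), 6, 2)))
  M <- withr::with_seed(5, matrix(rbinom(24, 1, 0.8), 6, 4))
  loss_at <- function(p) {
    phenocomplete:::joint_loss_logits(
      phenocomplete:::forward_full(X, p, spec)$output, Tg, M, spec) / nrow(X)
  }
  fw <- phenocomplete:::forward_full(X, params, spec)
  gr <- phenocomplete:::backward_full(fw, params, spec, Tg, M)
  h <- 1e-6
  for (l in seq_along(params)) {
    for (idx in seq_len(min(5, length(params[[l]]$W)))) {
      pp <- params; pm <- params
      pp[[l]]$W[idx] <- pp[[l]]$W[idx] + h
      pm[[l]]$W[idx] <- pm[[l]]$W[idx] - h
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(gr[[l]]$W[idx], fd, tolerance = 1e-4)
    }
    pp <- params; pm <- params
    pp[[l]]$b[1] <- pp[[l]]$b[1] + h
    pm[[l]]$b[1] <- pm[[l]]$b[1] - h
    fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
    expect_equal(gr[[l]]$b[1], fd, tolerance = 1e-4)
  }
})

test_that("zero-epoch training returns initialized parameters and an empty log", {
  d <- random_matrix(40, 4, 2, miss = 0.1, seed = 6)
  fit <- phenocomplete(d, epochs = 0, seed = 9)
  expect_equal(nrow(fit$log), 0L)
  expect_equal(fit$best_epoch, 0L)
  spec <- fit$spec
  expect_equal(fit$params, unclass(init_params(spec, 9)),
               ignore_attr = TRUE)
})

test_that("training is deterministic under a fixed seed", {
  d <- random_matrix(150, 5, 2, miss = 0.2, seed = 7)
  f1 <- phenocomplete(d, epochs = 8, batch_size = 64, seed = 31)
  f2 <- phenocomplete(d, epochs = 8, batch_size = 64, seed = 31)
  expect_identical(f1$log, f2$log)
  expect_equal(f1$params, f2$params)
  f3 <- phenocomplete(d, epochs = 8, batch_size = 64, seed = 32)
  expect_false(identical(f3$log$train_loss, f1$log$train_loss))
})

test_that("returned parameters reproduce the logged best validation loss", {
  d <- random_matrix(200, 6, 2, miss = 0.2, seed = 8)
  fit <- phenocomplete(d, epochs = 15, batch_size = 64, seed = 5)
  expect_equal(phenocomplete:::validation_loss(fit), fit$best_val_loss)
  expect_equal(fit$best_val_loss, min(fit$log$val_loss))
  expect_true(fit$log$checkpointed[fit$log$epoch == fit$best_epoch])
})

test_that("training on correlated data reduces the validation loss", {
  syn <- generate_phenotypes(synth_config(N = 2000, P_cont = 16, P_bin = 4,
                                          k = 2, seed = 13))
  fit <- phenocomplete(syn$masked, epochs = 40, batch_size = 256,
                       learning_rate = 0.05, seed = 13)
  expect_lt(fit$best_val_loss, fit$log$val_loss[1])
})

test_that("impute passes observed cells through exactly and fills missing ones", {
  s <- small_fit_setup()
  d <- s$split$test
  imp <- predict(s$fit, d)
  obs <- d$mask == 1L
  expect_identical(imp$values[obs], d$values[obs])
  expect_true(all(is.finite(imp$values)))
  bin <- which(d$schema$kind == "binary")
  miss_bin <- imp$values[, bin][d$mask[, bin] == 0L]
  expect_true(all(miss_bin >= 0 & miss_bin <= 1))
})

test_that("a fully missing row is imputed as the forward pass of zeros", {
  s <- small_fit_setup()
  d <- s$split$test
  empty <- pheno_matrix(matrix(NA_real_, 1, ncol(d$values)), "ghost",
                        d$schema)
  imp <- impute_matrix(empty, s$fit)
  y0 <- autoencoder_forward(rep(0, s$fit$spec$P), s$fit$params, s$fit$spec)
  st <- s$fit$normalization
  cont <- !is.na(st$scale)
  expect_equal(unname(imp$values[1, cont]),
               y0[cont] * st$scale[cont] + st$center[cont])
  expect_equal(unname(imp$values[1, !cont]), y0[!cont])
})

test_that("checkpoints round-trip through JSON and impute identically", {
  s <- small_fit_setup()
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(s$fit, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, s$fit$params, ignore_attr = TRUE)
  expect_equal(back$normalization$center, s$fit$normalization$center)
  i1 <- impute_matrix(s$split$test, s$fit)
  i2 <- impute_matrix(s$split$test, back)
  expect_equal(i1$values, i2$values)
})

test_that("model methods expose the usual surface", {
  s <- small_fit_setup()
  fit <- s$fit
  expect_output(print(fit), "autoencoder")
  expect_output(print(summary(fit)), "parameters")
  cf <- coef(fit)
  expect_named(cf, paste0("layer", seq_along(cf)))
  res <- residuals(fit)
  expect_equal(dim(res), dim(fit$data$values))
  expect_true(all(is.na(res[fit$data$mask == 0L])))
  rec <- fitted(fit)
  obs <- fit$data$mask == 1L
  expect_equal(res[obs], (fit$data$values - rec)[obs])
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
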