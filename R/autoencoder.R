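#' Autoencoder architecture specification
#'
#' Defines the feed-forward encoder-decoder: input width P, hidden widths, the
#' leaky-rectifier slope, and the index partition `C` separating continuous
#' from binary outputs (outputs `1..C` are returned raw, outputs `C+1..P` pass
#' through a sigmoid and lie in (0,1)). The default architecture uses two
#' hidden layers of widths `ceiling(1.5 P)` and `ceiling(0.7 P)` before the
#' width-P output layer (three weight layers in total).
#'
#' The conventional leaky rectifier `max(0,x) + slope*min(0,x)` is the default
#' nonlinearity; `phi_variant = "printed"` selects the sign-flipped variant
#' `max(0,x) - slope*min(0,x)`, which maps negative inputs to small positive
#' values.
#'
#' @param P input width (number of phenotypes).
#' @param C number of columns treated as continuous (ordinal counts as
#'   continuous); the remaining `P - C` outputs are binary.
#' @param hidden integer vector of hidden-layer widths; `NULL` for the default.
#' @param leaky_slope slope of the rectifier on the negative side, in (0,1);
#'   fixed (not learned).
#' @param phi_variant `"standard"` or `"printed"` (see Details).
#' @return An object of class `ac_model_spec`.
#' @export
model_spec <- function(P, C, hidden = NULL, leaky_slope = 0.01,
                       phi_variant = c("standard", "printed")) {
  phi_variant <- match.arg(phi_variant)
  if (is.null(hidden)) hidden <- c(ceiling(1.5 * P), ceiling(0.7 * P))
  hidden <- as.integer(hidden)
  if (any(hidden <= 0L)) stop_pc("hidden widths must be positive")
  if (P < 1L || C < 0L || C > P) stop_pc("need 0 <= C <= P, P >= 1")
  if (leaky_slope <= 0 || leaky_slope >= 1) {
    stop_pc("leaky_slope must be in (0, 1)")
  }
  structure(list(P = as.integer(P), C = as.integer(C),
                 widths = c(as.integer(P), hidden, as.integer(P)),
                 leaky_slope = leaky_slope, phi_variant = phi_variant),
            class = "ac_model_spec")
}

spec_for_schema <- function(schema, ...) {
  model_spec(P = nrow(schema), C = schema_C(schema), ...)
}

phi_fun <- function(z, spec) {
  s <- if (spec$phi_variant == "standard") spec$leaky_slope else -spec$leaky_slope
  ifelse(z > 0, z, s * z)
}

phi_grad <- function(z, spec) {
  s <- if (spec$phi_variant == "standard") spec$leaky_slope else -spec$leaky_slope
  ifelse(z > 0, 1, s)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize model parameters
#'
#' Weights are drawn from the Kaiming uniform distribution with the gain for
#' a leaky rectifier, `U(-b, b)` with `b = sqrt(2/(1+slope^2)) * sqrt(3/fan_in)`;
#' biases from `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`.
#'
#' @param spec an [model_spec()].
#' @param seed integer seed.
#' @return An object of class `ac_model_params`: per layer, weight matrix `W`
#'   (rows = output units) and bias vector `b`.
#' @export
init_params <- function(spec, seed = 1) {
  L <- length(spec$widths) - 1L
  gain <- sqrt(2 / (1 + spec$leaky_slope^2))
  with_seed(derive_seed(seed, 5L), {
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- spec$widths[l]
      fan_out <- spec$widths[l + 1L]
      wb <- gain * sqrt(3 / fan_in)
      bb <- 1 / sqrt(fan_in)
      layers[[l]] <- list(
        W = matrix(stats::runif(fan_out * fan_in, -wb, wb), fan_out, fan_in),
        b = stats::runif(fan_out, -bb, bb))
    }
    structure(layers, class = "ac_model_params")
  })
}

n_parameters <- function(params) {
  sum(vapply(params, function(l) length(l$W) + length(l$b), numeric(1)))
}

# Full forward pass keeping intermediates for backprop.
# X: n x P matrix of encoded, zero-filled inputs.
forward_full <- function(X, params, spec) {
  L <- length(params)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% t(params[[l]]$W), 2L, params[[l]]$b, "+")
    A[[l + 1L]] <- if (l < L) phi_fun(Z[[l]], spec) else Z[[l]]
  }
  O <- A[[L + 1L]]
  if (!all(is.finite(O))) stop_pc("non-finite activations in forward pass")
  Y <- O
  if (spec$C < spec$P) {
    bin <- (spec$C + 1L):spec$P
    Y[, bin] <- sigmoid(O[, bin, drop = FALSE])
  }
  list(A = A, Z = Z, output = O, Y = Y)
}

#' Forward pass of the autoencoder
#'
#' Maps encoded input rows (normalized, zero-filled at missing positions)
#' through the network. Hidden layers apply an affine map followed by the
#' leaky rectifier; the output layer is affine, with a sigmoid applied to the
#' binary positions `C+1..P` so those entries lie in (0,1).
#'
#' @param x a length-P vector or n x P matrix of encoded inputs.
#' @param params an `ac_model_params` from [init_params()] or a fit.
#' @param spec the matching [model_spec()].
#' @return Reconstruction(s) with the same shape as `x`: continuous positions
#'   on the normalized scale, binary positions as probabilities.
#' @export
autoencoder_forward <- function(x, params, spec) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != spec$P) stop_pc("input width ", ncol(X), " != P = ", spec$P)
  Y <- forward_full(X, params, spec)$Y
  if (vec) drop(Y) else Y
}

#' Joint reconstruction loss
#'
#' Sums, over all originally observed cells, the squared error for continuous
#' positions and the cross-entropy `-(t log y + (1-t) log(1-y))` for binary
#' positions. Cells hidden from the input by copy-masking still contribute
#' whenever they were originally observed: that is the denoising objective.
#'
#' @param y n x P reconstruction (binary positions as probabilities in (0,1)).
#' @param targets n x P target matrix on the loss scale: normalized values for
#'   continuous positions, 0/1 for binary positions (`NA` allowed where
#'   unobserved).
#' @param observed_mask n x P indicator of originally observed cells.
#' @param spec the [model_spec()].
#' @return The scalar loss (a sum, not an average).
#' @export
joint_loss <- function(y, targets, observed_mask, spec) {
  y <- as.matrix(y); targets <- as.matrix(targets)
  M <- matrix(as.numeric(observed_mask), nrow(y), ncol(y))
  loss <- 0
  if (spec$C > 0L) {
    jj <- seq_len(spec$C)
    d <- (y[, jj, drop = FALSE] - targets[, jj, drop = FALSE])
    d[M[, jj, drop = FALSE] == 0] <- 0
    loss <- loss + sum(d^2)
  }
  if (spec$C < spec$P) {
    jj <- (spec$C + 1L):spec$P
    yb <- y[, jj, drop = FALSE]
    tb <- targets[, jj, drop = FALSE]
    mb <- M[, jj, drop = FALSE]
    if (any(mb == 1 & (yb <= 0 | yb >= 1))) {
      stop_pc("binary predictions must lie strictly inside (0, 1)")
    }
    if (any(mb == 1 & !(tb %in% c(0, 1)))) {
      stop_pc("binary targets must be 0 or 1 at observed cells")
    }
    ce <- -(tb * log(yb) + (1 - tb) * log(1 - yb))
    ce[mb == 0] <- 0
    loss <- loss + sum(ce)
  }
  loss
}

# Numerically stable variant computed from pre-sigmoid outputs O:
# cross-entropy for t in {0,1} is softplus(z) - t*z, which never overflows
# where sigmoid(z) would round to 0 or 1. Agrees with joint_loss away from
# saturation; used for the training and checkpointing path.
joint_loss_logits <- function(O, targets, observed_mask, spec) {
  M <- matrix(as.numeric(observed_mask), nrow(O), ncol(O))
  loss <- 0
  if (spec$C > 0L) {
    jj <- seq_len(spec$C)
    d <- O[, jj, drop = FALSE] - targets[, jj, drop = FALSE]
    d[M[, jj, drop = FALSE] == 0] <- 0
    loss <- loss + sum(d^2)
  }
  if (spec$C < spec$P) {
    jj <- (spec$C + 1L):spec$P
    z <- O[, jj, drop = FALSE]
    tb <- targets[, jj, drop = FALSE]
    ce <- pmax(z, 0) + log1p(exp(-abs(z))) - tb * z
    ce[M[, jj, drop = FALSE] == 0] <- 0
    loss <- loss + sum(ce)
  }
  loss
}

# Gradient of joint_loss w.r.t. all weights and biases for one batch.
# Returns gradients scaled by 1/nrow(X) (loss itself is a sum).
backward_full <- function(fw, params, spec, targets, M) {
  L <- length(params)
  n <- nrow(fw$output)
  G <- fw$output * 0
  if (spec$C > 0L) {
    jj <- seq_len(spec$C)
    d <- 2 * (fw$output[, jj, drop = FALSE] - targets[, jj, drop = FALSE])
    d[M[, jj, drop = FALSE] == 0] <- 0
    G[, jj] <- d
  }
  if (spec$C < spec$P) {
    jj <- (spec$C + 1L):spec$P
    d <- fw$Y[, jj, drop = FALSE] - targets[, jj, drop = FALSE]
    d[M[, jj, drop = FALSE] == 0] <- 0
    G[, jj] <- d
  }
  grads <- vector("list", L)
  delta <- G
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(delta, fw$A[[l]]) / n,
                       b = colSums(delta) / n)
    if (l > 1L) {
      delta <- (delta %*% params[[l]]$W) * phi_grad(fw$Z[[l - 1L]], spec)
    }
  }
  grads
}

# Encode a value matrix for the network input: continuous columns normalized,
# binary columns recoded 0/1 -> -0.5/+0.5, everything hidden by `input_mask`
# set to 0 (the neutral point).
encode_input <- function(values, input_mask, stats, schema) {
  X <- values
  bin <- schema_is_binary(schema)
  for (j in seq_len(ncol(X))) {
    if (bin[j]) {
      X[, j] <- X[, j] - 0.5
    } else {
      X[, j] <- (X[, j] - stats$center[j]) / stats$scale[j]
    }
  }
  X[input_mask == 0L] <- 0
  X[is.na(X)] <- 0
  X
}

# Loss-scale targets: normalized continuous values, raw 0/1 binary values,
# 0 placeholder where unobserved (masked out of the loss anyway).
encode_targets <- function(values, mask, stats, schema) {
  T <- values
  bin <- schema_is_binary(schema)
  for (j in seq_len(ncol(T))) {
    if (!bin[j]) T[, j] <- (T[, j] - stats$center[j]) / stats$scale[j]
  }
  T[mask == 0L] <- 0
  T[is.na(T)] <- 0
  T
}

#' Training configuration
#'
#' Defaults follow the tuned large-biobank settings: learning rate 0.1 with a
#' decay scheduler, momentum 0.9, batches of 2,048 rows, up to 500 epochs,
#' copy-mask probability `rho = 0.8`, and a 20% validation split used only for
#' checkpointing. The scheduler halves the learning rate after `lr_patience`
#' epochs without validation improvement; early stopping is off by default.
#'
#' @param learning_rate initial SGD step size (> 0).
#' @param momentum SGD momentum coefficient.
#' @param batch_size rows per mini-batch (>= 1); the final short batch is used.
#' @param max_epochs maximum training epochs (>= 0).
#' @param rho probability a row receives a mask augmentation each epoch.
#' @param validation_fraction fraction of training rows held out for
#'   checkpointing.
#' @param mask_mode `"copy"` (patterns drawn from the training mask rows) or
#'   `"uniform"` (cells hidden i.i.d. at the pattern source's mean missingness
#'   rate) — the ablation comparator.
#' @param lr_patience epochs without validation improvement before the
#'   learning rate is multiplied by `lr_factor`.
#' @param lr_factor learning-rate decay multiplier.
#' @param early_stop_patience stop after this many stagnant epochs
#'   (`Inf` = train to `max_epochs`, the default).
#' @param seed master seed controlling initialization, shuffling, masking and
#'   the validation split.
#' @return An object of class `ac_train_config`.
#' @export
train_config <- function(learning_rate = 0.1, momentum = 0.9,
                         batch_size = 2048, max_epochs = 500, rho = 0.8,
                         validation_fraction = 0.2,
                         mask_mode = c("copy", "uniform"),
                         lr_patience = 10, lr_factor = 0.5,
                         early_stop_patience = Inf, seed = 1) {
  mask_mode <- match.arg(mask_mode)
  if (learning_rate <= 0) stop_pc("learning_rate must be positive")
  if (batch_size < 1) stop_pc("batch_size must be >= 1")
  if (max_epochs < 0) stop_pc("max_epochs must be >= 0")
  if (rho < 0 || rho > 1) stop_pc("rho must be in [0, 1]")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), rho = rho,
                 validation_fraction = validation_fraction,
                 mask_mode = mask_mode, lr_patience = lr_patience,
                 lr_factor = lr_factor,
                 early_stop_patience = early_stop_patience,
                 seed = as.integer(seed)),
            class = "ac_train_config")
}

# One mask-augmentation draw for a set of rows. Returns the effective input
# mask (original mask AND the drawn pattern for selected rows). Caller owns
# the RNG state.
draw_augmentation <- function(mask, pattern_source, rho, mode) {
  n <- nrow(mask)
  aug <- mask
  sel <- stats::runif(n) < rho
  if (any(sel)) {
    if (mode == "copy") {
      idx <- sample.int(nrow(pattern_source), sum(sel), replace = TRUE)
      aug[sel, ] <- mask[sel, , drop = FALSE] *
        pattern_source[idx, , drop = FALSE]
    } else {
      q <- 1 - mean(pattern_source)  # match copy-masking intensity
      keep <- matrix(stats::runif(sum(sel) * ncol(mask)) >= q,
                     sum(sel), ncol(mask))
      aug[sel, ] <- mask[sel, , drop = FALSE] * keep
    }
  }
  aug
}

#' Fit the denoising autoencoder
#'
#' Carves a validation split from the training rows, standardizes the
#' continuous phenotypes on the remaining rows, initializes the network with
#' Kaiming-uniform draws, and trains by stochastic gradient descent with
#' momentum. Each epoch shuffles the rows and, with probability `rho` per
#' row, hides additional observed entries using a copy-mask drawn from the
#' training split's own missingness patterns; the loss is still taken over
#' all originally observed cells, so the network learns to reconstruct what
#' was hidden. After every epoch the joint loss is evaluated on the
#' validation rows under a fixed, seed-frozen copy-mask, and the parameters
#' attaining the best validation loss are checkpointed and returned.
#'
#' Most users should call [phenocomplete()], which wraps this and returns a
#' full model object with methods.
#'
#' @param train a [pheno_matrix()] of training individuals (raw scale).
#' @param config an [train_config()].
#' @param spec an [model_spec()]; defaults to the architecture derived from
#'   the schema.
#' @return A list with elements `params` (best checkpoint), `log` (per-epoch
#'   data frame), `normalization`, `spec`, `config`, `best_epoch`,
#'   `best_val_loss`, and the frozen validation tensors (`val_input`,
#'   `val_targets`, `val_mask`) used for checkpointing.
#' @export
fit_autoencoder <- function(train, config = train_config(), spec = NULL) {
  schema <- train$schema
  if (is.null(spec)) spec <- spec_for_schema(schema)
  if (spec$P != nrow(schema) || spec$C != schema_C(schema)) {
    stop_pc("model spec does not match the data schema")
  }
  N <- nrow(train$values)
  if (!N) stop_pc("training data has no rows")

  n_val <- round(N * config$validation_fraction)
  val_idx <- if (n_val > 0) {
    with_seed(derive_seed(config$seed, 6L), sort(sample.int(N, n_val)))
  } else integer(0)
  fit_idx <- setdiff(seq_len(N), val_idx)
  if (!length(fit_idx)) stop_pc("validation split leaves no training rows")

  fit_rows <- subset_rows(train, fit_idx)
  stats <- fit_normalization(fit_rows)

  pattern_source <- fit_rows$mask
  E <- encode_input(fit_rows$values, fit_rows$mask, stats, schema)
  Tg <- encode_targets(fit_rows$values, fit_rows$mask, stats, schema)
  M <- fit_rows$mask

  # frozen validation objective: one copy-mask draw, reused every epoch
  have_val <- length(val_idx) > 0
  if (have_val) {
    val_rows <- subset_rows(train, val_idx)
    val_aug <- with_seed(derive_seed(config$seed, 7L),
                         draw_augmentation(val_rows$mask, pattern_source,
                                           config$rho, config$mask_mode))
    val_input <- encode_input(val_rows$values, val_aug, stats, schema)
    val_targets <- encode_targets(val_rows$values, val_rows$mask, stats, schema)
    val_mask <- val_rows$mask
  } else {
    val_input <- val_targets <- val_mask <- NULL
  }

  params <- init_params(spec, config$seed)
  best <- params
  best_val <- Inf
  best_epoch <- 0L
  L <- length(params)
  vel <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  lr <- config$learning_rate
  stagnant <- 0L
  log_rows <- vector("list", config$max_epochs)

  n_fit <- nrow(E)
  if (config$max_epochs > 0) {
    with_seed(derive_seed(config$seed, 8L), {
      for (epoch in seq_len(config$max_epochs)) {
        ord <- sample.int(n_fit)
        aug <- draw_augmentation(M[ord, , drop = FALSE], pattern_source,
                                 config$rho, config$mask_mode)
        Xin <- E[ord, , drop = FALSE] * aug
        Tgt <- Tg[ord, , drop = FALSE]
        Mo <- M[ord, , drop = FALSE]
        epoch_loss <- 0
        starts <- seq(1L, n_fit, by = config$batch_size)
        for (s in starts) {
          e <- min(s + config$batch_size - 1L, n_fit)
          bi <- s:e
          fw <- forward_full(Xin[bi, , drop = FALSE], params, spec)
          bl <- joint_loss_logits(fw$output, Tgt[bi, , drop = FALSE],
                                  Mo[bi, , drop = FALSE], spec)
          if (!is.finite(bl)) {
            stop_pc("training diverged at epoch ", epoch,
                    " (non-finite loss; last epoch loss ",
                    signif(epoch_loss, 6), ")")
          }
          epoch_loss <- epoch_loss + bl
          gr <- backward_full(fw, params, spec, Tgt[bi, , drop = FALSE],
                              Mo[bi, , drop = FALSE])
          for (l in seq_len(L)) {
            vel[[l]]$W <- config$momentum * vel[[l]]$W - lr * gr[[l]]$W
            vel[[l]]$b <- config$momentum * vel[[l]]$b - lr * gr[[l]]$b
            params[[l]]$W <- params[[l]]$W + vel[[l]]$W
            params[[l]]$b <- params[[l]]$b + vel[[l]]$b
          }
        }
        val_loss <- if (have_val) {
          joint_loss_logits(forward_full(val_input, params, spec)$output,
                            val_targets, val_mask, spec)
        } else epoch_loss
        improved <- val_loss < best_val
        if (improved) {
          best_val <- val_loss
          best <- params
          best_epoch <- epoch
          stagnant <- 0L
        } else {
          stagnant <- stagnant + 1L
          if (stagnant %% config$lr_patience == 0L) lr <- lr * config$lr_factor
        }
        log_rows[[epoch]] <- data.frame(
          epoch = epoch, train_loss = epoch_loss, val_loss = val_loss,
          lr = lr, checkpointed = improved)
        if (stagnant >= config$early_stop_patience) break
      }
    })
  }
  log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  if (is.null(log)) {
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0), lr = numeric(0),
                      checkpointed = logical(0))
  }
  list(params = best, log = log, normalization = stats, spec = spec,
       config = config, best_epoch = best_epoch,
       best_val_loss = if (is.finite(best_val)) best_val else NA_real_,
       val_input = val_input, val_targets = val_targets, val_mask = val_mask)
}

#' Impute a phenotype matrix with a fitted model
#'
#' Composes the final completed matrix: observed cells are copied verbatim
#' from the input (exact passthrough), missing cells are filled with the
#' network reconstruction — continuous phenotypes returned on their original
#' scale, binary phenotypes as probabilities in \[0,1\].
#'
#' @param data a [pheno_matrix()] to complete.
#' @param model a fit from [fit_autoencoder()] or a [phenocomplete()] object.
#' @return An object of class `imputed_pheno`: `values` (complete N x P
#'   matrix), `ids`, `schema`, and `observed_mask` marking which cells are
#'   original data versus imputations.
#' @export
impute_matrix <- function(data, model) {
  spec <- model$spec
  stats <- model$normalization
  schema <- data$schema
  if (!identical(stats$names, schema$name)) {
    stop_pc("model was fitted on a different schema")
  }
  X <- encode_input(data$values, data$mask, stats, schema)
  Y <- forward_full(X, model$params, spec)$Y
  # back to the original scale
  filled <- Y
  bin <- schema_is_binary(schema)
  for (j in seq_len(ncol(filled))) {
    if (!bin[j]) filled[, j] <- filled[, j] * stats$scale[j] + stats$center[j]
  }
  out <- filled
  obs <- data$mask == 1L
  out[obs] <- data$values[obs]
  dimnames(out) <- dimnames(data$values)
  structure(list(values = out, ids = data$ids, schema = schema,
                 observed_mask = data$mask),
            class = "imputed_pheno")
}

#' @export
print.imputed_pheno <- function(x, ...) {
  cat(sprintf(
    "Imputed phenotype matrix: %d x %d (%d cells imputed, %.1f%%)\n",
    nrow(x$values), ncol(x$values), sum(x$observed_mask == 0L),
    100 * mean(x$observed_mask == 0L)))
  invisible(x)
}

# Re-evaluate the checkpointed validation loss for a fit (checkpoint contract).
validation_loss <- function(model) {
  if (is.null(model$val_input)) return(NA_real_)
  joint_loss_logits(
    forward_full(model$val_input, model$params, model$spec)$output,
    model$val_targets, model$val_mask, model$spec)
}
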