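#' Fit a phenotype-imputation autoencoder
#'
#' The main entry point of the package. Fits a mixed-type denoising
#' autoencoder to a masked phenotype matrix: continuous phenotypes are
#' reconstructed under squared error, binary phenotypes under cross-entropy
#' through a sigmoid output, and training hides observed entries by
#' copy-masking — applying missingness patterns sampled from other
#' individuals — so the network learns to impute under the structured
#' missingness it will face. See [fit_autoencoder()] for the training
#' procedure and [train_config()] for tuning parameters.
#'
#' @param data a [pheno_matrix()] of training individuals, e.g. from
#'   [read_phenotype_table()] or [generate_phenotypes()].
#' @param hidden hidden-layer widths (`NULL` = `ceiling(1.5P)`, `ceiling(0.7P)`).
#' @param rho copy-mask probability per row per epoch (tuned values in the
#'   source application: 0.8 for a sparse psychiatric collection, 0.3 for a
#'   denser cardiometabolic one).
#' @param learning_rate,momentum,batch_size,epochs,validation_fraction,
#'   mask_mode,lr_patience,lr_factor,early_stop_patience,seed
#'   see [train_config()].
#' @param leaky_slope,phi_variant see [model_spec()].
#' @param keep_data keep the training data inside the object (needed by
#'   [residuals.phenocomplete()] and [simulate.phenocomplete()] without an
#'   explicit `data` argument).
#' @return An object of class `phenocomplete` with components `params`,
#'   `spec`, `normalization`, `log`, `config`, `schema`, `best_epoch`,
#'   `best_val_loss` and (optionally) `data`.
#' @examples
#' syn <- generate_phenotypes(synth_config(N = 400, P_cont = 6, P_bin = 2,
#'                                         seed = 7))
#' fit <- phenocomplete(syn$masked, epochs = 5, batch_size = 128, seed = 7)
#' print(fit)
#' completed <- predict(fit, syn$masked)
#' @export
phenocomplete <- function(data, hidden = NULL, rho = 0.8,
                          learning_rate = 0.1, momentum = 0.9,
                          batch_size = 2048, epochs = 500,
                          validation_fraction = 0.2,
                          mask_mode = c("copy", "uniform"),
                          leaky_slope = 0.01,
                          phi_variant = c("standard", "printed"),
                          lr_patience = 10, lr_factor = 0.5,
                          early_stop_patience = Inf, seed = 1,
                          keep_data = TRUE) {
  if (!inherits(data, "pheno_matrix")) {
    stop_pc("`data` must be a pheno_matrix (see read_phenotype_table)")
  }
  mask_mode <- match.arg(mask_mode)
  phi_variant <- match.arg(phi_variant)
  spec <- spec_for_schema(data$schema, hidden = hidden,
                          leaky_slope = leaky_slope,
                          phi_variant = phi_variant)
  config <- train_config(learning_rate = learning_rate, momentum = momentum,
                         batch_size = batch_size, max_epochs = epochs,
                         rho = rho,
                         validation_fraction = validation_fraction,
                         mask_mode = mask_mode, lr_patience = lr_patience,
                         lr_factor = lr_factor,
                         early_stop_patience = early_stop_patience,
                         seed = seed)
  fit <- fit_autoencoder(data, config, spec)
  fit$schema <- data$schema
  fit$call <- match.call()
  if (keep_data) fit$data <- data
  class(fit) <- "phenocomplete"
  fit
}

#' @export
print.phenocomplete <- function(x, ...) {
  cat("Copy-masked denoising autoencoder for phenotype imputation\n")
  cat(sprintf("  architecture: %s (leaky slope %.3g, %s rectifier)\n",
              paste(x$spec$widths, collapse = " -> "),
              x$spec$leaky_slope, x$spec$phi_variant))
  cat(sprintf("  phenotypes:   %d continuous-like + %d binary\n",
              x$spec$C, x$spec$P - x$spec$C))
  cat(sprintf("  training:     %d epochs run, mask mode '%s' (rho = %.2f)\n",
              nrow(x$log), x$config$mask_mode, x$config$rho))
  if (!is.na(x$best_val_loss)) {
    cat(sprintf("  checkpoint:   epoch %d, validation loss %.4f\n",
                x$best_epoch, x$best_val_loss))
  }
  invisible(x)
}

#' @export
summary.phenocomplete <- function(object, ...) {
  out <- list(
    widths = object$spec$widths,
    n_parameters = n_parameters(object$params),
    epochs_run = nrow(object$log),
    best_epoch = object$best_epoch,
    best_val_loss = object$best_val_loss,
    final_train_loss = if (nrow(object$log)) {
      object$log$train_loss[nrow(object$log)]
    } else NA_real_,
    config = object$config,
    schema = object$schema)
  class(out) <- "summary.phenocomplete"
  out
}

#' @export
print.summary.phenocomplete <- function(x, ...) {
  cat("Fitted phenotype-imputation autoencoder\n")
  cat(sprintf("  layers %s  (%d parameters)\n",
              paste(x$widths, collapse = " -> "), x$n_parameters))
  cat(sprintf("  %d epochs run; checkpoint at epoch %d (val loss %.4f)\n",
              x$epochs_run, x$best_epoch, x$best_val_loss))
  cat(sprintf("  final training loss %.4f\n", x$final_train_loss))
  cat(sprintf("  config: lr %.3g, momentum %.2f, batch %d, rho %.2f, mask '%s'\n",
              x$config$learning_rate, x$config$momentum,
              x$config$batch_size, x$config$rho, x$config$mask_mode))
  invisible(x)
}

#' @export
coef.phenocomplete <- function(object, ...) {
  out <- object$params
  names(out) <- paste0("layer", seq_along(out))
  unclass(out)
}

#' Impute phenotypes with a fitted model
#'
#' @param object a [phenocomplete()] fit.
#' @param newdata a [pheno_matrix()] to complete; defaults to the training
#'   data kept in the object.
#' @param type `"complete"` (observed cells verbatim, missing cells imputed;
#'   the final matrix) or `"reconstruction"` (the raw network output for
#'   every cell, on the original scale).
#' @param ... unused.
#' @return For `"complete"`, an `imputed_pheno` object (see
#'   [impute_matrix()]); for `"reconstruction"`, a numeric matrix.
#' @export
predict.phenocomplete <- function(object, newdata = NULL,
                                  type = c("complete", "reconstruction"),
                                  ...) {
  type <- match.arg(type)
  data <- newdata %||% object$data
  if (is.null(data)) stop_pc("no data: supply `newdata` or fit with keep_data")
  if (type == "complete") return(impute_matrix(data, object))
  X <- encode_input(data$values, data$mask, object$normalization, data$schema)
  Y <- forward_full(X, object$params, object$spec)$Y
  stats <- object$normalization
  for (j in seq_len(ncol(Y))) {
    if (!is.na(stats$scale[j])) {
      Y[, j] <- Y[, j] * stats$scale[j] + stats$center[j]
    }
  }
  dimnames(Y) <- dimnames(data$values)
  Y
}

#' @export
fitted.phenocomplete <- function(object, ...) {
  predict(object, type = "reconstruction")
}

#' Observed-cell reconstruction residuals
#'
#' Residuals (observed value minus network reconstruction, original scale)
#' at observed cells; `NA` elsewhere. For binary phenotypes the residual is
#' the 0/1 value minus the predicted probability.
#'
#' @param object a [phenocomplete()] fit.
#' @param newdata optional [pheno_matrix()]; defaults to the training data.
#' @param ... unused.
#' @return An N x P matrix.
#' @export
residuals.phenocomplete <- function(object, newdata = NULL, ...) {
  data <- newdata %||% object$data
  if (is.null(data)) stop_pc("no data: supply `newdata` or fit with keep_data")
  recon <- predict(object, data, type = "reconstruction")
  res <- data$values - recon
  res[data$mask == 0L] <- NA_real_
  res
}

#' Plot training and validation loss
#'
#' @param x a [phenocomplete()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.phenocomplete <- function(x, ...) {
  if (!nrow(x$log)) {
    warning("no epochs were run; nothing to plot")
    return(invisible(x))
  }
  graphics::matplot(x$log$epoch,
                    cbind(x$log$train_loss, x$log$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "joint loss (sum)", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Draw multiple imputations from a fitted-model configuration
#'
#' `simulate` on a `phenocomplete` object produces `nsim` bootstrap multiple
#' imputations: each replicate refits the model on individuals resampled with
#' replacement (with fresh initialization, shuffling and copy-mask draws) and
#' imputes the original data. See [multiple_impute()].
#'
#' @param object a [phenocomplete()] fit (its configuration is reused).
#' @param nsim number of imputations (default 10).
#' @param seed master seed for the replicates.
#' @param data the [pheno_matrix()] to impute; defaults to the training data.
#' @param ... unused.
#' @return An `imputation_set` (see [multiple_impute()]).
#' @export
simulate.phenocomplete <- function(object, nsim = 10, seed = 1,
                                   data = NULL, ...) {
  data <- data %||% object$data
  if (is.null(data)) stop_pc("no data: supply `data` or fit with keep_data")
  cfg <- object$config
  multiple_impute(data, m = nsim, seed = seed,
                  hidden = object$spec$widths[-c(1, length(object$spec$widths))],
                  rho = cfg$rho, learning_rate = cfg$learning_rate,
                  momentum = cfg$momentum, batch_size = cfg$batch_size,
                  epochs = cfg$max_epochs,
                  validation_fraction = cfg$validation_fraction,
                  mask_mode = cfg$mask_mode,
                  leaky_slope = object$spec$leaky_slope,
                  phi_variant = object$spec$phi_variant)
}

#' Save or load a fitted model as a text checkpoint
#'
#' The checkpoint is a single JSON file carrying the architecture, all
#' weights and biases, the normalization statistics, the training
#' configuration and a format version; adequate for the model sizes this
#' package targets and portable across platforms.
#'
#' @param object a [phenocomplete()] fit.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `phenocomplete` object (without training data).
#' @export
save_checkpoint <- function(object, path) {
  payload <- list(
    format = "phenocomplete-checkpoint",
    version = 1L,
    spec = object$spec[c("P", "C", "widths", "leaky_slope", "phi_variant")],
    params = lapply(object$params, function(l) {
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)
    }),
    normalization = object$normalization[c("center", "scale", "names",
                                           "kinds", "sd_estimator")],
    config = {
      cfg <- unclass(object$config)
      if (is.infinite(cfg$early_stop_patience)) cfg$early_stop_patience <- -1
      cfg
    },
    schema = list(name = object$schema$name, kind = object$schema$kind,
                  original_order = attr(object$schema, "original_order")),
    best_epoch = object$best_epoch,
    best_val_loss = object$best_val_loss)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "phenocomplete-checkpoint")) {
    stop_pc("not a phenocomplete checkpoint: ", path)
  }
  spec <- structure(list(P = as.integer(p$spec$P), C = as.integer(p$spec$C),
                         widths = as.integer(p$spec$widths),
                         leaky_slope = p$spec$leaky_slope,
                         phi_variant = p$spec$phi_variant),
                    class = "ac_model_spec")
  params <- if (is.data.frame(p$params)) {
    lapply(seq_len(nrow(p$params)), function(l) {
      list(W = matrix(p$params$W[[l]], p$params$dim[[l]][1],
                      p$params$dim[[l]][2]),
           b = as.numeric(p$params$b[[l]]))
    })
  } else {
    lapply(p$params, function(l) {
      list(W = matrix(as.numeric(l$W), l$dim[1], l$dim[2]),
           b = as.numeric(l$b))
    })
  }
  class(params) <- "ac_model_params"
  stats <- structure(list(center = as.numeric(p$normalization$center),
                          scale = as.numeric(p$normalization$scale),
                          names = p$normalization$names,
                          kinds = p$normalization$kinds,
                          binary_recoding = c(`0` = -0.5, `1` = 0.5),
                          sd_estimator = p$normalization$sd_estimator),
                     class = "pheno_normalization")
  schema <- pheno_schema(p$schema$name, p$schema$kind)
  attr(schema, "original_order") <- p$schema$original_order
  out <- list(params = params, spec = spec, normalization = stats,
              schema = schema,
              log = data.frame(epoch = integer(0), train_loss = numeric(0),
                               val_loss = numeric(0), lr = numeric(0),
                               checkpointed = logical(0)),
              config = {
                cfg <- as.list(p$config)
                if (!is.null(cfg$early_stop_patience) &&
                    cfg$early_stop_patience < 0) {
                  cfg$early_stop_patience <- Inf
                }
                do.call(train_config, cfg)
              },
              best_epoch = p$best_epoch, best_val_loss = p$best_val_loss)
  class(out) <- "phenocomplete"
  out
}
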