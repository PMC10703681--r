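#' Copy-mask plan
#'
#' Copy-masking withholds observed entries by applying missingness patterns
#' that already exist in the data: a pattern row m is drawn from the rows of a
#' mask matrix and multiplied elementwise into an individual's own mask, so
#' simulated missingness inherits the block structure of real missingness
#' (e.g. whole questionnaires absent together).
#'
#' @param rho probability, in `[0,1]`, that an individual receives a copy-mask
#'   during one training pass.
#' @param pattern_source an observedness mask matrix (rows = patterns), e.g.
#'   `train$mask`. Training uses the training split's own patterns so no test
#'   patterns leak in.
#' @param seed integer seed.
#' @return An object of class `copy_mask_plan`.
#' @export
copy_mask_plan <- function(rho, pattern_source, seed = 1) {
  if (rho < 0 || rho > 1) stop_pc("rho must be in [0, 1]")
  pattern_source <- as.matrix(pattern_source)
  if (!nrow(pattern_source)) stop_pc("pattern source has no rows")
  structure(list(rho = rho, pattern_source = pattern_source,
                 seed = as.integer(seed)),
            class = "copy_mask_plan")
}

#' Apply copy-masking to a batch
#'
#' Each row independently receives, with probability `rho`, a pattern drawn
#' uniformly from the rows of the plan's pattern source; the row's effective
#' input mask becomes the elementwise product of its own mask and the pattern.
#' The original observedness mask is returned untouched: the loss is computed
#' over all originally observed cells, including those hidden from the input
#' (the denoising objective).
#'
#' @param batch a [pheno_matrix()].
#' @param plan a [copy_mask_plan()].
#' @return A list: `values` (batch values with newly hidden cells set `NA`),
#'   `input_mask` (the effective N x P input mask), `observed_mask` (the
#'   original mask, unchanged), `received` (logical, which rows got a pattern),
#'   `pattern_index` (donor row per masked row, NA otherwise).
#' @export
apply_copy_mask <- function(batch, plan) {
  if (ncol(batch$values) != ncol(plan$pattern_source)) {
    stop_pc("pattern source width does not match batch")
  }
  n <- nrow(batch$values)
  with_seed(derive_seed(plan$seed, 2L), {
    received <- stats::runif(n) < plan$rho
    pat_idx <- rep(NA_integer_, n)
    if (any(received)) {
      pat_idx[received] <- sample.int(nrow(plan$pattern_source),
                                      sum(received), replace = TRUE)
    }
    input_mask <- batch$mask
    if (any(received)) {
      input_mask[received, ] <- batch$mask[received, , drop = FALSE] *
        plan$pattern_source[pat_idx[received], , drop = FALSE]
    }
    vals <- batch$values
    vals[input_mask == 0L] <- NA_real_
    list(values = vals, input_mask = input_mask,
         observed_mask = batch$mask, received = received,
         pattern_index = pat_idx)
  })
}

new_evaluation_mask <- function(cells, truth, data, target_fraction,
                                achieved_fraction, mode) {
  structure(list(
    cells = data.frame(row = cells[, 1L], col = cells[, 2L],
                       IID = data$ids[cells[, 1L]],
                       phenotype = data$schema$name[cells[, 2L]],
                       true_value = truth, stringsAsFactors = FALSE),
    target_fraction = target_fraction,
    achieved_fraction = achieved_fraction,
    mode = mode),
    class = "evaluation_mask")
}

#' @export
print.evaluation_mask <- function(x, ...) {
  cat(sprintf(
    "Evaluation mask (%s): %d cells withheld (target %.2f%%, achieved %.2f%%)\n",
    x$mode, nrow(x$cells), 100 * x$target_fraction,
    100 * x$achieved_fraction))
  invisible(x)
}

#' Simulate missingness by copying existing patterns
#'
#' Repeatedly draws a donor individual and a recipient individual, and
#' withholds the recipient's observed entries at the donor's missing
#' positions, until the cumulative withheld count first reaches
#' `target_fraction` of all observed entries. The final donor pattern is
#' applied in full, so the achieved fraction may overshoot the target by less
#' than one pattern's worth; it is always reported. Withheld cells were all
#' observed and their true values are recorded for later scoring.
#'
#' @param data a [pheno_matrix()].
#' @param target_fraction proportion of observed entries to withhold, in (0,1).
#' @param seed integer seed.
#' @param max_futile_factor abort after `max_futile_factor * N` consecutive
#'   draws that withhold no new cell (e.g. all patterns fully observed).
#' @return An object of class `evaluation_mask`: the withheld cells with their
#'   true values, plus target and achieved fractions.
#' @export
simulate_missingness_copy <- function(data, target_fraction, seed = 1,
                                      max_futile_factor = 100) {
  if (target_fraction <= 0 || target_fraction >= 1) {
    stop_pc("target_fraction must be in (0, 1)")
  }
  n_obs <- sum(data$mask)
  if (n_obs == 0L) stop_pc("data has no observed entries")
  N <- nrow(data$mask)
  target_cells <- target_fraction * n_obs
  cur_mask <- data$mask
  withheld <- 0L
  futile <- 0L
  futile_limit <- max_futile_factor * N
  rows <- integer(0); cols <- integer(0)
  with_seed(derive_seed(seed, 3L), {
    while (withheld < target_cells) {
      donor <- sample.int(N, 1L)
      recip <- sample.int(N, 1L)
      hit <- which(cur_mask[recip, ] == 1L & data$mask[donor, ] == 0L)
      if (!length(hit)) {
        futile <- futile + 1L
        if (futile >= futile_limit) {
          stop_pc("copy-masking target unreachable after ", futile,
                  " futile draws (patterns may be fully observed)")
        }
        next
      }
      futile <- 0L
      cur_mask[recip, hit] <- 0L
      rows <- c(rows, rep(recip, length(hit)))
      cols <- c(cols, hit)
      withheld <- withheld + length(hit)
    }
  })
  truth <- data$values[cbind(rows, cols)]
  new_evaluation_mask(cbind(rows, cols), truth, data, target_fraction,
                      withheld / n_obs, "copy")
}

#' Simulate missingness uniformly at random
#'
#' Withholds `round(target_fraction * n_observed)` cells drawn uniformly
#' without replacement from all observed cells, ignoring the structure of the
#' existing missingness. This is the evaluation baseline that copy-masking is
#' contrasted against: uniform withholding tends to inflate apparent accuracy
#' because it rarely removes a whole questionnaire block at once.
#'
#' @inheritParams simulate_missingness_copy
#' @return An `evaluation_mask` (see [simulate_missingness_copy()]).
#' @export
simulate_missingness_uniform <- function(data, target_fraction, seed = 1) {
  if (target_fraction <= 0 || target_fraction >= 1) {
    stop_pc("target_fraction must be in (0, 1)")
  }
  obs_cells <- which(data$mask == 1L)
  if (!length(obs_cells)) stop_pc("data has no observed entries")
  n_take <- round(target_fraction * length(obs_cells))
  take <- with_seed(derive_seed(seed, 4L),
                    sample(obs_cells, n_take, replace = FALSE))
  rows <- ((take - 1L) %% nrow(data$mask)) + 1L
  cols <- ((take - 1L) %/% nrow(data$mask)) + 1L
  truth <- data$values[cbind(rows, cols)]
  new_evaluation_mask(cbind(rows, cols), truth, data, target_fraction,
                      n_take / length(obs_cells), "uniform")
}

#' Apply an evaluation mask to data
#'
#' Sets the withheld cells missing, producing the input actually given to the
#' imputation model during accuracy measurement.
#'
#' @param data the [pheno_matrix()] the mask was simulated on.
#' @param eval_mask an `evaluation_mask`.
#' @return A [pheno_matrix()] with the withheld cells set missing.
#' @export
apply_evaluation_mask <- function(data, eval_mask) {
  idx <- cbind(eval_mask$cells$row, eval_mask$cells$col)
  if (any(data$mask[idx] == 0L)) {
    stop_pc("evaluation mask touches cells that are not observed in the data")
  }
  mask <- data$mask
  mask[idx] <- 0L
  vals <- data$values
  vals[idx] <- NA_real_
  pheno_matrix(vals, data$ids, data$schema, mask)
}

#' Summarize distinct missingness patterns
#'
#' @param mask an observedness mask matrix (or a [pheno_matrix()]).
#' @return Data frame of distinct row patterns (as `"0/1"` strings) with
#'   counts; counts sum to the number of rows.
#' @export
pattern_statistics <- function(mask) {
  if (inherits(mask, "pheno_matrix")) mask <- mask$mask
  keys <- apply(mask, 1L, paste, collapse = "")
  tab <- table(keys)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$pattern), , drop = FALSE]
}

# Frobenius distance between column-missingness correlation of simulated
# cells and that of the original mask; used to show copy-simulated masks
# preserve block structure better than uniform ones.
missingness_correlation_distance <- function(data, eval_mask) {
  miss_orig <- 1 - data$mask
  sim <- matrix(0L, nrow(data$mask), ncol(data$mask))
  sim[cbind(eval_mask$cells$row, eval_mask$cells$col)] <- 1L
  c_orig <- suppressWarnings(stats::cor(miss_orig))
  c_sim <- suppressWarnings(stats::cor(sim))
  c_orig[!is.finite(c_orig)] <- 0
  c_sim[!is.finite(c_sim)] <- 0
  sqrt(sum((c_orig - c_sim)^2))
}
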