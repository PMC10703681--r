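#' Bootstrap multiple imputation
#'
#' Produces `m` plausible completions of a dataset to capture imputation
#' uncertainty. For each replicate the model is refitted from scratch on a
#' bootstrap resample of individuals (sampled with replacement) with a fresh
#' seed — so initialization, shuffling and copy-mask draws all vary — and the
#' fitted model imputes the ORIGINAL, unresampled data. Observed cells are
#' identical across all replicates (exact passthrough); imputed cells vary,
#' and that between-imputation variance is what Rubin's rule propagates.
#'
#' @param data a [pheno_matrix()] to impute.
#' @param m number of imputations (default 10).
#' @param seed master seed; replicate `r` trains under `seed + r`.
#' @param ... training arguments passed to [phenocomplete()]
#'   (`epochs`, `rho`, `batch_size`, ...).
#' @return An object of class `imputation_set`: `imputations` (list of `m`
#'   `imputed_pheno` objects), `seeds`, `boot_rows` (the resample draws),
#'   `m`, `failed` (indices of diverged replicates, if any).
#' @export
multiple_impute <- function(data, m = 10, seed = 1, ...) {
  if (m < 1) stop_pc("m must be >= 1")
  N <- nrow(data$values)
  imputations <- vector("list", m)
  boot_rows <- vector("list", m)
  seeds <- integer(m)
  failed <- integer(0)
  for (r in seq_len(m)) {
    seeds[r] <- seed + r
    rows <- with_seed(derive_seed(seeds[r], 10L),
                      sample.int(N, N, replace = TRUE))
    boot_rows[[r]] <- rows
    boot <- pheno_matrix(data$values[rows, , drop = FALSE],
                         paste0(data$ids[rows], "_b", seq_len(N)),
                         data$schema,
                         data$mask[rows, , drop = FALSE])
    fit <- tryCatch(
      phenocomplete(boot, ..., seed = seeds[r], keep_data = FALSE),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, r)
      imputations[r] <- list(NULL)
      next
    }
    imputations[[r]] <- impute_matrix(data, fit)
  }
  if (length(failed)) {
    warning("replicate(s) failed: ", paste(failed, collapse = ", "),
            "; imputation set is invalid")
  }
  structure(list(imputations = imputations, seeds = seeds,
                 boot_rows = boot_rows, m = m, failed = failed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Bootstrap multiple-imputation set: m = %d replicates", x$m))
  if (length(x$failed)) cat(sprintf(" (%d FAILED)", length(x$failed)))
  cat("\n")
  invisible(x)
}

#' Pool estimates across imputations with Rubin's rule
#'
#' Combines `m` per-imputation point estimates and standard errors into one
#' estimate, standard error and p-value. With `Q` the estimates and `U = SE^2`
#' the within-imputation variances: `Q_bar = mean(Q)`, `W_bar = mean(U)`,
#' `B = var(Q)` (divide by m-1), total variance `T = W_bar + (1 + 1/m) B`.
#' The p-value uses a t reference with
#' `df = (m-1) (1 + W_bar / ((1+1/m) B))^2`, falling back to a normal
#' reference when `B = 0` (all imputations agree) or `m = 1` (passthrough).
#'
#' @param estimates numeric vector of m point estimates.
#' @param ses numeric vector of m standard errors (> 0).
#' @return list of class `pooled_estimate`: `Q_bar`, `W_bar`, `B`, `T`,
#'   `se`, `df` (Inf when normal reference), `p`, `m`.
#' @export
rubin_pool <- function(estimates, ses) {
  m <- length(estimates)
  if (m < 1L) stop_pc("need at least one imputation")
  if (length(ses) != m) stop_pc("estimates and ses lengths differ")
  if (!all(is.finite(estimates)) || !all(is.finite(ses))) {
    stop_pc("estimates and ses must be finite")
  }
  if (any(ses <= 0)) stop_pc("standard errors must be positive")
  Q_bar <- mean(estimates)
  W_bar <- mean(ses^2)
  if (m == 1L) {
    out <- list(Q_bar = Q_bar, W_bar = W_bar, B = 0, T = W_bar,
                se = ses[1], df = Inf,
                p = 2 * stats::pnorm(-abs(Q_bar / ses[1])), m = 1L)
    class(out) <- "pooled_estimate"
    return(out)
  }
  B <- stats::var(estimates)
  T_tot <- W_bar + (1 + 1 / m) * B
  se <- sqrt(T_tot)
  if (B == 0) {
    df <- Inf
    p <- 2 * stats::pnorm(-abs(Q_bar / se))
  } else {
    df <- (m - 1) * (1 + W_bar / ((1 + 1 / m) * B))^2
    p <- 2 * stats::pt(-abs(Q_bar / se), df = df)
  }
  out <- list(Q_bar = Q_bar, W_bar = W_bar, B = B, T = T_tot, se = se,
              df = df, p = p, m = m)
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Rubin-pooled estimate (m = %d): %.4g (SE %.4g), p = %.3g (df %.3g)\n",
    x$m, x$Q_bar, x$se, x$p, x$df))
  invisible(x)
}

#' Read a per-imputation association table
#'
#' Tab-delimited summary statistics with PLINK-compatible header columns
#' `SNP`, `CHR`, `BP`, `BETA`, `SE`, `P`.
#'
#' @param path file path.
#' @return data frame of association records.
#' @export
read_assoc_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("SNP", "CHR", "BP", "BETA", "SE")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_pc("association table ", path, " lacks column(s): ",
            paste(miss, collapse = ", "))
  }
  if (any(df$SE <= 0)) stop_pc("non-positive SE in ", path)
  if (any(df$BP <= 0)) stop_pc("non-positive BP in ", path)
  df
}

#' Pool per-imputation association statistics
#'
#' Applies [rubin_pool()] per variant across `m` association tables (one per
#' imputation), preserving variant metadata. All tables must cover the same
#' variant set with consistent chromosome/position per identifier.
#'
#' @param tables a list of data frames (columns `SNP`, `CHR`, `BP`, `BETA`,
#'   `SE`, optionally `P`) or a character vector of file paths read with
#'   [read_assoc_table()].
#' @return data frame with one pooled row per variant: `SNP`, `CHR`, `BP`,
#'   `BETA` (pooled), `SE` (pooled), `P` (pooled), `B` (between-imputation
#'   variance), `DF`.
#' @export
pool_association_files <- function(tables) {
  if (is.character(tables)) tables <- lapply(tables, read_assoc_table)
  if (!length(tables)) stop_pc("no association tables supplied")
  ref <- tables[[1]]
  for (k in seq_along(tables)[-1]) {
    t_k <- tables[[k]]
    extra <- setdiff(t_k$SNP, ref$SNP)
    missing <- setdiff(ref$SNP, t_k$SNP)
    if (length(extra) || length(missing)) {
      stop_pc("variant set mismatch in table ", k, ": ",
              paste(utils::head(c(extra, missing), 5), collapse = ", "))
    }
    idx <- match(ref$SNP, t_k$SNP)
    if (any(t_k$CHR[idx] != ref$CHR) || any(t_k$BP[idx] != ref$BP)) {
      bad <- ref$SNP[which(t_k$CHR[idx] != ref$CHR |
                           t_k$BP[idx] != ref$BP)[1]]
      stop_pc("inconsistent position for variant ", bad, " in table ", k)
    }
  }
  betas <- vapply(tables, function(t) t$BETA[match(ref$SNP, t$SNP)],
                  numeric(nrow(ref)))
  ses <- vapply(tables, function(t) t$SE[match(ref$SNP, t$SNP)],
                numeric(nrow(ref)))
  if (nrow(ref) == 1L) {
    betas <- matrix(betas, nrow = 1L); ses <- matrix(ses, nrow = 1L)
  }
  pooled <- lapply(seq_len(nrow(ref)), function(i) {
    rubin_pool(betas[i, ], ses[i, ])
  })
  data.frame(SNP = ref$SNP, CHR = ref$CHR, BP = ref$BP,
             BETA = vapply(pooled, `[[`, numeric(1), "Q_bar"),
             SE = vapply(pooled, `[[`, numeric(1), "se"),
             P = vapply(pooled, `[[`, numeric(1), "p"),
             B = vapply(pooled, `[[`, numeric(1), "B"),
             DF = vapply(pooled, `[[`, numeric(1), "df"),
             stringsAsFactors = FALSE)
}

#' Effective sample size after phenotype imputation
#'
#' `N_eff = N_observed + r2 * N_imputed`: imputed individuals contribute in
#' proportion to the simulation-estimated imputation accuracy of the
#' phenotype. The fold increase is `(N_eff - N_observed) / N_observed`.
#'
#' @param n_observed individuals with the phenotype observed.
#' @param r2 imputation accuracy (squared Pearson correlation from simulated
#'   missingness), in `[0,1]`.
#' @param n_imputed individuals whose phenotype was imputed.
#' @return list with `n_effective` and `fold_increase`.
#' @export
effective_sample_size <- function(n_observed, r2, n_imputed) {
  if (r2 < 0 || r2 > 1) stop_pc("r2 must be in [0, 1]")
  if (n_observed < 0 || n_imputed < 0) stop_pc("counts must be non-negative")
  n_eff <- n_observed + r2 * n_imputed
  fold <- if (n_observed > 0) (n_eff - n_observed) / n_observed else NA_real_
  list(n_effective = n_eff, fold_increase = fold)
}

#' Sign-concordance binomial test
#'
#' Exact two-sided binomial test that `n_matching` of `n_total` loci share
#' the effect direction of a replication analysis by chance (null probability
#' 0.5). Uses the minimum-likelihood two-sided definition (outcomes no more
#' probable than the observed count), which for the symmetric 0.5 null equals
#' twice the tail.
#'
#' @param n_matching loci with matching effect direction.
#' @param n_total loci tested.
#' @return the two-sided p-value.
#' @export
sign_concordance_test <- function(n_matching, n_total) {
  if (n_total < 1 || n_matching < 0 || n_matching > n_total) {
    stop_pc("need 0 <= n_matching <= n_total, n_total >= 1")
  }
  stats::binom.test(n_matching, n_total, p = 0.5,
                    alternative = "two.sided")$p.value
}

#' Clump significant variants into independent loci
#'
#' Within each chromosome, the most significant remaining variant below the
#' threshold is tallied as a locus and every significant variant within
#' `window` base pairs of it (inclusive) is discarded; the procedure repeats
#' until no significant variant remains. Ties in p-value are broken by
#' smaller position.
#'
#' @param records data frame with columns `SNP`, `CHR`, `BP`, `P`.
#' @param threshold genome-wide significance level (default `5e-8`).
#' @param window distance in base pairs (default 1 Mb).
#' @return data frame of index variants, one row per locus, sorted by
#'   chromosome then position; zero rows when nothing is significant.
#' @export
clump_loci <- function(records, threshold = 5e-8, window = 1e6) {
  need <- c("SNP", "CHR", "BP", "P")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_pc("records lack column(s): ",
                            paste(miss, collapse = ", "))
  sig <- records[records$P < threshold, , drop = FALSE]
  loci <- list()
  for (chr in unique(sig$CHR)) {
    rem <- sig[sig$CHR == chr, , drop = FALSE]
    while (nrow(rem)) {
      top <- rem[order(rem$P, rem$BP), , drop = FALSE][1, , drop = FALSE]
      loci[[length(loci) + 1L]] <- top
      rem <- rem[abs(rem$BP - top$BP) > window, , drop = FALSE]
    }
  }
  if (!length(loci)) {
    return(records[0, need, drop = FALSE])
  }
  out <- do.call(rbind, loci)[, need, drop = FALSE]
  out <- out[order(out$CHR, out$BP), , drop = FALSE]
  rownames(out) <- NULL
  out
}
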