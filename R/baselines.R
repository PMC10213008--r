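#' Single-SNP mixed-model association scan
#'
#' Fits the ACE model one SNP at a time (intercept, the SNP, and any
#' covariates) by exact generalized least squares, with the variance
#' components estimated once on the null (no-SNP) model and reused across
#' SNPs; Wald t-tests give two-sided marginal p-values. Optionally the
#' variance components can be re-estimated per SNP.
#'
#' @param dataset A [fam_dataset()].
#' @param level FDR level for the Benjamini-Hochberg decision column.
#' @param refit_each Re-estimate variance components for every SNP
#'   (slower; default `FALSE`).
#' @param reml Variance-component flavour for the null fit.
#' @return An object of class `snp_scan`: a data frame with per-SNP
#'   `beta`, `se`, `t`, `p` and `bh_selected`, plus the null-model variance
#'   components as attribute `"varcomp"`.
#' @export
single_snp_scan <- function(dataset, level = 0.05, refit_each = FALSE,
                            reml = FALSE) {
  stopifnot(inherits(dataset, "fam_dataset"))
  p_g <- length(dataset$snp_ids)
  null_ds <- strip_snps(dataset)
  null_fit <- fit_ace_lmm(null_ds, reml = reml)
  design <- ds_design(dataset)
  suff <- ds_suffstats(design)
  acc <- ds_accumulate(suff, null_fit$varcomp)
  n <- design$n
  est <- se <- tval <- pval <- numeric(p_g)
  for (j in seq_len(p_g)) {
    if (refit_each) {
      one <- keep_snps(dataset, j)
      fit_j <- fit_ace_lmm(one, reml = reml)
      est[j] <- fit_j$beta_g[1]
      se[j] <- sqrt(fit_j$fixed_effect_cov[2, 2])
    } else {
      cols <- c(1L, design$gcols[j], design$ccols)
      Asub <- acc$A[cols, cols, drop = FALSE]
      R <- tryCatch(chol(Asub), error = function(e) NULL)
      if (is.null(R)) {
        warning(sprintf("SNP %s is monomorphic or collinear; p set to 1",
                        dataset$snp_ids[j]))
        est[j] <- 0; se[j] <- NA_real_; tval[j] <- 0; pval[j] <- 1
        next
      }
      bsub <- backsolve(R, backsolve(R, acc$b[cols], transpose = TRUE))
      est[j] <- bsub[2]
      se[j] <- sqrt(chol2inv(R)[2, 2])
    }
    df <- n - (2L + length(design$ccols))
    tval[j] <- est[j] / se[j]
    pval[j] <- 2 * stats::pt(-abs(tval[j]), df = df)
  }
  out <- data.frame(snp_id = dataset$snp_ids, beta = est, se = se,
                    t = tval, p = pval)
  out$bh_selected <- seq_len(p_g) %in% bh_select(out$p, level)
  attr(out, "varcomp") <- null_fit$varcomp
  class(out) <- c("snp_scan", "data.frame")
  out
}

strip_snps <- function(dataset) {
  fams <- lapply(dataset$families, function(f) {
    family_block(f$family_id, f$y, matrix(0L, f$n_i, 0L), f$phi, f$C,
                 f$roles, f$family_type)
  })
  fam_dataset(fams, snp_ids = character(),
              covariate_names = dataset$covariate_names)
}

keep_snps <- function(dataset, j) {
  fams <- lapply(dataset$families, function(f) {
    family_block(f$family_id, f$y, f$G[, j, drop = FALSE], f$phi, f$C,
                 f$roles, f$family_type)
  })
  fam_dataset(fams, snp_ids = dataset$snp_ids[j],
              covariate_names = dataset$covariate_names)
}

#' Benjamini-Hochberg selection
#'
#' Standard step-up false-discovery-rate control; a thin wrapper around
#' [stats::p.adjust()] returning the rejected index set.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @param level FDR level (default 0.05).
#' @return Integer indices of rejected hypotheses.
#' @export
bh_select <- function(pvalues, level = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  which(stats::p.adjust(pvalues, method = "BH") <= level)
}

#' mBIC2 backward deletion on an ordinary linear model
#'
#' Ignores the family covariance (deliberately, as a no-dependence
#' baseline) and performs backward deletion of SNPs from the ordinary
#' least-squares model `y ~ 1 + G + C`, minimizing the mBIC2 criterion
#' `n log(RSS/n) + k log(n) + 2 k log(p_g / c) - 2 log(k!)` with `c = 4`,
#' where `k` counts the SNPs retained (intercept and covariates are always
#' kept and not penalized). Deletion stops when no single removal lowers
#' the criterion.
#'
#' @param dataset A [fam_dataset()].
#' @param const The constant `c` in the penalty (default 4).
#' @return Integer vector of retained SNP indices (possibly empty), with
#'   the criterion trace as attribute `"trace"`.
#' @export
mbic2_backward <- function(dataset, const = 4) {
  stopifnot(inherits(dataset, "fam_dataset"))
  design <- ds_design(dataset)
  n <- design$n
  p_g <- design$p_g
  XtX <- crossprod(design$X)
  Xty <- crossprod(design$X, design$y)
  yty <- sum(design$y^2)
  rss_of <- function(active) {
    cols <- c(1L, design$gcols[active], design$ccols)
    R <- tryCatch(chol(XtX[cols, cols, drop = FALSE]),
                  error = function(e) stop("rank-deficient design"))
    b <- backsolve(R, backsolve(R, Xty[cols], transpose = TRUE))
    max(yty - sum(Xty[cols] * b), 1e-12)
  }
  crit_of <- function(active) {
    k <- length(active)
    n * log(rss_of(active) / n) + k * log(n) +
      2 * k * log(p_g / const) - 2 * lfactorial(k)
  }
  active <- seq_len(p_g)
  trace <- crit_of(active)
  repeat {
    if (!length(active)) break
    cand <- vapply(seq_along(active),
                   function(i) crit_of(active[-i]), 0)
    best <- which.min(cand)
    if (cand[best] < trace[length(trace)]) {
      active <- active[-best]
      trace <- c(trace, cand[best])
    } else break
  }
  attr(active, "trace") <- trace
  active
}

#' Benchmark selection methods on the synthetic generator
#'
#' Runs the generate / select / score loop `reps` times with independent
#' per-replication seeds and averages the TP/TN/RTP/RTN metrics. E-value
#' methods tune the bootstrap scale `s` by holdout prediction error on an
#' independently generated test dataset of the same size, at the fixed
#' threshold `t`.
#'
#' @param config A [sim_config()].
#' @param method One of `"evalue-E2"`, `"evalue-E1"`, `"singlesnp-BH"`,
#'   `"mbic2"`.
#' @param reps Number of replications.
#' @param seed Base seed; per-replication seeds are derived from it.
#' @param t Threshold for the e-value methods.
#' @param s_grid Bootstrap scale grid for the e-value methods.
#' @param B_ref,B_eval Ensemble sizes.
#' @param level FDR level for `"singlesnp-BH"`.
#' @param rule Threshold rule for the e-value methods.
#' @return An object of class `metrics_report`: list with the per-rep
#'   data frame `per_rep`, the averaged `means`, and the call settings.
#' @export
benchmark_methods <- function(config, method = c("evalue-E2", "evalue-E1",
                                                 "singlesnp-BH", "mbic2"),
                              reps = 100L, seed = 1L, t = 0.8,
                              s_grid = default_sim_s_grid(),
                              B_ref = 500L, B_eval = 500L, level = 0.05,
                              rule = "scaled_threshold") {
  method <- match.arg(method)
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    train <- simulate_dataset(config)
    if (startsWith(method, "evalue")) {
      test <- simulate_dataset(config)
      map <- sub("evalue-", "", method)
      res <- run_selection(train, test, map = map, s_grid = s_grid,
                           t_grid = t, B_ref = B_ref, B_eval = B_eval,
                           rule = rule)
      sel <- res$final_selected
      extra <- data.frame(best_s = res$best_s)
    } else if (method == "singlesnp-BH") {
      scan <- single_snp_scan(train, level = level)
      sel <- which(scan$bh_selected)
      extra <- data.frame(best_s = NA_real_)
    } else {
      sel <- mbic2_backward(train)
      extra <- data.frame(best_s = NA_real_)
    }
    rows[[r]] <- cbind(data.frame(rep = r, seed = rep_seeds[r]),
                       compute_metrics(sel, config), extra)
  }
  per_rep <- do.call(rbind, rows)
  means <- colMeans(per_rep[, c("tp", "tn", "rtp", "rtn", "n_selected")],
                    na.rm = TRUE)
  structure(list(per_rep = per_rep, means = as.list(means),
                 reps = reps, method = method, h = config$h, t = t,
                 seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: %s, h = %g, %d replications\n",
              x$method, x$h, x$reps))
  cat(sprintf("  TP = %.3f  TN = %.3f  RTP = %.3f  RTN = %.3f  |S| = %.2f\n",
              x$means$tp, x$means$tn, x$means$rtp, x$means$rtn,
              x$means$n_selected))
  invisible(x)
}
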