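#' Profiled Gaussian log-likelihood of the ACE mixed model
#'
#' Evaluates the log-likelihood of the multi-SNP ACE model at a fixed value
#' of the variance components, with the fixed effects (intercept, SNP and
#' covariate coefficients) profiled out by generalized least squares. The
#' block-diagonal family structure is exploited throughout: only per-family
#' covariance matrices (typically 4 x 4) are ever formed.
#'
#' @param dataset A [fam_dataset()].
#' @param varcomp Variance components, see [variance_components()].
#' @param reml If `TRUE`, return the restricted (REML) log-likelihood.
#' @return A list with `loglik`, `alpha`, `beta_g`, `beta_c` and the full
#'   profiled coefficient vector `coefficients`.
#' @export
profile_loglik <- function(dataset, varcomp, reml = FALSE) {
  design <- ds_design(dataset)
  suff <- ds_suffstats(design)
  out <- profile_loglik_core(suff, as_varcomp(varcomp), design$n, reml)
  if (is.null(out)) stop("covariance matrix not positive definite")
  beta <- out$beta
  list(loglik = out$loglik,
       alpha = beta[1],
       beta_g = beta[design$gcols],
       beta_c = beta[design$ccols],
       coefficients = beta)
}

profile_loglik_core <- function(suff, varcomp, n, reml = FALSE) {
  acc <- ds_accumulate(suff, varcomp)
  if (is.null(acc)) return(NULL)
  RA <- tryCatch(chol(acc$A), error = function(e) NULL)
  if (is.null(RA)) {
    stop("rank-deficient fixed-effect design (collinear predictors)")
  }
  beta <- backsolve(RA, backsolve(RA, acc$b, transpose = TRUE))
  quad <- acc$yVy - sum(acc$b * beta)
  ll <- -0.5 * (n * log(2 * pi) + acc$logdet + quad)
  if (reml) {
    p <- length(beta)
    ll <- ll - 0.5 * 2 * sum(log(diag(RA))) + 0.5 * p * log(2 * pi)
  }
  list(loglik = ll, beta = beta, acc = acc, chol_A = RA)
}

#' Fit the multi-SNP ACE linear mixed model by maximum likelihood
#'
#' Maximizes the profiled log-likelihood over log-scale variance components
#' (`L-BFGS-B`, with a Nelder-Mead fallback), starting from equal thirds of
#' the ordinary-least-squares residual variance. The residual component
#' `sigma_e2` is floored at `1e-6` times the total phenotypic variance to
#' keep every family covariance invertible; `sigma_a2` and `sigma_c2` may
#' reach the zero boundary, which is flagged, not treated as an error.
#'
#' The returned object caches per-family inverse-covariance crossproducts,
#' which the generalized bootstrap ([gbs_ensemble()]) and restricted refits
#' ([gls_refit()]) reuse without touching the raw data again.
#'
#' @param dataset A [fam_dataset()].
#' @param reml Use REML instead of ML for the variance components.
#' @param start Optional starting values for
#'   `c(sigma_a2, sigma_c2, sigma_e2)`.
#' @param control Optional list passed to [stats::optim()] (merged over the
#'   defaults).
#' @return An object of class `ace_fit` with components `alpha`, `beta_g`,
#'   `beta_c`, `varcomp`, `loglik`, `fixed_effect_cov`, convergence flags,
#'   and internal caches.
#' @export
fit_ace_lmm <- function(dataset, reml = FALSE, start = NULL, control = list()) {
  counter_bump("fit_ace_lmm")
  design <- ds_design(dataset)
  suff <- ds_suffstats(design)
  n <- design$n

  # OLS start: equal thirds of residual variance (also catches collinearity)
  qrX <- qr(design$X)
  if (qrX$rank < design$p) {
    stop("rank-deficient fixed-effect design (collinear predictors)")
  }
  res <- qr.resid(qrX, design$y)
  vtot <- sum(res^2) / max(1, n - design$p)
  if (vtot <= 0) vtot <- stats::var(design$y) + 1e-8
  floor_e <- 1e-6 * vtot
  if (is.null(start)) start <- rep(vtot / 3, 3)
  lpar0 <- log(pmax(start, floor_e))

  obj <- function(lpar) {
    vc <- variance_components(exp(lpar[1]), exp(lpar[2]),
                              max(exp(lpar[3]), floor_e))
    out <- tryCatch(profile_loglik_core(suff, vc, n, reml),
                    error = function(e) NULL)
    if (is.null(out) || !is.finite(out$loglik)) return(-1e10)
    out$loglik
  }

  ctl <- utils::modifyList(list(fnscale = -1, maxit = 500L, factr = 1e7), control)
  opt <- tryCatch(
    stats::optim(lpar0, obj, method = "L-BFGS-B",
                 lower = c(-30, -30, log(floor_e)), upper = rep(30, 3),
                 control = ctl[names(ctl) %in% c("fnscale", "maxit", "factr",
                                                 "trace")]),
    error = function(e) NULL)
  if (is.null(opt) || opt$value <= -1e9) {
    opt <- stats::optim(lpar0, obj, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 2000L,
                                       reltol = 1e-10))
  }
  if (opt$value < obj(lpar0) - 1e-6) {
    stop("variance-component optimization failed to improve on start")
  }
  vc <- variance_components(exp(opt$par[1]), exp(opt$par[2]),
                            max(exp(opt$par[3]), floor_e))
  final <- profile_loglik_core(suff, vc, n, reml)

  boundary <- c(sigma_a2 = vc$sigma_a2 < 1e-5 * vtot,
                sigma_c2 = vc$sigma_c2 < 1e-5 * vtot,
                sigma_e2 = vc$sigma_e2 <= floor_e * (1 + 1e-8))

  # per-family caches for the generalized bootstrap. Xi' Vi^-1 Xi is
  # symmetric, so only the upper triangle is stored (halves the big
  # weights-times-crossproducts multiply); expand_idx rebuilds the full
  # p x p matrix from the packed column.
  p <- design$p
  ut <- upper.tri(matrix(0, p, p), diag = TRUE)
  pos <- matrix(0L, p, p)
  pos[ut] <- seq_len(sum(ut))
  tpos <- t(pos)
  pos[pos == 0L] <- tpos[pos == 0L]
  expand_idx <- as.vector(pos)
  A_tri <- matrix(0, sum(ut), dataset$m)
  b_mat <- matrix(0, p, dataset$m)
  for (gi in seq_along(design$groups)) {
    g <- design$groups[[gi]]
    Vinv <- final$acc$Vinv[[gi]]
    for (jj in seq_along(g$fams)) {
      i <- g$fams[jj]
      rows_i <- g$rows[, jj]
      Xi <- design$X[rows_i, , drop = FALSE]
      XtVi <- crossprod(Xi, Vinv)
      A_tri[, i] <- (XtVi %*% Xi)[ut]
      b_mat[, i] <- XtVi %*% design$y[rows_i]
    }
  }

  beta <- final$beta
  structure(list(
    alpha = beta[1],
    beta_g = stats::setNames(beta[design$gcols], dataset$snp_ids),
    beta_c = stats::setNames(beta[design$ccols], dataset$covariate_names),
    coefficients = beta,
    varcomp = vc,
    loglik = final$loglik,
    reml = reml,
    fixed_effect_cov = chol2inv(final$chol_A),
    boundary = boundary,
    convergence = opt$convergence,
    XtViX = final$acc$A,
    XtViy = final$acc$b,
    A_tri = A_tri,
    expand_idx = expand_idx,
    b_mat = b_mat,
    m = dataset$m,
    p = p,
    gcols = design$gcols,
    ccols = design$ccols,
    snp_ids = dataset$snp_ids,
    covariate_names = dataset$covariate_names,
    Vinv_groups = final$acc$Vinv,
    group_phi = lapply(design$groups, `[[`, "phi")),
    class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("ACE mixed model fit (%s): %d families, %d SNPs\n",
              if (x$reml) "REML" else "ML", x$m, length(x$beta_g)))
  print(x$varcomp)
  cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  if (any(x$boundary)) {
    cat("boundary estimates:", paste(names(x$boundary)[x$boundary],
                                     collapse = ", "), "\n")
  }
  invisible(x)
}

#' Restricted generalized-least-squares refit over a subset of SNPs
#'
#' Re-estimates the fixed effects using only the intercept, covariates and
#' the SNPs in `active_snps`, with the variance components frozen at the
#' fitted values. Uses the cached full-model crossproducts, so no per-family
#' work is repeated. SNPs outside the active set get coefficient zero.
#'
#' @param fit An [fit_ace_lmm()] result.
#' @param active_snps Integer indices of SNPs (subset of `1..p_g`); may be
#'   empty, in which case only intercept and covariates are estimated.
#' @return A list with `beta_g` (full length, zeros off the active set),
#'   `alpha`, `beta_c` and the full-length `coefficients` vector.
#' @export
gls_refit <- function(fit, active_snps) {
  stopifnot(inherits(fit, "ace_fit"))
  active_snps <- sort(unique(as.integer(active_snps)))
  p_g <- length(fit$gcols)
  if (length(active_snps) && (min(active_snps) < 1 || max(active_snps) > p_g)) {
    stop("active_snps out of range")
  }
  cols <- c(1L, fit$gcols[active_snps], fit$ccols)
  Asub <- fit$XtViX[cols, cols, drop = FALSE]
  R <- tryCatch(chol(Asub), error = function(e) {
    stop("rank-deficient restricted design")
  })
  bsub <- backsolve(R, backsolve(R, fit$XtViy[cols], transpose = TRUE))
  beta <- numeric(fit$p)
  beta[cols] <- bsub
  list(beta_g = stats::setNames(beta[fit$gcols], fit$snp_ids),
       alpha = beta[1],
       beta_c = stats::setNames(beta[fit$ccols], fit$covariate_names),
       coefficients = beta)
}

# ---- fit-call instrumentation -------------------------------------------

the_counters <- new.env(parent = emptyenv())

counter_bump <- function(key) {
  cur <- get0(key, envir = the_counters, ifnotfound = 0L)
  assign(key, cur + 1L, envir = the_counters)
  invisible(cur + 1L)
}

#' Count of full-model fits since the last reset
#'
#' Diagnostic counter used to verify that grid search over the bootstrap
#' scale and selection threshold reuses a single full-model fit.
#' @return Integer count.
#' @export
fit_call_count <- function() {
  get0("fit_ace_lmm", envir = the_counters, ifnotfound = 0L)
}

#' @rdname fit_call_count
#' @export
reset_fit_call_count <- function() {
  assign("fit_ace_lmm", 0L, envir = the_counters)
  invisible(NULL)
}
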