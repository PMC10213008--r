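#' Generalized-bootstrap configuration
#'
#' @param s Bootstrap noise scale: the standard deviation of the per-family
#'   resampling weights. The bootstrap spread of the coefficient draws is
#'   approximately `s` times the sampling standard error, so `s` directly
#'   controls how far reduced-model points must move to be distinguishable.
#' @param B_ref,B_eval Number of draws in the reference and evaluation
#'   ensembles (each at least 100).
#' @param weight_law `"gamma"` (default): independent Gamma(1/s^2, scale s^2)
#'   weights with mean 1, sd `s` and positive support; `"multinomial"`:
#'   m-out-of-m multinomial resampling counts (then `s` is ignored and the
#'   effective scale is close to 1).
#' @param seed Optional integer seed set before drawing.
#' @return A list of class `gbs_config`.
#' @export
gbs_config <- function(s, B_ref = 500L, B_eval = 500L,
                       weight_law = c("gamma", "multinomial"), seed = NULL) {
  weight_law <- match.arg(weight_law)
  stopifnot(is.numeric(s), length(s) == 1, s > 0)
  B_ref <- as.integer(B_ref); B_eval <- as.integer(B_eval)
  if (B_ref < 100L || B_eval < 100L) stop("B_ref and B_eval must be >= 100")
  structure(list(s = s, B_ref = B_ref, B_eval = B_eval,
                 weight_law = weight_law, seed = seed),
            class = "gbs_config")
}

#' Draw generalized-bootstrap resampling weights
#'
#' One row per resample; weights are independent across families, strictly
#' positive (Gamma law), with mean 1 and standard deviation `s`.
#'
#' @param m Number of families (independent sampling units).
#' @param s Weight standard deviation (> 0).
#' @param B Number of resamples.
#' @param weight_law See [gbs_config()].
#' @return A `B x m` matrix of weights.
#' @export
draw_weights <- function(m, s, B, weight_law = c("gamma", "multinomial")) {
  weight_law <- match.arg(weight_law)
  if (weight_law == "gamma") {
    if (!is.numeric(s) || s <= 0) stop("s must be > 0")
    matrix(stats::rgamma(B * m, shape = 1 / s^2, scale = s^2), B, m)
  } else {
    t(stats::rmultinom(B, m, rep(1 / m, m)))
  }
}

#' Generalized bootstrap of the SNP coefficient vector
#'
#' Produces bootstrap draws of the fixed-effect estimate by reweighting the
#' cached per-family estimating-equation contributions of the full-model
#' fit: for weight vector `w`, the draw solves
#' `(sum_i w_i Xi' Vi^-1 Xi) beta = sum_i w_i Xi' Vi^-1 yi`, with the family
#' covariances frozen at the fitted variance components (they are never
#' re-estimated inside the bootstrap). Two independent ensembles are
#' returned: the reference ensemble supplies the moments against which
#' e-values are computed, the evaluation ensemble supplies the points that
#' get scored.
#'
#' @param fit An [fit_ace_lmm()] result with caches populated.
#' @param config A [gbs_config()].
#' @return A list with elements `reference` and `evaluation`, each of class
#'   `gbs_ensemble` carrying `draws` (`B x p_g` matrix of SNP-coefficient
#'   draws), `ref_mean`, `ref_sd`, and the scale `s` used.
#' @export
gbs_ensemble <- function(fit, config) {
  stopifnot(inherits(fit, "ace_fit"), inherits(config, "gbs_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  reference <- gbs_one_ensemble(fit, config$s, config$B_ref, config$weight_law)
  evaluation <- gbs_one_ensemble(fit, config$s, config$B_eval, config$weight_law)
  list(reference = reference, evaluation = evaluation)
}

gbs_one_ensemble <- function(fit, s, B, weight_law = "gamma") {
  p <- fit$p
  W <- draw_weights(fit$m, s, B, weight_law)
  MM <- fit$A_tri %*% t(W)            # packed weighted crossproducts
  CC <- fit$b_mat %*% t(W)            # p x B weighted score sums
  draws <- matrix(0, B, p)
  bad <- 0L
  for (b in seq_len(B)) {
    db <- gbs_solve(MM[, b][fit$expand_idx], CC[, b], p)
    tries <- 0L
    while (is.null(db) && tries < 50L) {
      # singular weighted crossproduct: reject and redraw this resample
      bad <- bad + 1L; tries <- tries + 1L
      w <- draw_weights(fit$m, s, 1L, weight_law)
      db <- gbs_solve((fit$A_tri %*% t(w))[fit$expand_idx],
                      fit$b_mat %*% t(w), p)
    }
    if (is.null(db)) stop("generalized bootstrap: persistent singular draws")
    draws[b, ] <- db
  }
  if (bad > 0.01 * B) {
    warning(sprintf("generalized bootstrap rejected %d singular draws", bad))
  }
  bg <- draws[, fit$gcols, drop = FALSE]
  colnames(bg) <- fit$snp_ids
  ref_sd <- apply(bg, 2, stats::sd)
  if (any(ref_sd <= 0)) {
    stop("degenerate bootstrap ensemble: zero spread in some coordinate")
  }
  structure(list(draws = bg, ref_mean = colMeans(bg), ref_sd = ref_sd,
                 s = s, B = B, weight_law = weight_law),
            class = "gbs_ensemble")
}

gbs_solve <- function(Mflat, cvec, p) {
  M <- matrix(Mflat, p, p)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  backsolve(R, backsolve(R, cvec, transpose = TRUE))
}

#' @export
print.gbs_ensemble <- function(x, ...) {
  cat(sprintf("gbs_ensemble: %d draws of %d SNP coefficients (s = %.3g)\n",
              x$B, ncol(x$draws), x$s))
  invisible(x)
}
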