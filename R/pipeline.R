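#' Holdout fixed-effect prediction error of a selected SNP set
#'
#' Refits the fixed effects on the training data restricted to the selected
#' SNPs (plus intercept and covariates) with variance components frozen at
#' the full-model fit, then sums squared residuals of the fixed-effect
#' prediction over all individuals of the test families.
#'
#' @param selected Integer vector of selected SNP indices (may be empty).
#' @param fit Full-model [fit_ace_lmm()] on the training data.
#' @param train Training [fam_dataset()] (unused when `use_refit = TRUE`
#'   beyond the cached fit; kept for interface clarity).
#' @param test Test `fam_dataset` with the same SNP panel and covariates.
#' @param use_refit If `TRUE` (default), use the restricted GLS refit; if
#'   `FALSE`, use the full-model estimate with unselected coordinates set
#'   to zero.
#' @return Non-negative prediction error.
#' @export
prediction_error <- function(selected, fit, train = NULL, test,
                             use_refit = TRUE) {
  stopifnot(inherits(fit, "ace_fit"), inherits(test, "fam_dataset"))
  if (!identical(test$snp_ids, fit$snp_ids)) {
    stop("test dataset SNP ids do not match the fitted model")
  }
  if (!identical(test$covariate_names, fit$covariate_names)) {
    stop("test dataset covariates do not match the fitted model")
  }
  beta <- if (use_refit) {
    gls_refit(fit, selected)$coefficients
  } else {
    bz <- fit$coefficients
    off <- setdiff(seq_along(fit$gcols), selected)
    bz[fit$gcols[off]] <- 0
    bz
  }
  design <- ds_design(test)
  sum((design$y - as.vector(design$X %*% beta))^2)
}

#' Family-level holdout split
#'
#' @param dataset A [fam_dataset()].
#' @param fraction Fraction of families assigned to the training set.
#' @return A list with `train` and `test` datasets (family-disjoint).
#' @export
holdout_split <- function(dataset, fraction = 0.75) {
  stopifnot(inherits(dataset, "fam_dataset"), fraction > 0, fraction < 1)
  n_train <- max(1L, round(fraction * dataset$m))
  if (n_train >= dataset$m) n_train <- dataset$m - 1L
  idx <- sample(dataset$m, n_train)
  list(train = fam_dataset(dataset$families[sort(idx)], dataset$snp_ids,
                           dataset$covariate_names),
       test = fam_dataset(dataset$families[-sort(idx)], dataset$snp_ids,
                          dataset$covariate_names))
}

#' Default bootstrap-scale grids
#'
#' `default_sim_s_grid()` is the grid used in the simulation experiments
#' (0.1 to 0.95 in steps of 0.05, plus 2); `default_select_s_grid()` and
#' `default_select_t_grid()` are the wider data-analysis grids
#' (s = 0.2, 0.4, ..., 3; t = 0.1, 0.15, ..., 0.8).
#' @return Numeric vector.
#' @export
default_sim_s_grid <- function() c(seq(0.1, 0.95, by = 0.05), 2)

#' @rdname default_sim_s_grid
#' @export
default_select_s_grid <- function() seq(0.2, 3, by = 0.2)

#' @rdname default_sim_s_grid
#' @export
default_select_t_grid <- function() seq(0.1, 0.8, by = 0.05)

#' End-to-end e-value SNP selection with (s, t) tuning
#'
#' Fits the full multi-SNP ACE model once on the training data; then, for
#' every bootstrap scale `s` in the grid, draws one pair of
#' reference/evaluation ensembles and evaluates the quantile selection rule
#' at every threshold `t`, scoring each candidate set by holdout
#' fixed-effect prediction error on the test families. The `(s, t)` pair
#' minimizing prediction error (first minimum in grid order, i.e. smallest
#' `s`, on ties) gives the final selected set.
#'
#' @param train,test Family-disjoint [fam_dataset()]s with identical SNP
#'   panels.
#' @param map Evaluation map, `"E2"` (default) or `"E1"`.
#' @param s_grid Bootstrap noise scales to try.
#' @param t_grid Selection thresholds in (0, 1).
#' @param q_set Quantile levels enforced jointly (default 0.5 to 0.9).
#' @param B_ref,B_eval Ensemble sizes.
#' @param weight_law Bootstrap weight law, see [gbs_config()].
#' @param rule Threshold rule, see [select_snps_quantile()].
#' @param seed Optional integer seed (set once before the bootstrap loop).
#' @param use_refit Prediction-error convention, see [prediction_error()].
#' @param reml Variance-component estimation flavour for the single fit.
#' @return An object of class `snp_selection` with the tuning `grid` (data
#'   frame of s, t, set size, prediction error), `best_s`, `best_t`,
#'   `final_selected`, `final_beta` (restricted refit) and the full-model
#'   `fit`.
#' @export
run_selection <- function(train, test, map = c("E2", "E1"),
                          s_grid = default_sim_s_grid(),
                          t_grid = default_select_t_grid(),
                          q_set = seq(0.5, 0.9, by = 0.1),
                          B_ref = 500L, B_eval = 500L,
                          weight_law = "gamma",
                          rule = "scaled_threshold",
                          seed = NULL, use_refit = TRUE, reml = FALSE) {
  map <- match.arg(map)
  stopifnot(length(s_grid) >= 1, length(t_grid) >= 1)
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_ace_lmm(train, reml = reml)
  test_design <- ds_design(test)
  if (!identical(test$snp_ids, train$snp_ids)) {
    stop("train and test SNP panels differ")
  }
  pe_of <- function(selected) {
    beta <- if (use_refit) gls_refit(fit, selected)$coefficients else {
      bz <- fit$coefficients
      bz[fit$gcols[setdiff(seq_along(fit$gcols), selected)]] <- 0
      bz
    }
    sum((test_design$y - as.vector(test_design$X %*% beta))^2)
  }
  grid <- expand.grid(s = s_grid, t = t_grid, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(match(grid$s, s_grid), match(grid$t, t_grid)), ]
  rownames(grid) <- NULL
  grid$n_selected <- NA_integer_
  grid$pe <- NA_real_
  sets <- vector("list", nrow(grid))
  pe_cache <- new.env(parent = emptyenv())
  row <- 1L
  for (s in s_grid) {
    ens <- gbs_ensemble(fit, gbs_config(s = s, B_ref = B_ref,
                                        B_eval = B_eval,
                                        weight_law = weight_law))
    summ <- evalue_distributions(ens$reference, ens$evaluation, map, q_set)
    for (t in t_grid) {
      sel <- select_snps_quantile(summ, t, rule)
      key <- paste0("S", paste(sel, collapse = ","))
      pe <- get0(key, envir = pe_cache)
      if (is.null(pe)) {
        pe <- pe_of(sel)
        assign(key, pe, envir = pe_cache)
      }
      sets[[row]] <- sel
      grid$n_selected[row] <- length(sel)
      grid$pe[row] <- pe
      row <- row + 1L
    }
  }
  best <- which.min(grid$pe)
  final_selected <- sets[[best]]
  structure(list(grid = grid, sets = sets,
                 best_s = grid$s[best], best_t = grid$t[best],
                 final_selected = final_selected,
                 final_beta = gls_refit(fit, final_selected)$beta_g,
                 map = map, q_set = q_set, fit = fit),
            class = "snp_selection")
}

#' @export
print.snp_selection <- function(x, ...) {
  cat(sprintf("snp_selection (%s): best s = %.3g, best t = %.3g, %d SNPs selected\n",
              x$map, x$best_s, x$best_t, length(x$final_selected)))
  if (length(x$final_selected)) {
    cat("selected:", paste(x$fit$snp_ids[x$final_selected], collapse = ", "),
        "\n")
  }
  invisible(x)
}
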