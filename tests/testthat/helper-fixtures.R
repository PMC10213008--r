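# Small in-code fixtures shared across test files.

# A tiny deterministic dataset: m families with p_g SNPs, mixed types.
toy_dataset <- function(m = 6, p_g = 3, seed = 42, types = c("MZ", "DZ"),
                        with_cov = FALSE) {
  set.seed(seed)
  fams <- lapply(seq_len(m), function(i) {
    type <- types[((i - 1) %% length(types)) + 1]
    G <- matrix(sample(0:2, 4 * p_g, replace = TRUE), 4, p_g)
    C <- if (with_cov) matrix(rnorm(4), 4, 1) else NULL
    y <- rnorm(4, mean = rowSums(G) * 0.1)
    family_block(paste0("f", i), y, G, build_kinship_matrix(type),
                 C = C, roles = c("father", "mother", "child", "child"),
                 family_type = type)
  })
  fam_dataset(fams, snp_ids = paste0("s", seq_len(p_g)),
              covariate_names = if (with_cov) "c1" else character())
}

# Dense-covariance log-likelihood oracle: builds the full n x n block
# covariance and computes the profiled Gaussian log-likelihood directly.
dense_loglik <- function(dataset, varcomp, reml = FALSE) {
  vc <- evaluesnp:::as_varcomp(varcomp)
  blocks <- lapply(dataset$families, function(f) {
    assemble_covariance(vc, f$phi)
  })
  n <- dataset$n
  V <- matrix(0, n, n)
  X <- NULL; y <- NULL
  at <- 0
  for (i in seq_along(dataset$families)) {
    f <- dataset$families[[i]]
    idx <- at + seq_len(f$n_i)
    V[idx, idx] <- blocks[[i]]
    Xi <- cbind(1, f$G, if (is.null(f$C)) NULL else f$C)
    X <- rbind(X, Xi)
    y <- c(y, f$y)
    at <- at + f$n_i
  }
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  b <- t(X) %*% Vi %*% y
  beta <- solve(A, b)
  r <- y - X %*% beta
  ll <- -0.5 * (n * log(2 * pi) + determinant(V)$modulus +
                  t(r) %*% Vi %*% r)
  if (reml) {
    ll <- ll - 0.5 * determinant(A)$modulus + 0.5 * length(beta) * log(2 * pi)
  }
  list(loglik = as.numeric(ll), beta = as.numeric(beta))
}

# Minimal hand-built bootstrap ensemble for e-value unit tests.
fake_ensemble <- function(draws, s = 0.5) {
  draws <- as.matrix(draws)
  if (is.null(colnames(draws))) {
    colnames(draws) <- paste0("s", seq_len(ncol(draws)))
  }
  structure(list(draws = draws, ref_mean = colMeans(draws),
                 ref_sd = apply(draws, 2, sd), s = s, B = nrow(draws),
                 weight_law = "gamma"),
            class = "gbs_ensemble")
}

# Small simulation config for fast tests.
small_sim <- function(m = 60, h = 10, ...) {
  sim_config(m = m, h = h, ...)
}
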