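test_that("kinship matrices match the standard nuclear-pedigree values", {
  phi_mz <- build_kinship_matrix("MZ", 4)
  expect_identical(phi_mz,
                   rbind(c(1, 0, .5, .5), c(0, 1, .5, .5),
                         c(.5, .5, 1, 1), c(.5, .5, 1, 1)))
  phi_dz <- build_kinship_matrix("DZ", 4)
  expect_identical(phi_dz[3, 4], 0.5)
  expect_identical(phi_dz[1, 3], 0.5)
  expect_identical(build_kinship_matrix("adopted", 4), diag(4))
  expect_identical(build_kinship_matrix("non_twin_sibs", 4), phi_dz)
  phi_mix <- build_kinship_matrix("mixed_adopted_bio", 4)
  expect_identical(phi_mix[1, 3], 0.5)
  expect_identical(phi_mix[1, 4], 0)
  expect_identical(phi_mix[3, 4], 0)
  # parents-only and one-child variants
  expect_identical(build_kinship_matrix("MZ", 2), diag(2))
  expect_identical(build_kinship_matrix("DZ", 3)[1, 3], 0.5)
  expect_error(build_kinship_matrix("cousins", 4))
  expect_error(build_kinship_matrix("mixed_adopted_bio", 3))
})

test_that("assemble_covariance follows the three-component decomposition", {
  expect_equal(assemble_covariance(variance_components(0, 0, 1),
                                   build_kinship_matrix("MZ")),
               diag(4))
  V <- assemble_covariance(variance_components(4, 1, 1),
                           build_kinship_matrix("MZ"))
  expect_equal(diag(V), rep(6, 4))
  expect_equal(V[3, 4], 5)   # MZ twins: 4*1 + 1
  expect_equal(V[1, 3], 3)   # parent-child: 4*0.5 + 1
  expect_equal(V[1, 2], 1)   # parents: shared environment only
  eps <- 1e-8
  expect_equal(assemble_covariance(variance_components(1, 0, eps), diag(3)),
               (1 + eps) * diag(3))
  expect_error(assemble_covariance(variance_components(1, 1, 1),
                                   matrix(c(1, .5, 0, 1), 2, 2)),
               "symmetric")
})

test_that("family_block and fam_dataset validate their invariants", {
  G <- matrix(c(0, 1, 2, 1), 2, 2)
  phi <- diag(2)
  expect_s3_class(family_block("f1", c(1, 2), G, phi), "family_block")
  expect_error(family_block("f1", c(1, 2), G + 2, phi), "0/1/2")
  expect_error(family_block("f1", c(1, 2), G, matrix(1, 2, 2) * 2))
  expect_error(family_block("f1", 1:3, G, phi))
  Gna <- G; Gna[1] <- NA
  expect_error(family_block("f1", c(1, 2), Gna, phi), "missing")
  f1 <- family_block("f1", c(1, 2), G, phi)
  f2 <- family_block("f2", c(1, 2), G[, 1, drop = FALSE], phi)
  expect_error(fam_dataset(list(f1, f2)), "same number of SNPs")
  ds <- fam_dataset(list(f1, f1))
  expect_equal(ds$m, 2)
  expect_equal(ds$n, 4)
})

test_that("block-wise profiled likelihood equals the dense-covariance oracle", {
  ds <- toy_dataset(m = 3, p_g = 2, seed = 7)
  for (vc in list(c(1, 0.5, 0.8), c(4, 1, 1), c(0.1, 0.1, 2))) {
    got <- profile_loglik(ds, vc)
    want <- dense_loglik(ds, vc)
    expect_equal(got$loglik, want$loglik, tolerance = 1e-8)
    expect_equal(unname(got$coefficients), want$beta, tolerance = 1e-8)
    got_reml <- profile_loglik(ds, vc, reml = TRUE)
    want_reml <- dense_loglik(ds, vc, reml = TRUE)
    expect_equal(got_reml$loglik, want_reml$loglik, tolerance = 1e-8)
  }
})

test_that("profiled GLS reduces to OLS when the covariance is spherical", {
  ds <- toy_dataset(m = 8, p_g = 3, seed = 11, with_cov = TRUE)
  got <- profile_loglik(ds, variance_components(0, 0, 1.7))
  design <- evaluesnp:::ds_design(ds)
  ols <- lm.fit(design$X, design$y)
  expect_equal(unname(got$coefficients), unname(ols$coefficients),
               tolerance = 1e-8)
})

test_that("collinear predictors raise an explicit rank error", {
  ds <- toy_dataset(m = 5, p_g = 2, seed = 3)
  dup <- lapply(ds$families, function(f) {
    family_block(f$family_id, f$y, cbind(f$G, f$G[, 1]), f$phi,
                 roles = f$roles, family_type = f$family_type)
  })
  ds_dup <- fam_dataset(dup, snp_ids = c("s1", "s2", "s1_copy"))
  expect_error(profile_loglik(ds_dup, c(1, 1, 1)), "collinear|rank")
  expect_error(fit_ace_lmm(ds_dup), "collinear|rank")
})

test_that("ML fit attains at least the starting log-likelihood and is order-invariant", {
  set.seed(21)
  ds <- simulate_dataset(small_sim(m = 80, h = 0,
                                   family_type_mix = c(MZ = .5, DZ = .5)))
  fit <- fit_ace_lmm(ds)
  start_ll <- profile_loglik(ds, rep(var(unlist(lapply(ds$families,
                                                       `[[`, "y"))) / 3, 3))
  expect_gte(fit$loglik, start_ll$loglik)
  # permuting families changes nothing
  perm <- rev(seq_len(ds$m))
  ds_perm <- fam_dataset(ds$families[perm], ds$snp_ids, ds$covariate_names)
  fit_perm <- fit_ace_lmm(ds_perm)
  expect_equal(fit_perm$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(fit_perm$beta_g, fit$beta_g, tolerance = 1e-7)
  expect_equal(fit_perm$varcomp$sigma_a2, fit$varcomp$sigma_a2,
               tolerance = 1e-5)
})

test_that("fit degenerates to OLS with identity kinship", {
  # adopted-only families have Phi = I, so sigma_a2 and sigma_e2 are
  # confounded: only their sum is identified. The shared-environment
  # component and the fixed effects remain well determined.
  set.seed(31)
  cfg <- sim_config(m = 150, h = 0, varcomp = variance_components(1e-9, 1e-9, 1),
                    family_type_mix = c(adopted = 1))
  ds <- simulate_dataset(cfg)
  fit <- fit_ace_lmm(ds)
  expect_lt(fit$varcomp$sigma_c2, 0.1)
  expect_lt(abs(fit$varcomp$sigma_a2 + fit$varcomp$sigma_e2 - 1), 0.2)
  design <- evaluesnp:::ds_design(ds)
  ols <- lm.fit(design$X, design$y)
  expect_lt(max(abs(fit$coefficients - ols$coefficients)), 0.05)
})

test_that("variance components are recovered on average across simulations", {
  set.seed(97)
  reps <- 50
  est <- replicate(reps, {
    ds <- simulate_dataset(sim_config(m = 500, h = 0,
                                      family_type_mix = c(MZ = .5, DZ = .5)))
    vc <- fit_ace_lmm(ds)$varcomp
    c(vc$sigma_a2, vc$sigma_c2, vc$sigma_e2)
  })
  means <- rowMeans(est)
  expect_equal(means[1], 4, tolerance = 0.1)
  expect_equal(means[2], 1, tolerance = 0.1)
  expect_equal(means[3], 1, tolerance = 0.1)
})

test_that("restricted GLS refit agrees with a dense-matrix oracle", {
  ds <- toy_dataset(m = 10, p_g = 3, seed = 13)
  fit <- fit_ace_lmm(ds)
  # refit with all SNPs equals the full fit
  expect_equal(gls_refit(fit, 1:3)$beta_g, fit$beta_g, tolerance = 1e-10)
  # empty active set gives the zero SNP vector
  expect_equal(unname(gls_refit(fit, integer())$beta_g), rep(0, 3))
  expect_error(gls_refit(fit, 5), "range")
  # restricted refit = dense GLS on the restricted design at frozen varcomp
  for (active in list(1L, c(1L, 3L), 2L)) {
    keep <- evaluesnp:::keep_snps(ds, active)
    want <- dense_loglik(keep, fit$varcomp)$beta
    got <- gls_refit(fit, active)
    expect_equal(unname(got$alpha), want[1], tolerance = 1e-8)
    expect_equal(unname(got$beta_g[active]), want[-1], tolerance = 1e-8)
    expect_equal(unname(got$beta_g[-active]),
                 rep(0, 3 - length(active)))
  }
})
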