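test_that("evaluation maps hit their closed-form values", {
  mu <- c(1, -2, 3); sd_ <- c(1, 2, 0.5)
  expect_equal(evaluate_map(mu, mu, sd_, "E1"), 1)
  expect_equal(evaluate_map(mu, mu, sd_, "E2"), 1)
  # one coordinate one sd away: ||z|| = 1
  x <- mu + c(1, 0, 0) * sd_
  expect_equal(evaluate_map(x, mu, sd_, "E1"), 0.5)
  expect_equal(evaluate_map(x, mu, sd_, "E2"), exp(-1))
  # ||z|| = 2
  x2 <- mu + c(0, 2, 0) * sd_
  expect_equal(evaluate_map(x2, mu, sd_, "E1"), 0.2)
  expect_equal(evaluate_map(x2, mu, sd_, "E2"), exp(-2))
  expect_error(evaluate_map(x, mu, c(1, 0, 1), "E1"), "positive")
  expect_error(evaluate_map(x[1:2], mu, sd_), "length")
})

test_that("E1 dominates E2 everywhere and both stay in (0, 1]", {
  # 1/(1 + r^2) >= exp(-r) for all r >= 0 (exp(r) > 1 + r^2), with
  # equality only at r = 0
  set.seed(10)
  for (i in 1:50) {
    z <- rnorm(sample(2:10, 1)) * runif(1, 0.1, 3)
    e1 <- 1 / (1 + sum(z^2)); e2 <- exp(-sqrt(sum(z^2)))
    expect_true(e1 > 0 && e1 <= 1 && e2 > 0 && e2 <= 1)
    expect_gte(e1, e2)
  }
  expect_equal(evaluate_map(0, 0, 1, "E1"), evaluate_map(0, 0, 1, "E2"))
})

test_that("evaluation maps are coordinate-wise location-scale invariant", {
  set.seed(11)
  ref <- fake_ensemble(matrix(rnorm(300), 100, 3))
  ev <- fake_ensemble(matrix(rnorm(300, sd = 1.3), 100, 3))
  base <- evalue_distributions(ref, ev, "E2")
  a <- c(2, 0.5, 7); b <- c(-1, 3, 100)
  tr <- function(d) sweep(sweep(d, 2, a, "*"), 2, b, "+")
  trans <- evalue_distributions(fake_ensemble(tr(ref$draws)),
                                fake_ensemble(tr(ev$draws)), "E2")
  expect_equal(trans$e_star_samples, base$e_star_samples, tolerance = 1e-10)
  base1 <- evalue_distributions(ref, ev, "E1")
  trans1 <- evalue_distributions(fake_ensemble(tr(ref$draws)),
                                 fake_ensemble(tr(ev$draws)), "E1")
  expect_equal(trans1$e_star_samples, base1$e_star_samples,
               tolerance = 1e-10)
})

test_that("reduced_model_point zeroes exactly one coordinate", {
  expect_equal(reduced_model_point(c(1, 2, 3), 2), c(1, 0, 3))
  th <- c(0.5, 0, -1)
  expect_equal(reduced_model_point(th, 2), th)
  d <- 4; th <- rnorm(d)
  acc <- Reduce(`+`, lapply(seq_len(d), reduced_model_point, theta_draw = th))
  expect_equal(acc, (d - 1) * th)
  expect_error(reduced_model_point(th, 0), "range")
})

test_that("e-value distributions match a hand-computed toy ensemble", {
  ref <- fake_ensemble(rbind(c(0, 0), c(2, 2), c(1, 1)))
  ev <- fake_ensemble(rbind(c(1, 1), c(2, 0), c(0, 1)))
  summ <- evalue_distributions(ref, ev, "E2", q_set = 0.5)
  mu <- c(1, 1); sd_ <- c(1, 1)
  e_star <- apply(ev$draws, 1, evaluate_map, ref_mean = mu, ref_sd = sd_,
                  kind = "E2")
  expect_equal(unname(summ$e_star_samples), unname(e_star))
  expect_equal(summ$quantiles_star, quantile(e_star, 0.5, names = FALSE))
  e_minus_1 <- apply(ev$draws, 1, function(x) {
    evaluate_map(reduced_model_point(x, 1), mu, sd_, "E2")
  })
  expect_equal(unname(summ$e_minus_samples[1, ]), unname(e_minus_1))
  # a SNP whose draws and reference mean are zero scores like the full model
  ref0 <- fake_ensemble(cbind(rnorm(50), 0))
  ref0$ref_sd[2] <- 1  # bypass the degenerate-coordinate guard
  ev0 <- fake_ensemble(cbind(rnorm(50), 0))
  ev0$ref_sd[2] <- 1
  s0 <- evalue_distributions(ref0, ev0, "E2", q_set = c(0.5, 0.9))
  expect_equal(s0$e_minus_samples[2, ], unname(s0$e_star_samples))
})

test_that("quantile curves are monotone in q", {
  set.seed(12)
  ref <- fake_ensemble(matrix(rnorm(500), 100, 5))
  ev <- fake_ensemble(matrix(rnorm(500), 100, 5))
  summ <- evalue_distributions(ref, ev, "E1",
                               q_set = seq(0.1, 0.9, by = 0.1))
  expect_true(all(diff(summ$quantiles_star) >= 0))
  expect_true(all(apply(summ$quantiles_minus, 1,
                        function(r) all(diff(r) >= 0))))
})

test_that("quantile selection enforces the all-q conjunction and strictness", {
  qs <- seq(0.5, 0.9, 0.1)
  summ <- structure(list(
    quantiles_star = rep(0.5, 5),
    quantiles_minus = rbind(rep(0.1, 5),            # passes at all q
                            c(0.45, rep(0.1, 4)),   # fails only at q=0.5
                            rep(0.4, 5)),           # exactly at the boundary
    e_star_samples = runif(100), q_set = qs,
    snp_ids = c("a", "b", "c")), class = "evalue_summary")
  # SNP 3 sits exactly at t * c_q for t = 0.8: a tie is NOT selected
  expect_equal(select_snps_quantile(summ, 0.8), 1L)
  # at t = 0.9 SNP 3 clears the threshold; SNP 2 still fails at q = 0.5
  expect_equal(select_snps_quantile(summ, 0.9), c(1L, 3L))
  expect_error(select_snps_quantile(summ, 1.2), "0, 1")
})

test_that("selection sets shrink to empty as t decreases and are nested", {
  set.seed(13)
  ds <- simulate_dataset(small_sim(m = 60, h = 10))
  fit <- fit_ace_lmm(ds)
  ens <- gbs_ensemble(fit, gbs_config(s = 0.6, B_ref = 200, B_eval = 200,
                                      seed = 3))
  summ <- evalue_distributions(ens$reference, ens$evaluation, "E2")
  sel_small <- select_snps_quantile(summ, 0.5)
  sel_big <- select_snps_quantile(summ, 0.8)
  expect_true(all(sel_small %in% sel_big))
  expect_length(select_snps_quantile(summ, 1e-9), 0)
  # determinism: same seeds, same set
  ens2 <- gbs_ensemble(fit, gbs_config(s = 0.6, B_ref = 200, B_eval = 200,
                                       seed = 3))
  summ2 <- evalue_distributions(ens2$reference, ens2$evaluation, "E2")
  expect_identical(select_snps_quantile(summ2, 0.8), sel_big)
})

test_that("a strong-signal coordinate separates from the full model", {
  # reference moments with coordinate 1 ten sds from zero: zeroing it must
  # push the e-value distribution far left of the full model's
  set.seed(14)
  successes <- 0L
  for (r in 1:20) {
    ref <- fake_ensemble(cbind(rnorm(300, 10), rnorm(300), rnorm(300)))
    ev <- fake_ensemble(cbind(rnorm(300, 10), rnorm(300), rnorm(300)))
    summ <- evalue_distributions(ref, ev, "E2", q_set = 0.9)
    if (summ$quantiles_minus[1, 1] < summ$quantiles_star[1]) {
      successes <- successes + 1L
    }
  }
  expect_gte(successes, 20L * 0.99)
})

test_that("mean-functional selection is more liberal than the quantile rule", {
  set.seed(15)
  # identical reduced and full distributions: nothing selected
  d <- matrix(rnorm(300), 100, 3)
  ref <- fake_ensemble(d + rep(c(0, 0, 0), each = 100))
  ev <- fake_ensemble(matrix(rnorm(300), 100, 3))
  summ0 <- evalue_distributions(ref, ev, "E2")
  summ0$mean_minus <- rep(summ0$mean_star, 3)
  expect_length(select_snps_mean(summ0), 0)
  # weak-signal regime: the mean rule selects a superset of the t=0.5
  # quantile rule in the majority of runs
  superset <- 0L
  for (r in 1:9) {
    ds <- simulate_dataset(small_sim(m = 60, h = 1))
    fit <- fit_ace_lmm(ds)
    ens <- gbs_ensemble(fit, gbs_config(s = 0.5, B_ref = 150, B_eval = 150))
    summ <- evalue_distributions(ens$reference, ens$evaluation, "E2")
    if (all(select_snps_quantile(summ, 0.5) %in% select_snps_mean(summ))) {
      superset <- superset + 1L
    }
  }
  expect_gte(superset, 5L)
})
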