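test_that("solve_exact solves anchor systems and construct-then-invert cases", {
  # two sources, F14C only: (1.0 - 0.76) / (1.0 - 0.4) = 0.40
  f <- solve_exact(matrix(c(0.4, 1.0), 1,
                          dimnames = list(NULL, c("peat", "modern"))), 0.76)
  expect_equal(f, c(peat = 0.4, modern = 0.6))

  # mixture at a vertex of the simplex
  S <- rbind(d13c = c(-28, -29, -9.8), f14c = c(0.35, 1.02, 1.01))
  colnames(S) <- c("peat", "modern", "atmosphere")
  expect_equal(solve_exact(S, S[, 1]),
               c(peat = 1, modern = 0, atmosphere = 0))

  # three sources: compose the mixture from known fractions, invert
  m <- drop(S %*% c(0.4, 0.5, 0.1))
  expect_equal(solve_exact(S, m), c(peat = 0.4, modern = 0.5, atmosphere = 0.1),
               tolerance = 1e-10)

  # fractions are NOT clamped
  f_out <- solve_exact(matrix(c(0.4, 1.0), 1,
                              dimnames = list(NULL, c("peat", "modern"))), 1.2)
  expect_lt(f_out[["peat"]], 0)
  expect_equal(sum(f_out), 1)
})

test_that("solve_exact rejects collinear end members, naming them", {
  S <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("peat", "modern")))
  expect_error(solve_exact(S, 0.5), "peat.*modern|collinear")
  S3 <- rbind(c(-28, -28, -28), c(0.4, 0.4, 0.4))
  colnames(S3) <- c("a", "b", "c")
  expect_error(solve_exact(S3, c(-28, 0.4)), "singular|collinear")
  expect_error(solve_exact(matrix(c(0.4, 1.0), 1), c(0.7, 0.9)),
               "k - 1 tracers")
})

test_that("oracle equivalence: random simplex points are recovered to 1e-10", {
  set.seed(11)
  for (i in 1:200) {
    S <- random_three_source_system()
    f_true <- random_simplex(3)
    m <- drop(S %*% f_true)
    expect_equal(unname(solve_exact(S, m)), f_true, tolerance = 1e-10)
    # two-source case on the F14C row alone
    f2 <- random_simplex(2)
    S2 <- S[2, 1:2, drop = FALSE]
    expect_equal(unname(solve_exact(S2, drop(S2 %*% f2))), f2,
                 tolerance = 1e-10)
  }
})

test_that("degenerate Monte Carlo (all sds 0) equals the exact solution", {
  pr <- outgassing_problem(0.76)
  post <- run_monte_carlo(pr, n_iter = 500, seed = 7)
  expect_identical(unname(post$fractions_mean), unname(solve_exact(pr)))
  expect_identical(post$acceptance_rate, 1)
  expect_identical(unname(post$fractions_sd), c(0, 0))
})

test_that("Monte Carlo posterior matches the affine closed form", {
  # f_peat = (1 - F_mix) / 0.6 with F_mix ~ N(0.76, 0.02):
  # mean 0.40, sd 0.02 / 0.6 = 1/30
  pr <- outgassing_problem(0.76, mix_sd = 0.02)
  post <- run_monte_carlo(pr, n_iter = 100000, seed = 3)
  mc_se_mean <- (0.02 / 0.6) / sqrt(post$n_accepted)
  mc_se_sd <- (0.02 / 0.6) / sqrt(2 * post$n_accepted)
  expect_lt(abs(post$fractions_mean[["peat"]] - 0.4), 3 * mc_se_mean)
  expect_lt(abs(post$fractions_sd[["peat"]] - 1 / 30), 3 * mc_se_sd)
  expect_gt(post$acceptance_rate, 0.999)  # bounds are ~12 sigma away
})

test_that("retained draws satisfy the simplex and rejection contracts", {
  em <- list(end_member("peat", c(-28, 1), c(0.35, 0.15)),
             end_member("modern", c(-29, 1), c(1.02, 0.02)),
             end_member("atmosphere", c(-9.8, 0.1), c(1.01, 0.01)))
  mx <- mixture_obs("L", d13c = c(-23.5, 1.1), f14c = c(0.76, 0.02))
  pr <- mixing_problem("equilibration", em, mx)
  post <- run_monte_carlo(pr, n_iter = 20000, seed = 5, keep_draws = TRUE)
  expect_true(all(abs(rowSums(post$samples) - 1) < 1e-12))
  expect_true(all(post$samples >= 0 & post$samples <= 1))
  # brute-force re-filter of the raw draw log reproduces n_accepted
  raw <- post$draws
  ok <- rowSums(is.finite(raw) & raw >= 0 & raw <= 1) == ncol(raw)
  expect_identical(sum(ok), post$n_accepted)
  expect_lt(post$acceptance_rate, 1)  # this problem does reject some draws
})

test_that("Monte Carlo is deterministic given (problem, n_iter, seed)", {
  pr <- outgassing_problem(0.76, mix_sd = 0.05,
                           src_f14c = c(peat = 0.4, modern = 1.0))
  a <- run_monte_carlo(pr, n_iter = 5000, seed = 123)
  b <- run_monte_carlo(pr, n_iter = 5000, seed = 123)
  expect_identical(a, b)
  c <- run_monte_carlo(pr, n_iter = 5000, seed = 124)
  expect_false(identical(a$samples, c$samples))
})

test_that("infeasible mixtures raise the zero-acceptance error", {
  pr <- outgassing_problem(2.0, mix_sd = 0.01)
  expect_error(run_monte_carlo(pr, n_iter = 2000, seed = 1),
               "zero accepted draws.*acceptance_rate = 0")
  expect_error(run_monte_carlo(outgassing_problem(0.76), n_iter = 0, seed = 1),
               "n_iter")
})

test_that("inverse-variance combination matches closed forms", {
  # agreement fixed point
  cmb0 <- combine_inverse_variance(list(mean = 0.4, sd = 0.2),
                                   list(mean = 0.4, sd = 0.01))
  expect_equal(cmb0$mean, 0.4)
  # equal weights
  cmb1 <- combine_inverse_variance(list(mean = 0.3, sd = 0.1),
                                   list(mean = 0.5, sd = 0.1))
  expect_equal(cmb1$mean, 0.4)
  expect_equal(cmb1$sd, sqrt(1 / 200), tolerance = 1e-12)  # ~0.0707
  # weights 400 and 100
  cmb2 <- combine_inverse_variance(list(mean = 0.3, sd = 0.05),
                                   list(mean = 0.5, sd = 0.10))
  expect_equal(cmb2$mean, 0.34)
  expect_equal(cmb2$sd, sqrt(1 / 500), tolerance = 1e-12)  # ~0.0447
  expect_error(combine_inverse_variance(list(mean = 0.3, sd = 0),
                                        list(mean = 0.5, sd = 0.1)),
               "s.d. must be > 0")
})

test_that("combined mean is bounded and moves monotonically with precision", {
  set.seed(21)
  for (i in 1:50) {
    m <- sort(stats::runif(2))
    s <- stats::runif(2, 0.01, 0.3)
    cmb <- combine_inverse_variance(list(mean = m[1], sd = s[1]),
                                    list(mean = m[2], sd = s[2]))
    expect_gte(cmb$mean, m[1])
    expect_lte(cmb$mean, m[2])
  }
  # shrinking model a's sd pulls the combined mean toward model a
  sds <- c(0.2, 0.1, 0.05, 0.02, 0.01)
  means <- vapply(sds, function(s) {
    combine_inverse_variance(list(mean = 0.3, sd = s),
                             list(mean = 0.5, sd = 0.1))$mean
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("pooled-posterior sd mode works on real posterior summaries", {
  pr <- outgassing_problem(0.76, mix_sd = 0.02)
  a <- run_monte_carlo(pr, n_iter = 20000, seed = 1)
  b <- run_monte_carlo(pr, n_iter = 20000, seed = 2)
  pooled <- combine_inverse_variance(a, b, source = "peat",
                                     sd_mode = "pooled")
  analytic <- combine_inverse_variance(a, b, source = "peat")
  expect_equal(pooled$mean, analytic$mean)
  # pooled spread reflects within-model spread, not the analytic 1/sqrt(sum w)
  expect_gt(pooled$sd, analytic$sd)
  expect_lt(abs(pooled$sd - 1 / 30), 0.005)
  expect_error(combine_inverse_variance(a, b, source = "atmosphere"),
               "not present")
})

test_that("consistency_check applies the k-sigma rule", {
  expect_true(consistency_check(list(mean = 0.4, sd = 0.1),
                                list(mean = 0.4, sd = 0.1))$consistent)
  # headline-style values: 0.39 +/- 0.08 vs 0.40 +/- 0.06
  rep1 <- consistency_check(list(mean = 0.39, sd = 0.08),
                            list(mean = 0.40, sd = 0.06))
  expect_true(rep1$consistent)
  expect_equal(rep1$delta, 0.01)
  expect_equal(rep1$threshold, sqrt(0.08^2 + 0.06^2))
  expect_false(consistency_check(list(mean = 0.2, sd = 0.01),
                                 list(mean = 0.5, sd = 0.01))$consistent)
  # boundary: delta exactly k * pooled counts as consistent
  # (5 = sqrt(3^2 + 4^2), all representable exactly)
  expect_true(consistency_check(list(mean = 0, sd = 3),
                                list(mean = 5, sd = 4))$consistent)
})

test_that("problem construction enforces model arity", {
  em2 <- noise_free_sources()
  em3 <- c(em2, list(end_member("atmosphere", c(-9.8, 0.1), c(1.01, 0.01))))
  mx <- mixture_obs("L", d13c = c(-25, 0.5), f14c = c(0.8, 0.02))
  expect_error(mixing_problem("equilibration", unname(em2), mx), "3 sources")
  expect_error(mixing_problem("outgassing", unname(em3), mx), "2 sources")
  expect_identical(mixing_problem("outgassing", unname(em2), mx)$tracers,
                   "f14c")
  expect_identical(mixing_problem("equilibration", unname(em3), mx)$tracers,
                   c("d13c", "f14c"))
  expect_error(end_member("x", c(-28, -1), c(0.4, 0)), "sds")
  expect_error(end_member("x", c(-28, 1), c(-0.4, 0.1)), "F14C")
})
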