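test_that("noise-free generation is exactly the linear blend", {
  spec <- scenario_spec(
    true_fractions = c(peat = 0.4, modern = 0.5, atmosphere = 0.1),
    end_members = list(
      end_member("peat", c(-28, 0), c(0.35, 0)),
      end_member("modern", c(-29, 0), c(1.02, 0)),
      end_member("atmosphere", c(-9.8, 0), c(1.01, 0))
    ),
    measurement_noise = c(d13c = 0, f14c = 0),
    n_replicates = 5, seed = 2
  )
  tab <- generate_mixture_table(spec)
  dic <- tab[tab$pool == "DIC", ]
  expect_equal(unique(dic$d13c), 0.4 * -28 + 0.5 * -29 + 0.1 * -9.8)
  expect_equal(unique(dic$f14c), 0.4 * 0.35 + 0.5 * 1.02 + 0.1 * 1.01)
  expect_identical(nrow(dic), 5L)
})

test_that("tables are reproducible bit-for-bit from (spec, seed)", {
  spec <- default_scenario(seed = 33)
  t1 <- generate_mixture_table(spec)
  t2 <- generate_mixture_table(spec)
  expect_identical(t1, t2)
  t3 <- generate_mixture_table(spec, seed = 34)
  expect_false(identical(t1$f14c, t3$f14c))
  # generator-side truncation: F14C never non-positive despite wide peat sd
  wide <- default_scenario(seed = 1, n_replicates = 2000)
  tw <- generate_mixture_table(wide)
  expect_true(all(tw$f14c[tw$pool == "SOC"] > 0))
})

test_that("empirical mixture means converge to the blend (law of large numbers)", {
  spec <- default_scenario(seed = 8, n_replicates = 10000)
  tab <- generate_mixture_table(spec)
  dic <- tab[tab$pool == "DIC", ]
  # expected mixture mean: fraction-weighted end-member means; the peat
  # F14C mean is shifted by the generator's truncation at 0, by the
  # closed form for a below-truncated normal (independent oracle)
  exp_d13c <- 0.4 * -28 + 0.5 * -29 + 0.1 * -9.8
  trunc_mean <- function(mu, sd) {
    a <- -mu / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
  }
  exp_f14c <- 0.4 * trunc_mean(0.35, 0.15) + 0.5 * 1.02 + 0.1 * 1.01
  sd_f14c <- sqrt(0.4^2 * 0.15^2 + 0.5^2 * 0.02^2 + 0.1^2 * 0.01^2 + 0.01^2)
  expect_lt(abs(mean(dic$d13c) - exp_d13c), 4 * 1 / sqrt(10000))
  expect_lt(abs(mean(dic$f14c) - exp_f14c), 4 * sd_f14c / sqrt(10000))
})

test_that("forward-inverse consistency: exact solver recovers true fractions", {
  set.seed(14)
  for (i in 1:25) {
    f_true <- random_simplex(3)
    S <- random_three_source_system()
    spec <- scenario_spec(
      true_fractions = stats::setNames(f_true, colnames(S)),
      end_members = lapply(colnames(S), function(nm) {
        end_member(nm, c(S["d13c", nm], 0), c(S["f14c", nm], 0))
      }),
      measurement_noise = c(d13c = 0, f14c = 0),
      n_replicates = 1, seed = i
    )
    tab <- generate_mixture_table(spec)
    dic <- tab[tab$pool == "DIC", ]
    expect_equal(unname(solve_exact(S, c(dic$d13c, dic$f14c))), f_true,
                 tolerance = 1e-10)
  }
})

test_that("scenario validation rejects malformed worlds", {
  ems <- list(end_member("peat", c(-28, 1), c(0.35, 0.15)),
              end_member("modern", c(-29, 1), c(1.02, 0.02)))
  expect_error(scenario_spec(c(peat = 0.6, modern = 0.6), ems), "sum to 1")
  expect_error(scenario_spec(c(peat = 1.2, modern = -0.2), ems), ">= 0")
  expect_error(scenario_spec(c(peat = 0.5, other = 0.5), ems),
               "match end-member names")
})

test_that("recovery experiment is deterministic and exact in the degenerate world", {
  # atmosphere fraction must be 0 here: with sds = 0, the two-source
  # outgassing model is exact only when the mixture truly contains no
  # atmospheric carbon, otherwise the two models disagree deterministically
  spec <- scenario_spec(
    true_fractions = c(peat = 0.4, modern = 0.6, atmosphere = 0),
    end_members = list(
      end_member("peat", c(-28, 0), c(0.35, 0)),
      end_member("modern", c(-29, 0), c(1.02, 0)),
      end_member("atmosphere", c(-9.8, 0), c(1.01, 0))
    ),
    measurement_noise = c(d13c = 0, f14c = 0),
    n_replicates = 4, seed = 3
  )
  rep <- recovery_experiment(spec, n_datasets = 3, n_iter = 200, seed = 5)
  expect_equal(rep$bias, 0, tolerance = 1e-10)
  expect_equal(rep$rmse, 0, tolerance = 1e-10)
  expect_identical(rep$coverage, 1)
  rep2 <- recovery_experiment(spec, n_datasets = 3, n_iter = 200, seed = 5)
  expect_identical(rep$estimates, rep2$estimates)
})

test_that("single-dataset recovery equals the run_full_analysis path", {
  spec <- default_scenario(seed = 6)
  rep <- recovery_experiment(spec, n_datasets = 1, n_iter = 2000, seed = 6)
  seeds <- rep$estimates$table_seed
  tab <- generate_mixture_table(spec, seed = seeds[1])
  summ <- summarize_pools(tab)
  em_cfg <- lapply(spec$end_members, function(em) {
    s <- summ[summ$pool == spec$pool_map[[em$name]], ]
    list(name = em$name, d13c = c(s$d13c_mean, s$d13c_sd),
         f14c = c(s$f14c_mean, s$f14c_sd))
  })
  dic <- summ[summ$pool == "DIC", ]
  report <- run_full_analysis(list(
    end_members = em_cfg,
    mixture = list(label = "lake", d13c = c(dic$d13c_mean, dic$d13c_sd),
                   f14c = c(dic$f14c_mean, dic$f14c_sd)),
    model = "both", n_iter = 2000, seed = seeds[1] + 1
  ))
  expect_identical(report$combined$mean, rep$estimates$combined_mean[1])
  expect_identical(report$combined$sd, rep$estimates$combined_sd[1])
})
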