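test_that("effect sizes invert the variance-explained definitions", {
  eff <- solve_effect_sizes(0, 0, var_g = 0.18)
  expect_equal(unname(eff), c(0, 0))
  eff <- solve_effect_sizes(1e-4, 1e-3, var_g = 0.18)
  expect_equal(round(unname(eff), 3), c(0.049, 0.088))
  # exact round trip through the h^2 formulas
  A <- 4.321370; sg <- 3.103259
  h2d <- eff[["beta_d"]]^2 * 0.18 / (A + eff[["beta_d"]]^2 * 0.18)
  h2i <- sg * eff[["beta_i"]]^2 * 0.18 / (A + sg * eff[["beta_i"]]^2 * 0.18)
  expect_equal(h2d, 1e-4, tolerance = 1e-12)
  expect_equal(h2i, 1e-3, tolerance = 1e-12)
  expect_error(solve_effect_sizes(1, 0.5, 0.18), "\\[0, 1\\)")
})

test_that("configuration honours the aggregate constraints", {
  cfg <- sim_config()
  expect_equal(sum(cfg$gamma^2), cfg$s_gamma, tolerance = 1e-12)
  expect_equal(-sum(cfg$gamma[seq_len(cfg$k)]), cfg$s_indirect,
               tolerance = 1e-12)
  expect_equal(cfg$alpha_sex^2 * 0.25 + cfg$s_gamma + cfg$var_eps, cfg$A,
               tolerance = 1e-12)
  desk <- sim_config(preset = "desk")
  expect_equal(desk$n_pop, 30000L)
  expect_equal(desk$reps, 1000L)
  expect_error(sim_config(n_m = 999), "even")
  expect_error(sim_config(k = 60), "exceed")
})

test_that("population generation matches its design moments", {
  set.seed(61)
  cfg <- sim_config(n_pop = 50000L, nu = 0, h2_d = 0, h2_i = 0)
  pop <- generate_population(cfg)
  n <- cfg$n_pop
  # allele frequency
  expect_lt(abs(mean(pop$G) / 2 - 0.1), 3 * sqrt(0.1 * 0.9 / (2 * n)))
  # no mediation path at nu = 0: traits uncorrelated with genotype
  cors <- abs(cor(pop$G, pop$X))
  expect_lt(max(cors), 4 / sqrt(n))
  # global null: genotype uncorrelated with outcome
  expect_lt(abs(cor(pop$G, pop$y)), 3 / sqrt(n))
  # traits standard normal
  expect_lt(max(abs(colMeans(pop$X))), 4 / sqrt(n))
  expect_lt(max(abs(apply(pop$X[, 1:5], 2, sd) - 1)), 0.02)

  # with mediation the affected traits shift by -nu * beta_i per allele
  cfg2 <- sim_config(n_pop = 50000L, nu = 1, h2_d = 1e-4, h2_i = 1e-3)
  pop2 <- generate_population(cfg2)
  eff <- solve_effect_sizes(1e-4, 1e-3, 0.18)
  d <- mean(pop2$X[pop2$G == 2, 1]) - mean(pop2$X[pop2$G == 0, 1])
  expect_lt(abs(d - (-2 * eff[["beta_i"]])), 0.05)
  d45 <- mean(pop2$X[pop2$G == 2, 45]) - mean(pop2$X[pop2$G == 0, 45])
  expect_lt(abs(d45), 0.1)
})

test_that("study sampling gives the designed composition", {
  set.seed(62)
  cfg <- sim_config(n_pop = 30000L, n_m = 1000L)
  pop <- generate_population(cfg)
  st <- sample_study(pop)
  expect_length(st$labeled, 10000)
  expect_length(st$masked, 1000)
  expect_equal(sum(st$truth), 500)           # masked truth balanced
  expect_length(intersect(st$labeled, st$masked), 0)
  expect_equal(sum(pop$y[st$labeled]), 5000)
  st0 <- sample_study(pop, n_m = 0)
  expect_length(st0$masked, 0)
  tiny <- pop; tiny$y <- rep(0L, cfg$n_pop)
  expect_error(sample_study(structure(tiny, class = "wip_population")),
               "prevalence")
})

test_that("replicates with no masked subjects reduce IP/WIP to LR exactly", {
  set.seed(63)
  cfg <- sim_config(preset = "desk", n_m = 0L, h2_d = 1e-4, h2_i = 1e-3,
                    nu = 0.5)
  r <- run_replicate(cfg)
  expect_equal(r$p[r$method == "ip"], r$p[r$method == "lr"])
  expect_equal(r$p[r$method == "wip"], r$p[r$method == "lr"])
  expect_equal(r$beta[r$method == "wip"], r$beta[r$method == "lr"])
})

test_that("rejection-rate estimator reproduces the binomial standard error", {
  # the parenthetical of a printed 0.0507 at 10 000 replicates
  p <- c(rep(0.01, 507), rep(0.5, 10000 - 507))
  er <- estimate_rates(p, alpha = 0.05)
  expect_equal(er$rate, 0.0507)
  expect_equal(round(er$se, 4), 0.0022)
  # a printed 0.1590 gives 0.0037 (0.0036 printed under rounding)
  se2 <- sqrt(0.1590 * (1 - 0.1590) / 10000)
  expect_lt(abs(se2 - 0.00366), 5e-5)
  er3 <- estimate_rates(rep(0, 100), alpha = 0.05)
  expect_equal(er3$rate, 1)
  expect_equal(er3$se, 0)
})

test_that("collapsed and full trait generation are statistically equivalent", {
  cfg <- sim_config(preset = "desk", nu = 0.5, h2_d = 1e-4, h2_i = 1e-3,
                    n_m = 2500L)
  run_z <- function(traits, seed, reps = 60) {
    set.seed(seed)
    eff <- solve_effect_sizes(cfg$h2_d, cfg$h2_i, 0.18)
    vapply(seq_len(reps), function(r)
      run_replicate(cfg, eff, traits = traits)$z, numeric(3))
  }
  z_c <- run_z("collapsed", 641)
  z_f <- run_z("full", 642)
  # same mean signal per method within Monte-Carlo error
  for (m in 1:3) {
    se <- sqrt(var(z_c[m, ]) / 60 + var(z_f[m, ]) / 60)
    expect_lt(abs(mean(z_c[m, ]) - mean(z_f[m, ])), 3.5 * se)
  }
})

test_that("identical seed and config reproduce the experiment bit-for-bit", {
  cfg <- sim_config(preset = "desk", nu = 0.3, h2_d = 1e-4, h2_i = 1e-3)
  s1 <- run_simulation(cfg, reps = 5, seed = 99, n_m = c(1000, 5000))
  s2 <- run_simulation(cfg, reps = 5, seed = 99, n_m = c(1000, 5000))
  expect_identical(s1$table, s2$table)
})

test_that("null replicate p-values are uniform and rates nominal", {
  sim <- cached_null_run()
  reps <- sim$reps
  key <- sim$replicates$key
  # two-sided p-values per method at n_m = 5000 pass KS uniformity at 0.01
  for (m in c("lr", "ip", "wip")) {
    j <- which(key$method == m & key$n_m == 5000)
    p2 <- 2 * pnorm(-abs(sim$replicates$z[, j]))
    expect_gt(suppressWarnings(ks.test(p2, "punif")$p.value), 0.01)
  }
  # directional counting is nominal at every level and n_m
  tab <- sim$table
  for (i in seq_len(nrow(tab)))
    expect_lt(abs(tab$rate[i] - tab$alpha[i]),
              3 * sqrt(tab$alpha[i] * (1 - tab$alpha[i]) / reps) + 1e-9)
})

test_that("weighting gives (slightly) stronger evidence than plain imputation", {
  grid <- cached_power_grid()          # nu = 0, 0.3, 0.5, 0.8, 1
  wins <- 0L; cells <- 0L
  for (s in grid[-1]) {                # alternatives with nu >= 0.3
    key <- s$replicates$key
    for (nm in c(1000, 2500, 5000)) {
      j_ip <- which(key$method == "ip" & key$n_m == nm)
      j_wip <- which(key$method == "wip" & key$n_m == nm)
      p_ip <- pnorm(-s$replicates$z[, j_ip])
      p_wip <- pnorm(-s$replicates$z[, j_wip])
      cells <- cells + 1L
      if (mean(p_wip) <= mean(p_ip)) wins <- wins + 1L
    }
  }
  expect_gte(wins, ceiling(0.75 * cells))
})

test_that("power is monotone in the mediation weight for every method", {
  grid <- cached_power_grid()
  for (m in c("lr", "ip", "wip")) {
    r <- vapply(grid, cell_rate, numeric(1), method = m, n_m = 5000)
    # allow inversions within Monte-Carlo noise but require a clear trend
    expect_gt(r[5], r[1])
    expect_true(all(diff(r) > -0.02))
  }
  # at nu = 0 extra imputed subjects hurt; at nu = 1 they help
  g0 <- grid[[1]]; g1 <- grid[[5]]
  expect_lt(cell_rate(g0, "ip", 5000), cell_rate(g0, "ip", 1000) + 0.01)
  expect_gt(cell_rate(g1, "wip", 5000), cell_rate(g1, "wip", 1000))
})
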