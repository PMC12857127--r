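test_that("truth functions reproduce hand-evaluated values", {
  tp <- truth_probs(c(0.3, 0))
  expect_equal(unname(tp["lambda_2"]),
               0.25 * (0.5 * 0.027 / (0.027 + 0.027) + 0.05),
               tolerance = 1e-12)
  expect_equal(unname(tp["lambda_2"]), 0.075, tolerance = 1e-12)
  tp0 <- truth_probs(c(0, 0))
  expect_equal(unname(tp0["lambda_3"]), (2 / 3) * (exp(-4) + 0.15),
               tolerance = 1e-12)
  expect_equal(unname(tp0["lambda_3"]), 0.11221, tolerance = 1e-4)
  # complement identity on a grid
  grid <- as.matrix(expand.grid(seq(0, 1, 0.1), seq(0, 1, 0.1)))
  tg <- truth_probs(grid)
  expect_equal(rowSums(tg), rep(1, nrow(tg)), tolerance = 1e-14)
  expect_true(all(tg >= 0))
  expect_error(truth_probs(c(1.2, 0)), "\\[0, 1\\]")
})

test_that("proportional noise scales, clips, and keeps the simplex", {
  g <- cbind(c(0.1, 0.4), c(0.2, 0.5))
  same <- apply_proportional_noise(g, c(0, 0))
  expect_equal(unname(same[, 1:2]), g, ignore_attr = TRUE)
  scaled <- apply_proportional_noise(g, c(0.1, -0.1))
  expect_equal(scaled[1, 1], 0.11, tolerance = 1e-12)
  expect_equal(scaled[1, 2], 0.18, tolerance = 1e-12)
  # pathological draw: row total forced under 1
  big <- apply_proportional_noise(cbind(0.6, 0.5), c(0.5, 0.5))
  expect_lte(sum(big), 1 - 1e-9 + 1e-15)
  expect_equal(attr(big, "stay"), 1 - sum(big))
})

test_that("dataset-level noise has the configured spread", {
  set.seed(31)
  draws <- replicate(10000, rnorm(1, 0, 0.05))
  g <- matrix(0.2, 1, 1)
  ratio <- vapply(draws, function(e)
    apply_proportional_noise(g, e)[1, 1] / 0.2 - 1, numeric(1))
  expect_lt(abs(sd(ratio) - 0.05) / 0.05, 0.05)
})

test_that("transition times are geometric with the right destination mix", {
  lam <- matrix(rep(c(0.25, 0.25), each = 1e5), ncol = 2)
  set.seed(42)
  s <- sample_transition_times(lam)
  p_hat <- mean(s$destination_idx == 1)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_lt(abs(mean(s$k_star) - 2), 3 * sqrt((1 - 0.5) / 0.5^2 / 1e5))
  expect_gte(min(s$k_star), 1)
  # goodness of fit of the time distribution to Geometric(0.5)
  tab <- table(factor(pmin(s$k_star, 8), levels = 1:8))
  expected <- c(0.5 * 0.5^(0:6), 0.5^7) * 1e5
  chi <- sum((as.numeric(tab) - expected)^2 / expected)
  expect_lt(chi, qchisq(1 - 1e-6, df = 7))

  # deterministic edge cases
  sure <- sample_transition_times(matrix(c(1 - 1e-12, 0), 1))
  expect_equal(sure$destination_idx, 1L)
  expect_equal(sure$k_star, 1)
  never <- sample_transition_times(matrix(c(0, 0), 1), max_time = 50)
  expect_true(never$truncated)
  expect_equal(never$k_star, 50)
})

test_that("censoring produces the documented record types and rates", {
  cfg <- simulation_config(20000, seed = 3)
  set.seed(17)
  sampled <- data.frame(destination_idx = rep(1:2, 10000),
                        k_star = rpois(20000, 3) + 1,
                        truncated = FALSE)
  obs <- censor_observations(sampled, cfg)
  frac <- mean(obs$event == 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 20000))
  ev <- obs$event == 1
  expect_true(all(obs$time_kind[ev] == "interval"))
  expect_true(all(obs$k1[ev] >= 0))
  expect_true(all(obs$k1[ev] < obs$k2[ev]))
  expect_true(all(obs$k1[ev] < sampled$k_star[ev] + 1e-9))
  expect_true(all(obs$k2[ev] >= sampled$k_star[ev]))
  cens <- obs$event == 0
  expect_true(all(obs$k_star[cens] >= 0))
  expect_true(all(obs$k_star[cens] <= sampled$k_star[cens]))
})

test_that("generated datasets are valid, reproducible, and truth-aligned", {
  cfg <- simulation_config(400, seed = 23)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.data.frame(a$observations), as.data.frame(b$observations))
  expect_identical(a$truth, b$truth)
  c2 <- simulate_dataset(simulation_config(400, seed = 24))
  expect_false(identical(a$truth, c2$truth))

  expect_equal(nrow(a$truth), 400)
  expect_equal(a$truth$stay + a$truth$lambda_2 + a$truth$lambda_3,
               rep(1, 400), tolerance = 1e-12)
  # observations pass the type validator by construction (re-validate)
  expect_silent(as_transition_data(as.data.frame(a$observations),
                                   structure = attr(a$observations,
                                                    "structure")))
  # fixed epsilon override shares the perturbed truth across datasets
  d <- simulate_dataset(simulation_config(100, seed = 31),
                        epsilon = a$epsilon)
  expect_identical(d$epsilon, a$epsilon)
})

test_that("destination split matches the generating probabilities", {
  cfg <- simulation_config(100000, seed = 77, noise_sd = 0,
                           right_censor_prob = 0,
                           truth_functions = constant_truth(c(0.1, 0.3)))
  ds <- simulate_dataset(cfg)
  share2 <- mean(ds$observations$destination == 2)
  expect_lt(abs(share2 - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
})
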