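test_that("log posterior equals an independently computed small-problem value", {
  # K = 2, one consumer, hand-set numbers
  src <- two_sources(mu1 = c(-22, 4), mu2 = c(-17, -2),
                     sd1 = c(0.5, 1.0), sd2 = c(1.0, 0.5))
  tdf <- tibble::tibble(guild = "g", isotope = c("C13", "N15"),
                        mean = c(-0.5, 2.0), sd = c(1.0, 2.0))
  pr <- mixing_problem(consumer_at(-19.5, 4.0, guild = "g"), src, tdf)
  p <- c(0.3, 0.7)

  # oracle: two Gaussian log densities plus the flat-Dirichlet constant,
  # assembled from scratch
  m_c <- 0.3 * (-22 - 0.5) + 0.7 * (-17 - 0.5)
  m_n <- 0.3 * (4 + 2.0) + 0.7 * (-2 + 2.0)
  s2_c <- 0.3^2 * (0.5^2 + 1^2) + 0.7^2 * (1^2 + 1^2)
  s2_n <- 0.3^2 * (1^2 + 2^2) + 0.7^2 * (0.5^2 + 2^2)
  oracle <- lgamma(2) +
    dnorm(-19.5, m_c, sqrt(s2_c), log = TRUE) +
    dnorm(4.0, m_n, sqrt(s2_n), log = TRUE)

  expect_equal(log_unnormalized_posterior(p, pr), oracle, tolerance = 1e-12)
})

test_that("log posterior cannot tell identical sources apart", {
  # with identical source distributions the posterior is exchangeable in p:
  # swapping the proportions leaves it unchanged, so inference can only
  # return the prior's symmetric answer
  src <- two_sources(mu1 = c(-20, 5), mu2 = c(-20, 5))
  pr <- mixing_problem(consumer_at(-19, 6), src, zero_tdf())
  for (f in seq(0.05, 0.45, by = 0.1)) {
    expect_equal(log_unnormalized_posterior(c(f, 1 - f), pr),
                 log_unnormalized_posterior(c(1 - f, f), pr),
                 tolerance = 1e-12)
  }
  g <- grid_posterior_mean(pr, resolution = 0.005)
  expect_equal(g$mean, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("log posterior rejects off-simplex and degenerate inputs", {
  pr <- symmetric_problem()
  expect_error(log_unnormalized_posterior(c(0.6, 0.6), pr),
               class = "ventmix_input_error")
  expect_error(log_unnormalized_posterior(c(1.2, -0.2), pr),
               class = "ventmix_input_error")
  degen <- mixing_problem(consumer_at(-15, 10),
                          two_sources(sd1 = c(0, 0), sd2 = c(0, 0)),
                          zero_tdf())
  expect_error(log_unnormalized_posterior(c(0.5, 0.5), degen),
               class = "ventmix_degenerate_error")
  expect_error(fit_mixing(degen, iterations = 4000, burn_in = 500, thin = 2),
               class = "ventmix_degenerate_error")
})

test_that("grid oracle returns the prior mean for identical sources", {
  src <- tibble::tibble(
    name = c("a", "b", "c"),
    d13c_mean = -20, d13c_sd = 1, d15n_mean = 5, d15n_sd = 1
  )
  pr <- mixing_problem(consumer_at(-19, 6), src, zero_tdf())
  g <- grid_posterior_mean(pr, resolution = 0.02)
  expect_equal(g$mean, rep(1 / 3, 3), tolerance = 0.02)
})

test_that("grid oracle self-converges as the lattice refines", {
  pr <- kst_preset()$ep_crustacean_venting
  coarse <- grid_posterior_mean(pr, resolution = 0.02)
  fine <- grid_posterior_mean(pr, resolution = 0.002)
  expect_equal(coarse$mean, fine$mean, tolerance = 0.002)
})

test_that("grid oracle refuses problems too large to enumerate", {
  src <- tibble::tibble(
    name = letters[1:5],
    d13c_mean = seq(-25, -15, length.out = 5), d13c_sd = 1,
    d15n_mean = seq(0, 10, length.out = 5), d15n_sd = 1
  )
  pr <- mixing_problem(consumer_at(-20, 5), src, zero_tdf())
  expect_error(grid_posterior_mean(pr), class = "ventmix_capability_error")
})

test_that("MCMC is reproducible under a seed and symmetric when the problem is", {
  pr <- symmetric_problem()
  f1 <- fit_mixing(pr, iterations = 60000, burn_in = 5000, thin = 5, seed = 7)
  f2 <- fit_mixing(pr, iterations = 60000, burn_in = 5000, thin = 5, seed = 7)
  expect_identical(f1$draws$proportion, f2$draws$proportion)
  f3 <- fit_mixing(pr, iterations = 60000, burn_in = 5000, thin = 5, seed = 8)
  expect_false(identical(f1$draws$proportion, f3$draws$proportion))

  expect_equal(posterior_mean_of(f1, "s1"), 0.5, tolerance = 0.01)
  expect_equal(posterior_mean_of(f1, "s2"), 0.5, tolerance = 0.01)
})

test_that("relabeling the sources permutes the posterior means", {
  src <- two_sources(mu1 = c(-22, 4), mu2 = c(-17, -2))
  cons <- consumer_at(-19.5, 2.5)
  f_ab <- fit_mixing(mixing_problem(cons, src, zero_tdf()),
                     iterations = 100000, burn_in = 10000, thin = 5, seed = 3)
  f_ba <- fit_mixing(mixing_problem(cons, src[2:1, ], zero_tdf()),
                     iterations = 100000, burn_in = 10000, thin = 5, seed = 3)
  expect_equal(posterior_mean_of(f_ab, "s1"), posterior_mean_of(f_ba, "s1"),
               tolerance = 0.01)
  expect_equal(posterior_mean_of(f_ab, "s2"), posterior_mean_of(f_ba, "s2"),
               tolerance = 0.01)
})

test_that("MCMC agrees with the grid oracle on a two-source problem", {
  pr <- kst_preset()$ep_crustacean_venting
  fit <- fit_mixing(pr, seed = 5)
  grid <- grid_posterior_mean(pr, resolution = 0.005)
  expect_equal(posterior_mean_of(fit, "vent_pom"),
               grid$mean[grid$source == "vent_pom"], tolerance = 0.01)
})

test_that("vent-POM share rises monotonically as the consumer approaches vent POM", {
  pom <- kst_sources(c("seawater_pom", "vent_pom"))
  d13c_seq <- seq(-23, -19, by = 1)
  shares <- sapply(d13c_seq, function(x) {
    pr <- mixing_problem(consumer_at(x, 4, guild = "herbivore"), pom)
    g <- grid_posterior_mean(pr, resolution = 0.005)
    g$mean[g$source == "vent_pom"]
  })
  expect_true(all(diff(shares) > 0))
})

test_that("the posterior collapses to the analytic point as variances vanish", {
  eps <- 1e-3
  src <- two_sources(mu1 = c(-20, 8), mu2 = c(-10, 2),
                     sd1 = c(eps, eps), sd2 = c(eps, eps))
  tdf <- zero_tdf()
  # consumer exactly on the mixing line at f1 = 0.3
  cons <- consumer_at(0.3 * -20 + 0.7 * -10, 0.3 * 8 + 0.7 * 2)
  f_analytic <- analytic_two_source_point(cons, src,
                                          tdf_for_guild(tdf, "consumer"),
                                          "C13")
  expect_equal(f_analytic, 0.3, tolerance = 1e-12)
  fit <- fit_mixing(mixing_problem(cons, src, tdf),
                    iterations = 200000, burn_in = 30000, thin = 5, seed = 2)
  expect_equal(posterior_mean_of(fit, "s1"), 0.3, tolerance = 0.01)
})

test_that("the analytic two-source point matches hand mass balance", {
  pom <- kst_sources(c("vent_pom", "seawater_pom"))
  herb <- tdf_for_guild(kst_tdf(), "herbivore")
  f <- analytic_two_source_point(consumer_at(-21.0, 6.0), pom, herb, "C13")
  expect_equal(f, 2.81 / 5.2, tolerance = 1e-12)

  # consumer sitting exactly on a TDF-shifted source is a pure diet
  at_1 <- consumer_at(-18.2 + herb$mean[1], 0)
  expect_equal(analytic_two_source_point(at_1, pom, herb, "C13"), 1)
  at_2 <- consumer_at(-23.4 + herb$mean[1], 0)
  expect_equal(analytic_two_source_point(at_2, pom, herb, "C13"), 0)

  same <- two_sources(mu1 = c(-20, 5), mu2 = c(-20, 9))
  expect_error(
    analytic_two_source_point(consumer_at(-20, 7), same, herb, "C13"),
    class = "ventmix_input_error"
  )
})

test_that("every retained draw lies on the simplex", {
  pr <- kst_preset()$crab_mean # K = 3
  fit <- fit_mixing(pr, iterations = 40000, burn_in = 4000, thin = 10,
                    seed = 9)
  wide <- tidyr::pivot_wider(fit$draws, names_from = "source",
                             values_from = "proportion")
  P <- as.matrix(wide[, pr$sources$name])
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
  means <- tidy(fit)$mean
  expect_equal(sum(means), 1, tolerance = 1e-9)
})

test_that("consumers outside the TDF-shifted source range are flagged", {
  pom <- kst_sources(c("seawater_pom", "vent_pom"))
  inside <- fit_mixing(
    mixing_problem(consumer_at(-20, 4, guild = "herbivore"), pom),
    iterations = 8000, burn_in = 1000, thin = 4, seed = 1
  )
  expect_false(any(inside$out_of_polygon$out_of_polygon))
  # the heaviest crab lies beyond even the vent-POM end member
  outside <- fit_mixing(
    mixing_problem(consumer_at(-13.9, 1.1, guild = "herbivore"), pom),
    iterations = 8000, burn_in = 1000, thin = 4, seed = 1
  )
  expect_true(all(outside$out_of_polygon$out_of_polygon))
})

test_that("problem validation enforces the model's preconditions", {
  pom <- kst_sources(c("seawater_pom", "vent_pom"))
  expect_error(mixing_problem(consumer_at(-20, 5), pom[1, ], zero_tdf()),
               class = "ventmix_input_error")
  expect_error(
    mixing_problem(consumer_at(-20, 5, guild = "omnivore"), pom, kst_tdf()),
    class = "ventmix_lookup_error"
  )
  expect_error(
    mixing_problem(consumer_at(-20, 5, guild = "herbivore"), pom,
                   kst_tdf(), prior = c(1, -1)),
    class = "ventmix_input_error"
  )
  na_sd <- pom
  na_sd$d13c_sd[1] <- NA
  expect_error(
    mixing_problem(consumer_at(-20, 5, guild = "herbivore"), na_sd, kst_tdf()),
    class = "ventmix_input_error"
  )
})
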