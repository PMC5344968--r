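test_that("island-scale hypotheses free the right number of scales", {
  isl <- c("Guam", "Rota", "Saipan", "Tinian")
  expect_length(unique(scale_groups(isl, "shared")), 1L)
  expect_length(unique(scale_groups(isl, "guam_vs_rest")), 2L)
  expect_length(unique(scale_groups(isl, "all_distinct")), 4L)
  g <- scale_groups(isl, "guam_vs_rest")
  expect_identical(unname(g["Guam"]), "Guam")
  expect_identical(unname(g["Rota"]), unname(g["Tinian"]))
})

test_that("shared hypothesis yields one scale regardless of island count", {
  w <- simulate_world(world_config(seed = 4), oracle_n = 0)
  m <- build_dispersal_model(w$stand, "t2d", "shared")
  expect_length(m$idx$la, 1L)
  m2 <- build_dispersal_model(w$stand, "t2d", "all_distinct")
  expect_length(m2$idx$la, 4L)
})

test_that("log-posterior equals a hand-summed likelihood plus priors on a toy stand", {
  s <- toy_stand(c(3L, 0L))
  pr <- dispersal_priors()
  m <- build_dispersal_model(s, "t2d", "shared", priors = pr)
  # theta: mu_beta, log sigma, u_s1, log a, log k1, log k2
  theta <- c(6, log(0.4), 6.3, log(2), log(0.5), log(0.1))

  # independent hand computation
  a <- 2; beta <- exp(6.3); k1 <- 0.5; k2 <- 0.1
  b <- pi * (c(20, 10) / 200)^2
  f <- function(r) 1 / (pi * a^2) * (1 + r^2 / a^2)^-2
  mu1 <- 0.5 * beta * (b[1] * f(1) + b[2] * f(3))
  mu2 <- 0.5 * beta * (b[1] * f(3) + b[2] * f(1))
  ll <- dnbinom(3, size = mu1 / (k1 + k2 * mu1), mu = mu1, log = TRUE) +
    dnbinom(0, size = mu2 / (k1 + k2 * mu2), mu = mu2, log = TRUE)
  lp <- dnorm(6, 0, 1000, log = TRUE) +             # mu_beta prior
    dnorm(log(2), 0, 1000, log = TRUE) +            # log a prior
    (log(0.4) - log(10)) +                          # sigma: U(0,10) + Jacobian
    (log(0.5) - log(100)) +                         # k1: U(0,100) + Jacobian
    (log(0.1) - log(10)) +                          # k2: U(0,10) + Jacobian
    dnorm(6.3, 6, 0.4, log = TRUE)                  # site random effect
  expect_equal(m$log_post(theta), ll + lp, tolerance = 1e-10)
  expect_equal(m$loglik(theta), ll, tolerance = 1e-10)
  # outside a uniform-prior bound the posterior vanishes
  theta_bad <- theta; theta_bad[2] <- log(11)
  expect_identical(m$log_post(theta_bad), -Inf)
})

test_that("log-posterior is invariant to site relabelling", {
  w <- simulate_world(world_config(seed = 8), oracle_n = 0)
  trees <- w$trees[, names(w$trees) != "focal"]
  perm <- order(rev(trees$site_id))
  stand1 <- w$stand
  stand2 <- stand_data(trees[rev(seq_len(nrow(trees))), ],
                       w$traps[rev(seq_len(nrow(w$traps))), ])
  m1 <- build_dispersal_model(stand1, "t2d", "guam_vs_rest")
  m2 <- build_dispersal_model(stand2, "t2d", "guam_vs_rest")
  # same site set; map u entries by site name, scales by group name
  theta1 <- c(6, log(0.3), seq(5.8, by = 0.05,
                               length.out = length(m1$idx$u)),
              log(0.5), log(3.4), log(0.5), log(0.2))
  u1 <- stats::setNames(theta1[m1$idx$u], m1$sites)
  la1 <- stats::setNames(theta1[m1$idx$la], m1$group_levels)
  theta2 <- numeric(m2$dim)
  theta2[m2$idx$mu_beta] <- theta1[m1$idx$mu_beta]
  theta2[m2$idx$lsig] <- theta1[m1$idx$lsig]
  theta2[m2$idx$u] <- u1[m2$sites]
  theta2[m2$idx$la] <- la1[m2$group_levels]
  theta2[m2$idx$lk1] <- theta1[m1$idx$lk1]
  theta2[m2$idx$lk2] <- theta1[m1$idx$lk2]
  expect_equal(m1$log_post(theta1), m2$log_post(theta2), tolerance = 1e-9)
})

test_that("Gelman-Rubin matches a hand-worked table and limiting cases", {
  # 2 chains x 4 draws, computed by hand:
  # chain 1: 1,2,3,4 (mean 2.5, var 5/3); chain 2: 2,4,6,8 (mean 5, var 20/3)
  # W = 25/6; B/n = var(c(2.5,5)) = 25/8
  # Rhat = sqrt((3/4 * 25/6 + 25/8) / (25/6)) = sqrt(0.75 + 0.75) = sqrt(1.5)
  x <- cbind(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(gelman_rubin(x), sqrt(1.5), tolerance = 1e-12)

  set.seed(1)
  same <- cbind(rnorm(4000), rnorm(4000), rnorm(4000))
  expect_lt(gelman_rubin(same), 1.01)

  apart <- cbind(rep(0, 50), rep(10, 50))
  expect_gt(gelman_rubin(apart), 10)
  expect_error(gelman_rubin(matrix(rnorm(10), ncol = 1)), "two chains")
})

test_that("the generic adaptive sampler recovers a standard normal", {
  res <- seedshadow:::run_chain(function(th) dnorm(th, log = TRUE),
                                theta0 = 2, n_burn = 1500, n_iter = 4000,
                                thin = 2, seed = 123)
  x <- res$draws[, 1]
  ess <- seedshadow:::effective_size(matrix(x, ncol = 1, nrow = length(x)))
  expect_lt(abs(mean(x)), 3 / sqrt(min(ess, length(x))))
  expect_lt(abs(sd(x) - 1), 0.05)
})

test_that("identical seeds give identical posterior draws", {
  s <- toy_stand(c(5L, 1L))
  f1 <- fit_dispersal(s, "t2d", "shared", n_chains = 2, n_retain = 50,
                      burn_in = 100, thin = 1, seed = 77)
  f2 <- fit_dispersal(s, "t2d", "shared", n_chains = 2, n_retain = 50,
                      burn_in = 100, thin = 1, seed = 77)
  f3 <- fit_dispersal(s, "t2d", "shared", n_chains = 2, n_retain = 50,
                      burn_in = 100, thin = 1, seed = 78)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("retained draws respect the positivity constraints", {
  w <- simulate_world(world_config(seed = 9), oracle_n = 0)
  f <- fit_dispersal(w$stand, "t2d", "guam_vs_rest", n_chains = 2,
                     n_retain = 150, burn_in = 400, thin = 1, seed = 3)
  d <- f$draws
  expect_true(all(d$sigma_beta > 0))
  expect_true(all(d$k1 > 0) && all(d$k2 > 0))
  expect_true(all(d[["a[Guam]"]] > 0) && all(d[["a[birds]"]] > 0))
  expect_true(all(vapply(split(seq_len(nrow(d)), d$chain), length,
                         integer(1)) == 150L))
})

test_that("DIC is Dbar + pD with pD = 0 for a point-mass posterior", {
  s <- toy_stand(c(4L, 1L))
  f <- fit_dispersal(s, "t2d", "shared", n_chains = 2, n_retain = 30,
                     burn_in = 50, thin = 1, seed = 5)
  # overwrite with a degenerate posterior at one parameter point
  f$draws[, f$model$par_names] <-
    matrix(rep(as.numeric(f$draws[1, f$model$par_names]),
               each = nrow(f$draws)), nrow = nrow(f$draws))
  theta <- numeric(f$model$dim)
  theta[f$model$idx$mu_beta] <- f$draws$mu_beta[1]
  theta[f$model$idx$lsig] <- log(f$draws$sigma_beta[1])
  theta[f$model$idx$u] <- log(as.numeric(
    f$draws[1, grep("^beta\\[", names(f$draws))]))
  theta[f$model$idx$la] <- log(as.numeric(
    f$draws[1, grep("^a\\[", names(f$draws))]))
  theta[f$model$idx$lk1] <- log(f$draws$k1[1])
  theta[f$model$idx$lk2] <- log(f$draws$k2[1])
  f$deviance <- rep(-2 * f$model$loglik(theta), nrow(f$draws))
  sc <- dic(f)
  expect_equal(sc$pD, 0, tolerance = 1e-8)
  expect_equal(sc$DIC, sc$Dbar, tolerance = 1e-8)
  expect_equal(sc$DIC, sc$Dbar + sc$pD)
})

test_that("posterior credible interval covers the generating scale (desk-scale stand)", {
  # 3 sites x 17 traps with the stated generating values
  # (a = 3.0, mu_beta = log 500, k1 = 0.5, k2 = 0.2)
  cfg <- world_config(kernel_family = "t2d", a_guam = 3.0, a_birds = 3.0,
                      mu_beta = log(500), sigma_beta = 0.3,
                      k1 = 0.5, k2 = 0.2, seed = 21)
  cfg$trap_sites <- c(Rota = 3L)
  w <- simulate_world(cfg, oracle_n = 0)
  expect_equal(nrow(w$traps), 51L)
  f <- fit_dispersal(w$stand, "t2d", "shared", n_chains = 3,
                     n_retain = 400, burn_in = 1200, thin = 2, seed = 31)
  ci <- quantile(f$draws[["a[all]"]], c(0.025, 0.975))
  expect_gt(3.0, ci[1])
  expect_lt(3.0, ci[2])
})

test_that("posterior mass piling against a prior bound triggers a warning", {
  # grossly overdispersed counts force the dispersion upward; with the
  # uniform bounds clamped far below that, mass piles at the bound
  s <- toy_stand(c(0L, 50L))
  expect_warning(
    fit_dispersal(s, "t2d", "shared",
                  priors = dispersal_priors(k1_max = 0.01, k2_max = 0.01),
                  n_chains = 2, n_retain = 100, burn_in = 300, thin = 1,
                  seed = 2),
    "prior bound")
})
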