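const_links <- function(pI = 0, pG1 = 1, pG0 = 1, pS1 = 1, pS2 = 1) {
  list(p_ingest = function(r) rep(pI, length(r)),
       p_germ = function(r, ingested)
         rep(if (ingested) pG1 else pG0, length(r)),
       p_s1 = function(r) rep(pS1, length(r)),
       p_s2 = function(r) rep(pS2, length(r)))
}

test_that("constant stage probabilities make phi an exact product", {
  for (fam in c("power_exponential", "t2d")) {
    k <- dispersal_kernel(fam, 2)
    links <- const_links(pI = 0, pG0 = 0.3, pS1 = 0.8, pS2 = 0.5)
    expect_equal(seed_to_seedling(k, links), 0.3 * 0.8 * 0.5,
                 tolerance = 1e-6)
    # integrand reduces to c * g(r)
    r <- c(0.5, 2, 10)
    expect_equal(survival_integrand(r, k, links),
                 0.3 * 0.8 * 0.5 * radial_pdf(k, r), tolerance = 1e-12)
  }
})

test_that("with ingestion impossible only the uningested germination curve matters", {
  k <- dispersal_kernel("t2d", 1.5)
  links <- const_links(pI = 0, pG1 = 0.9, pG0 = 0.25, pS1 = 1, pS2 = 1)
  expect_equal(seed_to_seedling(k, links), 0.25, tolerance = 1e-6)
  # and with certain ingestion, only the ingested curve
  links$p_ingest <- function(r) rep(1, length(r))
  expect_equal(seed_to_seedling(k, links), 0.9, tolerance = 1e-6)
})

test_that("a step survival threshold composes with the kernel CDF", {
  k <- dispersal_kernel("t2d", 2)
  R <- 3; cc <- 0.4
  links <- const_links(pG0 = cc)
  links$p_s2 <- function(r) as.numeric(r > R)
  phi <- seed_to_seedling(k, links)
  expect_equal(phi, cc * (1 - fraction_within(k, R)), tolerance = 1e-4)
})

test_that("quadrature phi matches forward simulation on random link models", {
  set.seed(61)
  for (i in 1:3) {
    k <- dispersal_kernel(sample(c("power_exponential", "t2d"), 1),
                          runif(1, 0.5, 4))
    b <- list(i0 = rnorm(1, -1, 0.5), i1 = runif(1, 0, 0.2),
              g0 = rnorm(1, -1, 0.5), g1 = runif(1, 0.5, 1.5),
              gd = runif(1, 0, 0.1),
              s1 = rnorm(1, 0.5, 0.3), s2a = rnorm(1, -0.5, 0.3),
              s2b = runif(1, 0, 0.15))
    links <- list(
      p_ingest = function(r) plogis(b$i0 + b$i1 * r),
      p_germ = function(r, ingested)
        plogis(b$g0 + ingested * b$g1 + b$gd * pmin(r, 12)),
      p_s1 = function(r) rep(plogis(b$s1), length(r)),
      p_s2 = function(r) plogis(b$s2a + b$s2b * pmin(r, 15)))
    phi_q <- seed_to_seedling(k, links)
    sim <- forward_simulate_phi(k, links$p_ingest, links$p_germ,
                                links$p_s1, links$p_s2,
                                n = 2e5, seed = 70 + i)
    expect_lt(abs(phi_q - sim$phi), 4 * sim$se)
  }
})

test_that("recruitment links built from stage fits give probabilities in (0,1)", {
  w <- simulate_world(world_config(seed = 41), oracle_n = 0)
  g <- fit_germination_glm(w$germination)
  id <- fit_ingestion_distance(w$stand)
  ss <- fit_seedling_survival(w$survival)
  fg <- fit_field_germination(w$seed_addition, "germination")
  fs <- fit_field_germination(w$seed_addition, "survival")
  links <- recruitment_links(germination = g, ingestion = id, survival = ss,
                             field_germination = fg, field_survival = fs,
                             birds_present = TRUE)
  r <- seq(0, 30, by = 0.5)
  for (f in links) {
    v <- if (identical(f, links$p_germ)) f(r, TRUE) else f(r)
    expect_true(all(v >= 0 & v <= 1))
  }
  # the no-birds scenario has identically zero ingestion
  links0 <- recruitment_links(germination = g, ingestion = id, survival = ss,
                              field_germination = fg, field_survival = fs,
                              birds_present = FALSE)
  expect_true(all(links0$p_ingest(r) == 0))
})

test_that("identical scenarios give a survival ratio of exactly one", {
  w <- simulate_world(world_config(seed = 43), oracle_n = 0)
  g <- fit_germination_glm(w$germination)
  # shared kernel scale (one group), no ingestion model, and no
  # scenario-specific covariates: the two scenarios then share every
  # parameter, so each draw's ratio is exactly 1
  kf <- fit_dispersal(w$stand, "t2d", "shared", n_chains = 2,
                      n_retain = 120, burn_in = 400, thin = 1, seed = 5)
  res <- propagate_uncertainty(kf, list(germination = g),
                               n_draws = 120, seed = 9)
  expect_true(all(abs(res$draws$ratio - 1) < 1e-12))
  s <- decline_summary(res)
  expect_equal(s["decline", "mean"], 0, tolerance = 1e-12)
})

test_that("a stronger ingestion germination advantage cannot reduce birds-present phi", {
  k <- dispersal_kernel("t2d", 3)
  base <- list(
    p_ingest = function(r) plogis(-1 + 0.15 * pmin(r, 20)),
    p_s1 = function(r) rep(1, length(r)),
    p_s2 = function(r) rep(0.5, length(r)))
  phi_at <- function(adv) {
    links <- c(base, list(
      p_germ = function(r, ingested) plogis(-1.4 + ingested * adv)))
    seed_to_seedling(k, links[c("p_ingest", "p_germ", "p_s1", "p_s2")])
  }
  advs <- seq(0, 2.5, by = 0.5)
  expect_true(all(diff(vapply(advs, phi_at, numeric(1))) >= 0))
})

test_that("decline summary matches a direct sort-based computation", {
  res <- structure(list(draws = data.frame(
    phi_present = rep(0.2, 200), phi_absent = rep(0.2, 200) * NA,
    ratio = runif(200, 0.1, 0.6)), n_draws = 200, family = "t2d",
    settings = list()), class = "recruitment_result")
  s <- decline_summary(res)
  r <- sort(res$draws$ratio)
  expect_equal(s["ratio", "q2.5"], quantile(r, 0.025, names = FALSE))
  expect_equal(s["ratio", "q97.5"], quantile(r, 0.975, names = FALSE))
  expect_equal(s["decline", "mean"], 1 - mean(r))
  # decline is monotone decreasing in ratio
  expect_equal(s["decline", "q2.5"], 1 - s["ratio", "q97.5"])

  res$draws$ratio <- rep(0.1, 200)
  s2 <- decline_summary(res)
  expect_equal(s2["decline", "mean"], 0.9)
  expect_equal(s2["decline", "q2.5"], s2["decline", "q97.5"])

  res$draws <- res$draws[1:50, ]
  expect_error(decline_summary(res), "100")
})

test_that("rank-deficient stage covariance is refused during propagation", {
  w <- simulate_world(world_config(seed = 47), oracle_n = 0)
  g <- fit_germination_glm(w$germination)
  g$vcov <- matrix(0, nrow(g$vcov), ncol(g$vcov),
                   dimnames = dimnames(g$vcov))
  kf <- fit_dispersal(w$stand, "t2d", "guam_vs_rest", n_chains = 2,
                      n_retain = 100, burn_in = 300, thin = 1, seed = 5)
  expect_error(propagate_uncertainty(kf, list(germination = g),
                                     n_draws = 50, seed = 1),
               "rank-deficient")
})
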