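make_germ <- function(n, p) {
  # deterministic trial table with round(n * p) germinants per arm
  do.call(rbind, Map(function(trt, ni, pi) {
    g <- c(rep(1L, round(ni * pi)), rep(0L, ni - round(ni * pi)))
    data.frame(treatment = trt, germinated = g)
  }, names(n), n, p))
}

test_that("AICc follows its formula and limiting behaviour", {
  expect_equal(aicc(-10, 2, 10), 20 + 4 + 12 / 7, tolerance = 1e-12)
  expect_equal(aicc(-10, 0, 10), 20)                     # k = 0: AICc = AIC
  # positive correction whenever k >= 1 and n finite
  for (k in 1:4) expect_gt(aicc(-5, k, 30), -2 * -5 + 2 * k)
  expect_error(aicc(-10, 9, 10), "n must exceed")
})

test_that("germination MLE equals the cell proportions with the expected contrast", {
  rec <- make_germ(c(whole_fruit = 100, ingested = 150),
                   c(whole_fruit = 0.20, ingested = 0.40))
  fit <- fit_germination_glm(rec)
  expect_identical(fit$formula_tag, "treatment")
  expect_equal(unname(fit$cell_props), c(0.20, 0.40), tolerance = 1e-12)
  # ingested-vs-whole log-odds: ln[(0.4/0.6) / (0.2/0.8)] = ln(8/3)
  expect_equal(unname(fit$coefficients["treatmentingested"]), log(8 / 3),
               tolerance = 1e-8)
  expect_false(fit$ci$includes_zero[fit$ci$coefficient == "treatmentingested"])
})

test_that("identical outcomes in all arms favour the null model", {
  rec <- make_germ(c(whole_fruit = 120, depulped = 120, ingested = 120),
                   c(whole_fruit = 0.3, depulped = 0.3, ingested = 0.3))
  fit <- fit_germination_glm(rec)
  expect_identical(fit$formula_tag, "null")
})

test_that("both reference-level contrasts are reported when treatment matters", {
  rec <- make_germ(c(whole_fruit = 117, depulped = 104, ingested = 150),
                   c(whole_fruit = 0.2, depulped = 0.28, ingested = 0.5))
  fit <- fit_germination_glm(rec)
  expect_identical(fit$formula_tag, "treatment")
  expect_setequal(fit$ci$coefficient,
                  c("treatmentdepulped", "treatmentingested"))
  expect_setequal(fit$ci_depulped$coefficient,
                  c("treatmentwhole_fruit", "treatmentingested"))
  # the ingested-vs-depulped contrast equals the coefficient difference
  expect_equal(
    fit$ci_depulped$estimate[
      fit$ci_depulped$coefficient == "treatmentingested"],
    unname(fit$coefficients["treatmentingested"] -
             fit$coefficients["treatmentdepulped"]),
    tolerance = 1e-8)
})

test_that("profile CI matches a dense grid scan on a single-proportion model", {
  dat <- data.frame(succ = 7, fail = 13)
  fit <- glm(cbind(succ, fail) ~ 1, family = binomial(), data = dat)
  ci <- profile_ci(fit, "(Intercept)")
  # oracle: scan the deviance of a fixed-intercept model on a fine grid
  dev <- function(t) -2 * (7 * t - 20 * log(1 + exp(t)))
  grid <- seq(-4, 2, by = 1e-4)
  rel <- dev(grid) - min(dev(grid))
  inside <- grid[rel <= qchisq(0.95, 1)]
  expect_equal(ci$lower, min(inside), tolerance = 1e-3)
  expect_equal(ci$upper, max(inside), tolerance = 1e-3)
  # 7/20 successes: the interval straddles even odds, and the
  # includes-zero flag must agree with the scanned endpoints
  expect_identical(ci$includes_zero, min(inside) <= 0 && max(inside) >= 0)
  expect_identical(ci$method, "profile")
})

test_that("profile CI approaches the Wald interval at large n", {
  dat <- data.frame(x = rep(c(0, 1), each = 2),
                    succ = c(300, 300, 420, 420),
                    fail = c(700, 700, 580, 580))
  fit <- glm(cbind(succ, fail) ~ x, family = binomial(), data = dat)
  ci <- profile_ci(fit, "x")
  se <- sqrt(vcov(fit)["x", "x"])
  wald <- coef(fit)["x"] + c(-1.96, 1.96) * se
  expect_lt(abs(ci$lower - wald[1]) / se, 0.05)
  expect_lt(abs(ci$upper - wald[2]) / se, 0.05)
})

test_that("a balanced null predictor's CI includes zero", {
  dat <- data.frame(x = c(0, 1), succ = c(40, 40), fail = c(60, 60))
  fit <- glm(cbind(succ, fail) ~ x, family = binomial(), data = dat)
  ci <- profile_ci(fit, "x")
  expect_true(ci$includes_zero)
})

test_that("ingestion island model handles the structurally-zero no-bird arm", {
  w <- simulate_world(world_config(seed = 13), oracle_n = 0)
  expect_equal(sum(w$traps$ingested_count[w$traps$island == "Guam"]), 0)
  fit <- fit_ingestion_island(w$stand)
  expect_identical(fit$formula_tag, "island")
  expect_true(all(is.finite(fit$coefficients)))
  expect_match(paste(fit$notes, collapse = " "), "separation")
  # bird islands clearly differ from the zero-ingestion reference
  isl <- grep("^island", names(fit$coefficients), value = TRUE)
  expect_true(all(fit$coefficients[isl] > 0))
})

test_that("islands with zero classified seeds are excluded with a warning", {
  w <- simulate_world(world_config(seed = 13), oracle_n = 0)
  tr <- w$traps
  tr$total_classified[tr$island == "Tinian"] <- 0L
  tr$ingested_count[tr$island == "Tinian"] <- 0L
  expect_warning(fit <- fit_ingestion_island(tr), "Tinian")
  expect_false("islandTinian" %in% names(fit$coefficients))
})

test_that("ingestion distance model recovers a positive distance effect", {
  w <- simulate_world(world_config(seed = 17), oracle_n = 0)
  fit <- fit_ingestion_distance(w$stand)
  expect_true(grepl("distance", fit$formula_tag))
  expect_gt(fit$coefficients[["distance"]], 0)
  ci <- fit$ci[fit$ci$coefficient == "distance", ]
  expect_true(ci$lower <= 0.15 && 0.15 <= ci$upper)
})

test_that("binomial weighting: a heavily-classified trap moves the fit more", {
  set.seed(23)
  base <- data.frame(
    site_id = rep(c("A", "B", "C"), each = 10), island = "Rota",
    nearest_conspecific_m = rep(seq(1, 19, length.out = 10), 3))
  p <- plogis(-1 + 0.15 * base$nearest_conspecific_m)
  base$total_classified <- rep(10L, 30)
  base$ingested_count <- rbinom(30, base$total_classified, p)
  # one influential observation: far trap with inflated ingestion
  extra <- data.frame(site_id = "A", island = "Rota",
                      nearest_conspecific_m = 19,
                      total_classified = NA, ingested_count = NA)
  slope_with <- function(n_cls) {
    x <- extra; x$total_classified <- n_cls
    x$ingested_count <- n_cls   # all ingested
    f <- fit_ingestion_distance(rbind(base, x))
    co <- coef(f)
    if ("distance" %in% names(co)) co[["distance"]] else 0
  }
  f0 <- fit_ingestion_distance(base)
  s0 <- coef(f0)[["distance"]]
  expect_gt(abs(slope_with(20L) - s0), abs(slope_with(1L) - s0))
})

test_that("seedling survival recovers an additive far-vs-near advantage", {
  w <- simulate_world(world_config(seed = 19), oracle_n = 0)
  fit <- fit_seedling_survival(w$survival)
  expect_true(grepl("distance", fit$formula_tag))
  # no interaction under additive truth
  expect_false(grepl("birds_x_distance|full", fit$formula_tag))
  expect_gt(fit$coefficients[["distance_classfar"]], 0)
  ci <- fit$ci[fit$ci$coefficient == "distance_classfar", ]
  expect_true(ci$lower <= 0.8 && 0.8 <= ci$upper)
})

test_that("equal survival everywhere selects the null survival model", {
  set.seed(5)
  plots <- data.frame(
    site_id = rep(paste0("s", 1:6), each = 8), island = "Rota",
    birds_present = 1L,
    distance_class = rep(c("near", "far"), 24),
    n_planted = 10L,
    n_survived = rbinom(48, 10, 0.5),
    canopy_openness = rnorm(48, 12, 4))
  fit <- fit_seedling_survival(plots)
  expect_identical(fit$formula_tag, "null")
})

test_that("field germination feeds a distance effect of the right size", {
  w <- simulate_world(world_config(seed = 29), oracle_n = 0)
  fit <- fit_field_germination(w$seed_addition, "germination")
  expect_true(grepl("distance", fit$formula_tag))
  truth <- qlogis(0.28) - qlogis(0.12)
  ci <- fit$ci[fit$ci$coefficient == "distance_classfar", ]
  expect_true(ci$lower <= truth && truth <= ci$upper)
  # survival stage likewise
  fs <- fit_field_germination(w$seed_addition, "survival")
  expect_gt(coef(fs)[["distance_classfar"]], 0)
})

test_that("no distance effect in truth drops distance by AICc (majority of replicates)", {
  hits <- 0L
  for (i in 1:10) {
    cfg <- world_config(field_germ_near = 0.2, field_germ_far = 0.2,
                        seed = 100 + i)
    w <- simulate_world(cfg, oracle_n = 0)
    fit <- fit_field_germination(w$seed_addition, "germination")
    hits <- hits + !grepl("distance", fit$formula_tag)
  }
  expect_gte(hits, 6L)
})

test_that("AICc model ranking is invariant to data-row order", {
  w <- simulate_world(world_config(seed = 37), oracle_n = 0)
  f1 <- fit_seedling_survival(w$survival)
  f2 <- fit_seedling_survival(w$survival[rev(seq_len(nrow(w$survival))), ])
  expect_identical(f1$aicc_table$model, f2$aicc_table$model)
  expect_equal(f1$aicc_table$AICc, f2$aicc_table$AICc, tolerance = 1e-6)
})
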