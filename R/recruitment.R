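# The integrative seed-to-seedling recruitment metric: composes the
# dispersal kernel with the ingestion, germination and seedling-survival
# stage models into overall seed-to-seedling survival
#   phi = int_0^inf g(r) [p(I|r) p(G|I=1,r) + (1-p(I|r)) p(G|I=0,r)]
#                    p(S1|r) p(S2|r) dr
# under frugivore-present and frugivore-absent scenarios, and the
# absent:present survival ratio with Monte-Carlo uncertainty.

check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("internal error: ", what, " outside [0, 1]; a link model is broken")
  pmin(pmax(p, 0), 1)
}

#' Build the stage link functions of the recruitment integral
#'
#' Converts fitted stage models (or plain coefficient vectors) into the
#' distance-dependent probability functions entering the recruitment
#' integral. Categorical near/far stage effects are mapped onto
#' continuous distance by a log-odds ramp between representative
#' distances (defaults: near plots at 0.5 m, i.e. under or at the
#' canopy edge, far plots at 10 m), constant beyond the anchors: the
#' experiments inform only the near/far contrast, so the ramp is not
#' extrapolated.
#'
#' @param germination \code{"stage_fit"} from
#'   \code{\link{fit_germination_glm}} (ingestion effect on
#'   germination), or NULL for a constant-germination link.
#' @param ingestion \code{"stage_fit"} from
#'   \code{\link{fit_ingestion_distance}}, or NULL. Ignored when
#'   \code{birds_present} is FALSE (ingestion is then identically 0).
#'   Predictions are averaged over the bird islands on the probability
#'   scale.
#' @param survival \code{"stage_fit"} from
#'   \code{\link{fit_seedling_survival}} (late-stage survival S2), or
#'   NULL for \code{p(S2) = 1}.
#' @param field_germination,field_survival \code{"stage_fit"}s from
#'   \code{\link{fit_field_germination}} supplying the distance effect
#'   on germination and the early-survival stage S1 (both NULL for a
#'   species without seed-addition data: no distance term in
#'   germination and constant S1).
#' @param birds_present logical scenario switch: FALSE sets ingestion
#'   probability to zero and the bird-presence covariate of the
#'   survival model to 0.
#' @param coefs optional named list of coefficient vectors (elements
#'   \code{germination}, \code{ingestion}, \code{survival},
#'   \code{field_germination}, \code{field_survival}) overriding each
#'   fit's MLEs; used by the uncertainty propagation.
#' @param near_m,far_m representative distances (m) of the near/far
#'   classes.
#' @param openness_c mean-centred canopy openness at which survival
#'   models are evaluated (0 = the average openness across plots).
#' @return list of functions \code{p_ingest(r)}, \code{p_germ(r,
#'   ingested)}, \code{p_s1(r)}, \code{p_s2(r)}.
#' @export
recruitment_links <- function(germination = NULL, ingestion = NULL,
                              survival = NULL, field_germination = NULL,
                              field_survival = NULL, birds_present = TRUE,
                              coefs = list(), near_m = 0.5, far_m = 10,
                              openness_c = 0) {
  co <- function(fit, name) {
    if (!is.null(coefs[[name]])) coefs[[name]] else fit$coefficients
  }
  ramp <- function(r) pmin(pmax((r - near_m) / (far_m - near_m), 0), 1)

  # average linear predictor over the levels of any site fixed effect
  lp_nearfar <- function(cf, openterm = TRUE) {
    site_cols <- grep("^site_id", names(cf), value = TRUE)
    site_mean <- if (length(site_cols))
      mean(c(0, unlist(cf[site_cols]))) else 0
    base <- cf[["(Intercept)"]] + site_mean +
      if (openterm && "openness_c" %in% names(cf))
        cf[["openness_c"]] * openness_c else 0
    far_extra <- (if ("distance_classfar" %in% names(cf))
      cf[["distance_classfar"]] else 0) +
      (if ("distance_classfar:openness_c" %in% names(cf))
        cf[["distance_classfar:openness_c"]] * openness_c else 0) +
      (if ("openness_c:distance_classfar" %in% names(cf))
        cf[["openness_c:distance_classfar"]] * openness_c else 0)
    c(near = unname(base), far = unname(base + far_extra))
  }

  ## p(I|r): zero without birds; otherwise island-averaged predictions
  p_ingest <- if (!birds_present || is.null(ingestion)) {
    function(r) rep(0, length(r))
  } else {
    cf <- co(ingestion, "ingestion")
    isl_cols <- grep("^island(?!.*:)", names(cf), value = TRUE, perl = TRUE)
    int_cols <- grep("^island.*:distance$|^distance:island",
                     names(cf), value = TRUE)
    slope0 <- if ("distance" %in% names(cf)) cf[["distance"]] else 0
    offs <- c(0, unlist(cf[isl_cols]))
    slopes <- slope0 + c(0, if (length(int_cols)) unlist(cf[int_cols])
                         else rep(0, length(isl_cols)))
    function(r) {
      p <- rowMeans(vapply(seq_along(offs), function(i)
        invlogit(cf[["(Intercept)"]] + offs[i] + slopes[i] * r),
        numeric(length(r))))
      check_prob(p, "ingestion probability")
    }
  }

  ## p(G|I,r): greenhouse baseline by ingestion status, plus the field
  ## distance effect on the log-odds where available
  gh <- if (is.null(germination)) NULL else co(germination, "germination")
  field_delta <- if (is.null(field_germination)) 0 else {
    cf <- co(field_germination, "field_germination")
    if ("distance_classfar" %in% names(cf)) cf[["distance_classfar"]] else 0
  }
  p_germ <- function(r, ingested) {
    if (is.null(gh)) return(rep(1, length(r)))
    base <- gh[["(Intercept)"]] +
      ifelse(ingested & "treatmentingested" %in% names(gh),
             gh[["treatmentingested"]], 0)
    check_prob(invlogit(base + field_delta * ramp(r)), "germination")
  }

  ## p(S1|r): early survival from seed addition, or constant 1
  p_s1 <- if (is.null(field_survival)) {
    function(r) rep(1, length(r))
  } else {
    lp <- lp_nearfar(co(field_survival, "field_survival"))
    function(r)
      check_prob(invlogit(lp["near"] + ramp(r) * (lp["far"] - lp["near"])),
                 "early seedling survival")
  }

  ## p(S2|r): outplanted seedling survival; bird-presence covariate set
  ## by the scenario
  p_s2 <- if (is.null(survival)) {
    function(r) rep(1, length(r))
  } else {
    cf <- co(survival, "survival")
    birds_term <- if ("birds_present" %in% names(cf))
      cf[["birds_present"]] * as.numeric(birds_present) else 0
    birds_far <- if ("birds_present:distance_classfar" %in% names(cf))
      cf[["birds_present:distance_classfar"]] * as.numeric(birds_present)
      else 0
    lp <- lp_nearfar(cf)
    lp <- c(near = unname(lp["near"] + birds_term),
            far = unname(lp["far"] + birds_term + birds_far))
    function(r)
      check_prob(invlogit(lp["near"] + ramp(r) * (lp["far"] - lp["near"])),
                 "seedling survival")
  }

  list(p_ingest = p_ingest, p_germ = p_germ, p_s1 = p_s1, p_s2 = p_s2)
}

#' Integrand of the seed-to-seedling survival integral
#'
#' The radial dispersal density times the ingestion-marginalized
#' germination probability times both seedling-survival stages:
#' \deqn{g(r) [p(I|r) p(G|I{=}1,r) + (1 - p(I|r)) p(G|I{=}0,r)]
#'       p(S_1|r) p(S_2|r).}
#' The marginalization over ingestion status is explicit.
#'
#' @param r distances (m).
#' @param kernel a \code{\link{dispersal_kernel}}.
#' @param links stage link functions from
#'   \code{\link{recruitment_links}} (or any list with the same four
#'   functions).
#' @return integrand values.
#' @export
survival_integrand <- function(r, kernel, links) {
  pI <- check_prob(links$p_ingest(r), "ingestion probability")
  pG <- pI * check_prob(links$p_germ(r, TRUE), "germination (ingested)") +
    (1 - pI) * check_prob(links$p_germ(r, FALSE), "germination (uningested)")
  radial_pdf(kernel, r) * pG *
    check_prob(links$p_s1(r), "early survival") *
    check_prob(links$p_s2(r), "late survival")
}

#' Overall seed-to-seedling survival
#'
#' Numerically integrates \code{\link{survival_integrand}} over
#' dispersal distance, truncating where the kernel tail mass falls
#' below \code{tail_tol}.
#'
#' @inheritParams survival_integrand
#' @param tail_tol kernel tail mass beyond the integration limit
#'   (default 1e-8).
#' @return survival probability \eqn{\phi \in [0, 1]}.
#' @export
seed_to_seedling <- function(kernel, links, tail_tol = 1e-8) {
  r_max <- kernel_support_radius(kernel, tail_tol)
  out <- stats::integrate(survival_integrand, 0, r_max, kernel = kernel,
                          links = links, rel.tol = 1e-8,
                          subdivisions = 500L, stop.on.error = FALSE)
  if (out$message != "OK" && out$abs.error > 1e-6)
    stop("recruitment integral did not converge: ", out$message)
  min(max(out$value, 0), 1)
}

#' Forward-simulation estimate of seed-to-seedling survival
#'
#' Monte-Carlo oracle for \code{\link{seed_to_seedling}}: samples
#' dispersal distances from the radial kernel density and runs each
#' seed through Bernoulli ingestion, germination and the two survival
#' stages.
#'
#' @param kernel a \code{\link{dispersal_kernel}}.
#' @param p_ingest,p_germ,p_s1,p_s2 stage probability functions (as in
#'   \code{\link{recruitment_links}}).
#' @param n number of simulated seeds.
#' @param seed integer seed.
#' @return list with \code{phi} (the survival fraction) and \code{se}
#'   (its binomial standard error).
#' @export
forward_simulate_phi <- function(kernel, p_ingest, p_germ, p_s1, p_s2,
                                 n = 1e6, seed = 1L) {
  set.seed(seed)
  r <- sample_distance(kernel, n)
  ing <- stats::runif(n) < p_ingest(r)
  germ <- stats::runif(n) < ifelse(ing, p_germ(r, TRUE), p_germ(r, FALSE))
  s1 <- stats::runif(n) < p_s1(r)
  s2 <- stats::runif(n) < p_s2(r)
  alive <- germ & s1 & s2
  phi <- mean(alive)
  list(phi = phi, se = sqrt(phi * (1 - phi) / n))
}

draw_coefs <- function(fit) {
  if (is.null(fit)) return(NULL)
  v <- fit$vcov
  ch <- tryCatch(chol(v), error = function(e)
    stop("rank-deficient coefficient covariance in stage '", fit$stage,
         "'; cannot propagate uncertainty"))
  mu <- fit$coefficients
  stats::setNames(as.numeric(mu + drop(t(ch) %*% stats::rnorm(length(mu)))),
                  names(mu))
}

#' Propagate kernel and stage-model uncertainty into the recruitment
#' metric
#'
#' For each Monte-Carlo draw: a posterior draw of the kernel scale is
#' taken (the bird-island scale for the frugivore-present scenario, the
#' bird-free-island scale for the frugivore-absent scenario, from the
#' same posterior draw), stage regression coefficients are simulated
#' from their multivariate normal sampling distributions using the
#' fixed-effect covariance of the best-supported model, and the
#' recruitment integral is evaluated under both scenarios with
#' identical values for all shared parameters. Random effects are not
#' included: predictions are island-level averages, with canopy
#' openness held at the across-plot average (centred value 0).
#'
#' @param kernel_fit a \code{\link{fit_dispersal}} result whose stand
#'   includes both the bird-free island and at least one island with
#'   birds.
#' @param stages named list of \code{"stage_fit"}s: \code{germination},
#'   \code{ingestion} (distance model), \code{survival}, and optionally
#'   \code{field_germination}, \code{field_survival}.
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param seed integer seed.
#' @param near_m,far_m,openness_c passed to
#'   \code{\link{recruitment_links}}.
#' @return object of class \code{"recruitment_result"}: per-draw
#'   \code{phi_present}, \code{phi_absent} and their
#'   absent:present \code{ratio}, plus the scenario setup.
#' @export
propagate_uncertainty <- function(kernel_fit, stages, n_draws = 1000,
                                  seed = 1L, near_m = 0.5, far_m = 10,
                                  openness_c = 0) {
  stopifnot(inherits(kernel_fit, "dispersal_fit"))
  islands <- names(kernel_fit$model$groups)
  if (!"Guam" %in% islands)
    stop("kernel fit must include the bird-free island (Guam)")
  bird_islands <- setdiff(islands, "Guam")
  if (!length(bird_islands))
    stop("kernel fit must include at least one island with birds")
  set.seed(seed)
  n_post <- nrow(kernel_fit$draws)
  idx <- sample.int(n_post, n_draws, replace = n_draws > n_post)
  a_guam <- scale_draws(kernel_fit, "Guam")[idx]
  a_birds <- rowMeans(vapply(bird_islands, function(isl)
    scale_draws(kernel_fit, isl)[idx], numeric(n_draws)))
  family <- kernel_fit$model$family

  phi_p <- phi_a <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    cf <- list(germination = draw_coefs(stages$germination),
               ingestion = draw_coefs(stages$ingestion),
               survival = draw_coefs(stages$survival),
               field_germination = draw_coefs(stages$field_germination),
               field_survival = draw_coefs(stages$field_survival))
    links_p <- recruitment_links(
      germination = stages$germination, ingestion = stages$ingestion,
      survival = stages$survival,
      field_germination = stages$field_germination,
      field_survival = stages$field_survival,
      birds_present = TRUE, coefs = cf, near_m = near_m, far_m = far_m,
      openness_c = openness_c)
    links_a <- recruitment_links(
      germination = stages$germination, ingestion = stages$ingestion,
      survival = stages$survival,
      field_germination = stages$field_germination,
      field_survival = stages$field_survival,
      birds_present = FALSE, coefs = cf, near_m = near_m, far_m = far_m,
      openness_c = openness_c)
    phi_p[i] <- seed_to_seedling(dispersal_kernel(family, a_birds[i]),
                                 links_p)
    phi_a[i] <- seed_to_seedling(dispersal_kernel(family, a_guam[i]),
                                 links_a)
  }
  structure(list(
    draws = data.frame(phi_present = phi_p, phi_absent = phi_a,
                       ratio = phi_a / phi_p),
    n_draws = n_draws, family = family,
    settings = list(seed = seed, near_m = near_m, far_m = far_m,
                    openness_c = openness_c)),
    class = "recruitment_result")
}

#' Summarize the recruitment-decline metric
#'
#' Means, medians and 2.5/97.5% quantiles of the per-draw
#' absent:present survival ratio and of the implied recruitment decline
#' \eqn{1 - \mathrm{ratio}}.
#'
#' @param result a \code{\link{propagate_uncertainty}} result (at least
#'   100 draws).
#' @return a data frame with rows \code{ratio} and \code{decline}.
#' @export
decline_summary <- function(result) {
  stopifnot(inherits(result, "recruitment_result"))
  if (nrow(result$draws) < 100)
    stop("at least 100 draws are needed for a stable summary")
  ratio <- result$draws$ratio
  qs <- stats::quantile(ratio, c(0.025, 0.5, 0.975), names = FALSE)
  out <- data.frame(
    mean = c(mean(ratio), mean(1 - ratio)),
    median = c(qs[2], 1 - qs[2]),
    q2.5 = c(qs[1], 1 - qs[3]),
    q97.5 = c(qs[3], 1 - qs[1]),
    row.names = c("ratio", "decline"))
  out
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat(sprintf("seed-to-seedling recruitment metric (%d draws, %s kernel)\n",
              x$n_draws, x$family))
  cat(sprintf("  phi (birds present): mean %.4g; phi (birds absent): mean %.4g\n",
              mean(x$draws$phi_present), mean(x$draws$phi_absent)))
  if (nrow(x$draws) >= 100) {
    s <- decline_summary(x)
    cat(sprintf("  recruitment decline 1 - phi_absent/phi_present: %.1f%% (95%% CI %.1f-%.1f%%)\n",
                100 * s["decline", "mean"], 100 * s["decline", "q2.5"],
                100 * s["decline", "q97.5"]))
  }
  invisible(x)
}

#' @export
summary.recruitment_result <- function(object, ...) decline_summary(object)
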