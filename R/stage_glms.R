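# Binomial GLM/GLMM stages of the recruitment chain: frugivore
# ingestion, germination by fruit-handling treatment, and
# distance-dependent seedling survival, with AICc model selection and
# profile-likelihood confidence intervals.

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2 \log L + 2k + 2k(k+1)/(n-k-1)}. For the binomial
#' stages, \code{n} is the number of binomial observations (plots or
#' traps), not Bernoulli trials.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed \code{k + 1}.
#' @return the AICc score.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

aicc_of <- function(fit, n) {
  ll <- stats::logLik(fit)
  aicc(as.numeric(ll), attr(ll, "df"), n)
}

# Fit a set of candidate formulas, score by AICc, and pick the best;
# ties within 2 AICc units resolve to the simplest model (fewest
# parameters). `fitter` maps a formula to a fitted model or NULL.
select_by_aicc <- function(formulas, fitter, n) {
  fits <- lapply(formulas, function(f)
    tryCatch(fitter(f), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no candidate model could be fitted")
  k <- vapply(fits[ok], function(f)
    attr(stats::logLik(f), "df"), numeric(1))
  score <- vapply(fits[ok], aicc_of, numeric(1), n = n)
  tab <- data.frame(model = names(formulas)[ok], k = k, AICc = score)
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  near <- which(tab$delta_AICc <= 2)
  best <- near[which.min(tab$k[near])]
  tab$best <- seq_len(nrow(tab)) == best
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  list(fit = fits[ok][[best]], tag = names(formulas)[ok][best], table = tab)
}

is_mer <- function(fit) inherits(fit, "merMod")

# binomial glmer with a fallback: extreme (near-separated) arms can
# break the default PIRLS iterations, in which case the model is
# refitted with the random effects profiled out of the deviance
# update (nAGQ = 0), which is numerically robust here.
glmer_binomial <- function(f, data) {
  ctl <- lme4::glmerControl(calc.derivs = FALSE,
                            check.conv.grad = lme4::.makeCC("ignore", 2e-3))
  out <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::glmer(f, data = data, family = stats::binomial(),
                  control = ctl))),
    error = function(e) NULL)
  if (is.null(out))
    out <- suppressWarnings(suppressMessages(
      lme4::glmer(f, data = data, family = stats::binomial(),
                  control = ctl, nAGQ = 0)))
  out
}

fixed_coefs <- function(fit) {
  if (is_mer(fit)) lme4::fixef(fit) else stats::coef(fit)
}

fixed_vcov <- function(fit) {
  v <- as.matrix(stats::vcov(fit))
  dimnames(v) <- list(names(fixed_coefs(fit)), names(fixed_coefs(fit)))
  v
}

# Haldane-style correction for complete separation in aggregated
# binomial data: add half a success and half a failure to every row.
# Returns corrected success/failure columns.
haldane_correct <- function(succ, fail) {
  list(succ = succ + 0.5, fail = fail + 0.5)
}

separation_detected <- function(fit, limit = 10) {
  co <- fixed_coefs(fit)
  se <- sqrt(diag(fixed_vcov(fit)))
  any(!is.finite(co)) || any(!is.finite(se)) ||
    any(abs(co) > limit & se > limit)
}

#' Profile-likelihood confidence interval for one coefficient
#'
#' Endpoints are the values at which the profile deviance rises by the
#' \eqn{\chi^2_1} quantile (3.841 at the 95% level) above its minimum.
#' For GLMs the profile is computed by refitting with the focal term
#' moved to an offset; for GLMMs the lme4 profile machinery is used
#' (falling back to a Wald interval, flagged, if profiling fails). An
#' unbounded profile yields a one-sided interval with an infinite
#' endpoint and a flag.
#'
#' @param fit a fitted \code{glm} or \code{glmerMod} binomial model.
#' @param parm coefficient name.
#' @param level confidence level (default 0.95).
#' @return a list with \code{estimate}, \code{lower}, \code{upper},
#'   \code{includes_zero}, \code{one_sided}, and \code{method}.
#' @export
profile_ci <- function(fit, parm, level = 0.95) {
  est <- fixed_coefs(fit)[[parm]]
  if (is_mer(fit)) {
    ci <- tryCatch({
      out <- NULL
      utils::capture.output(
        out <- suppressMessages(suppressWarnings(
          stats::confint(fit, parm = parm, method = "profile",
                         level = level, quiet = TRUE))))
      out
    }, error = function(e) NULL)
    method <- "profile"
    if (is.null(ci) || any(!is.finite(ci))) {
      se <- sqrt(fixed_vcov(fit)[parm, parm])
      z <- stats::qnorm(1 - (1 - level) / 2)
      ci <- matrix(c(est - z * se, est + z * se), 1)
      method <- "wald"
    }
    lo <- ci[1, 1]; hi <- ci[1, 2]
    return(list(estimate = est, lower = lo, upper = hi,
                includes_zero = lo <= 0 && hi >= 0,
                one_sided = !all(is.finite(c(lo, hi))), method = method))
  }

  X <- stats::model.matrix(fit)
  j <- match(parm, colnames(X))
  if (is.na(j)) stop("no coefficient named ", parm)
  y <- fit$y
  w <- stats::weights(fit)
  if (is.null(w)) w <- rep(1, length(y))
  off0 <- fit$offset
  if (is.null(off0)) off0 <- rep(0, length(y))
  fam <- stats::family(fit)
  dev0 <- stats::deviance(fit)
  crit <- stats::qchisq(level, 1)

  prof_dev <- function(t) {
    f <- suppressWarnings(stats::glm.fit(
      x = X[, -j, drop = FALSE], y = y, weights = w,
      offset = off0 + t * X[, j], family = fam))
    f$deviance
  }
  se <- sqrt(diag(stats::vcov(fit)))[j]
  if (!is.finite(se) || se == 0) se <- max(abs(est), 1)

  find_end <- function(direction) {
    g <- function(t) prof_dev(t) - dev0 - crit
    step <- se
    t1 <- est
    for (i in 1:40) {
      t2 <- est + direction * step
      if (g(t2) > 0)
        return(stats::uniroot(g, sort(c(t1, t2)), tol = 1e-6)$root)
      t1 <- t2
      step <- step * 1.8
    }
    direction * Inf  # profile never reaches the cutoff
  }
  lo <- find_end(-1)
  hi <- find_end(1)
  list(estimate = est, lower = lo, upper = hi,
       includes_zero = lo <= 0 && hi >= 0,
       one_sided = !all(is.finite(c(lo, hi))), method = "profile")
}

profile_ci_table <- function(fit, parms, level = 0.95) {
  rows <- lapply(parms, function(p) {
    ci <- profile_ci(fit, p, level)
    data.frame(coefficient = p, estimate = ci$estimate,
               lower = ci$lower, upper = ci$upper,
               includes_zero = ci$includes_zero,
               one_sided = ci$one_sided, method = ci$method)
  })
  do.call(rbind, rows)
}

new_stage_fit <- function(stage, sel, n, ci = NULL, notes = character(0),
                          extra = list()) {
  fit <- sel$fit
  obj <- c(list(stage = stage, formula_tag = sel$tag,
                coefficients = fixed_coefs(fit),
                vcov = fixed_vcov(fit),
                aicc_table = sel$table, ci = ci, n = n,
                model = fit, notes = notes), extra)
  class(obj) <- "stage_fit"
  obj
}

#' @export
print.stage_fit <- function(x, ...) {
  cat(sprintf("binomial stage fit [%s]: best model '%s' (n = %d)\n",
              x$stage, x$formula_tag, x$n))
  print(round(x$coefficients, 4))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.stage_fit <- function(object, ...) object$coefficients

#' @export
vcov.stage_fit <- function(object, ...) object$vcov

#' Germination by fruit-handling treatment
#'
#' Binomial GLM of germination against the three nursery treatments
#' (whole fruit, manually de-pulped, bird-ingested), compared by AICc
#' with the intercept-only model. Profile 95% intervals are reported
#' under both reference levels: contrasts against whole fruit and
#' against manual de-pulping, so the ingestion effect can be read
#' against either baseline. Species are analysed separately (pass one
#' species' records).
#'
#' @param records data frame with columns \code{treatment} (levels
#'   \code{whole_fruit}, \code{depulped}, \code{ingested}) and
#'   \code{germinated} (0/1).
#' @return a \code{"stage_fit"}; the extra element \code{ci_depulped}
#'   holds the second contrast set.
#' @export
fit_germination_glm <- function(records) {
  stopifnot(all(c("treatment", "germinated") %in% names(records)))
  levs <- c("whole_fruit", "depulped", "ingested")
  present <- intersect(levs, unique(as.character(records$treatment)))
  if (length(present) < 2L) stop("need at least two treatment levels")
  records$treatment <- factor(records$treatment, levels = present)
  agg <- stats::aggregate(cbind(succ = germinated,
                                fail = 1 - germinated) ~ treatment,
                          data = records, FUN = sum)
  n <- nrow(records)

  fit_with <- function(dat) {
    sel <- select_by_aicc(
      list(treatment = cbind(succ, fail) ~ treatment,
           null = cbind(succ, fail) ~ 1),
      function(f) stats::glm(f, family = stats::binomial(), data = dat),
      n = n)
    sel
  }
  sel <- fit_with(agg)
  notes <- character(0)
  if (separation_detected(sel$fit)) {
    cc <- haldane_correct(agg$succ, agg$fail)
    agg$succ <- cc$succ; agg$fail <- cc$fail
    sel <- fit_with(agg)
    notes <- "complete separation: Haldane 0.5 correction applied"
  }

  tr_parms <- function(fit) setdiff(names(stats::coef(fit)), "(Intercept)")
  ci <- if (sel$tag == "treatment") profile_ci_table(sel$fit, tr_parms(sel$fit))
        else NULL
  ci2 <- NULL
  if (sel$tag == "treatment" && "depulped" %in% present) {
    agg2 <- agg
    agg2$treatment <- stats::relevel(agg2$treatment, "depulped")
    fit2 <- stats::glm(cbind(succ, fail) ~ treatment,
                       family = stats::binomial(), data = agg2)
    ci2 <- profile_ci_table(fit2, tr_parms(fit2))
  }
  new_stage_fit("germination", sel, n, ci = ci, notes = notes,
                extra = list(ci_depulped = ci2,
                             cell_props = agg$succ / (agg$succ + agg$fail)))
}

prepare_trap_proportions <- function(traps) {
  if (inherits(traps, "stand_data")) traps <- traps$traps
  req <- c("site_id", "island", "ingested_count", "total_classified")
  miss <- setdiff(req, names(traps))
  if (length(miss)) stop("traps need columns: ", paste(miss, collapse = ", "))
  tot <- tapply(traps$total_classified, traps$island, sum)
  empty <- names(tot)[is.na(tot) | tot == 0]
  if (length(empty))
    warning("islands with zero classified seeds excluded: ",
            paste(empty, collapse = ", "))
  traps <- traps[traps$total_classified > 0, , drop = FALSE]
  traps
}

#' Proportion of seeds ingested: island comparison
#'
#' Binomial GLMM (site random intercept) of the proportion of trapped
#' seeds classified as ingested, with island as the fixed effect,
#' compared by AICc with the no-island model. Profile intervals use
#' contrasts against the bird-free island (Guam) as the reference level.
#' An island whose traps hold no classified seeds is excluded with a
#' warning. When one arm is structurally zero (no birds, no ingestion),
#' complete separation is handled by a Haldane 0.5 correction, flagged
#' in the notes.
#'
#' @param traps trap records (or a \code{\link{stand_data}}) with
#'   \code{ingested_count}, \code{total_classified}, \code{island},
#'   \code{site_id}.
#' @return a \code{"stage_fit"}.
#' @export
fit_ingestion_island <- function(traps) {
  traps <- prepare_trap_proportions(traps)
  isl_levels <- unique(c("Guam", sort(unique(as.character(traps$island)))))
  isl_levels <- intersect(isl_levels, unique(as.character(traps$island)))
  traps$island <- factor(traps$island, levels = isl_levels)
  traps$site_id <- factor(traps$site_id)
  n <- nrow(traps)

  fitter <- function(dat) function(f) glmer_binomial(f, dat)
  forms <- list(island = cbind(succ, fail) ~ island + (1 | site_id),
                null = cbind(succ, fail) ~ 1 + (1 | site_id))
  traps$succ <- traps$ingested_count
  traps$fail <- traps$total_classified - traps$ingested_count
  notes <- character(0)
  # a structurally-zero arm (an island with no ingested or no uningested
  # seeds, as where birds are absent) makes the island MLE infinite;
  # apply the correction up front so the model remains fittable
  arm_succ <- tapply(traps$succ, traps$island, sum)
  arm_fail <- tapply(traps$fail, traps$island, sum)
  if (any(arm_succ == 0) || any(arm_fail == 0)) {
    cc <- haldane_correct(traps$succ, traps$fail)
    traps$succ <- cc$succ; traps$fail <- cc$fail
    notes <- "complete separation: Haldane 0.5 correction applied"
  }
  sel <- select_by_aicc(forms, fitter(traps), n = n)
  if (separation_detected(sel$fit)) {
    cc <- haldane_correct(traps$succ, traps$fail)
    traps$succ <- cc$succ; traps$fail <- cc$fail
    sel <- select_by_aicc(forms, fitter(traps), n = n)
    notes <- c(notes, "residual separation: correction re-applied")
  }
  parms <- grep("^island", names(fixed_coefs(sel$fit)), value = TRUE)
  ci <- if (sel$tag == "island" && length(parms))
    profile_ci_table(sel$fit, parms) else NULL
  new_stage_fit("ingestion_island", sel, n, ci = ci, notes = notes)
}

#' Proportion of seeds ingested versus distance to the nearest adult
#'
#' Binomial GLMM (site random intercept) of ingestion probability on
#' the islands with birds only (the bird-free island is excluded: its
#' ingestion is structurally zero), with island, distance to the
#' nearest conspecific adult, and their interaction as candidate fixed
#' effects. The full model and all four submodels (island + distance,
#' island, distance, null) are compared by AICc; the best is returned.
#' Traps with more classified seeds carry proportionally more binomial
#' weight.
#'
#' @param traps trap records (or a \code{\link{stand_data}}) with a
#'   \code{nearest_conspecific_m} distance column.
#' @return a \code{"stage_fit"}.
#' @export
fit_ingestion_distance <- function(traps) {
  traps <- prepare_trap_proportions(traps)
  if (!"nearest_conspecific_m" %in% names(traps))
    stop("traps need a nearest_conspecific_m column (see stand_data)")
  traps <- traps[traps$island != "Guam", , drop = FALSE]
  if (!nrow(traps)) stop("no bird-island traps with classified seeds")
  traps$island <- factor(as.character(traps$island))
  traps$site_id <- factor(traps$site_id)
  traps$distance <- traps$nearest_conspecific_m
  traps$succ <- traps$ingested_count
  traps$fail <- traps$total_classified - traps$ingested_count
  n <- nrow(traps)
  one_island <- nlevels(traps$island) < 2L

  forms <- list(
    island_x_distance = cbind(succ, fail) ~ island * distance + (1 | site_id),
    island_plus_distance = cbind(succ, fail) ~ island + distance + (1 | site_id),
    island = cbind(succ, fail) ~ island + (1 | site_id),
    distance = cbind(succ, fail) ~ distance + (1 | site_id),
    null = cbind(succ, fail) ~ 1 + (1 | site_id))
  if (one_island) forms <- forms[c("distance", "null")]
  fitter <- function(f) glmer_binomial(f, traps)
  sel <- select_by_aicc(forms, fitter, n = n)
  parms <- setdiff(names(fixed_coefs(sel$fit)), "(Intercept)")
  ci <- if (length(parms)) profile_ci_table(sel$fit, parms) else NULL
  new_stage_fit("ingestion_distance", sel, n, ci = ci)
}

#' Distance-dependent seedling survival
#'
#' Binomial GLMM of outplanted-seedling survival per plot with site as
#' a random intercept. The full model crosses bird presence with
#' near/far distance class (is distance dependence steeper where birds
#' are absent?) and canopy openness with distance class (is the
#' distance effect modified by light?); openness is mean-centred before
#' fitting. The full model and its submodels are compared by AICc.
#' Contrasts use the no-birds and near levels as references.
#'
#' @param plots data frame with \code{site_id}, \code{island},
#'   \code{birds_present} (0/1), \code{distance_class}
#'   (\code{near}/\code{far}), \code{n_planted}, \code{n_survived},
#'   \code{canopy_openness} (percent).
#' @return a \code{"stage_fit"}; \code{openness_center} stores the mean
#'   used for centring.
#' @export
fit_seedling_survival <- function(plots) {
  req <- c("site_id", "birds_present", "distance_class", "n_planted",
           "n_survived", "canopy_openness")
  miss <- setdiff(req, names(plots))
  if (length(miss)) stop("plots need columns: ", paste(miss, collapse = ", "))
  stopifnot(all(plots$n_survived >= 0), all(plots$n_survived <= plots$n_planted))
  plots$site_id <- factor(plots$site_id)
  plots$distance_class <- factor(plots$distance_class,
                                 levels = c("near", "far"))
  ocenter <- mean(plots$canopy_openness)
  plots$openness_c <- plots$canopy_openness - ocenter
  plots$succ <- plots$n_survived
  plots$fail <- plots$n_planted - plots$n_survived
  n <- nrow(plots)

  forms <- list(
    full = cbind(succ, fail) ~ birds_present * distance_class +
      openness_c * distance_class + (1 | site_id),
    birds_x_distance = cbind(succ, fail) ~ birds_present * distance_class +
      openness_c + (1 | site_id),
    openness_x_distance = cbind(succ, fail) ~ birds_present +
      distance_class * openness_c + (1 | site_id),
    additive = cbind(succ, fail) ~ birds_present + distance_class +
      openness_c + (1 | site_id),
    birds_distance = cbind(succ, fail) ~ birds_present + distance_class +
      (1 | site_id),
    distance_openness = cbind(succ, fail) ~ distance_class + openness_c +
      (1 | site_id),
    distance = cbind(succ, fail) ~ distance_class + (1 | site_id),
    null = cbind(succ, fail) ~ 1 + (1 | site_id))
  fitter <- function(f) glmer_binomial(f, plots)
  sel <- select_by_aicc(forms, fitter, n = n)
  parms <- setdiff(names(fixed_coefs(sel$fit)), "(Intercept)")
  ci <- if (length(parms)) profile_ci_table(sel$fit, parms) else NULL
  new_stage_fit("seedling_survival", sel, n, ci = ci,
                extra = list(openness_center = ocenter))
}

#' Field germination and early survival from seed-addition plots
#'
#' Binomial GLMs (no random effects; site enters as a fixed effect) for
#' the seed-addition experiment: germination out of seeds sown, or
#' early seedling survival out of germinants, in near versus far plots.
#' Candidate models combine distance class, mean-centred canopy
#' openness, their interaction, and site; all are compared by AICc.
#' The distance coefficient of the germination stage feeds the
#' distance-dependent germination term of the recruitment integral.
#'
#' @param records data frame with \code{site_id}, \code{distance_class},
#'   \code{n_sown}, \code{n_germinated}, \code{n_surviving},
#'   \code{canopy_openness}.
#' @param stage \code{"germination"} (germinants out of sown) or
#'   \code{"survival"} (survivors out of germinants; plots without
#'   germinants are dropped).
#' @return a \code{"stage_fit"}.
#' @export
fit_field_germination <- function(records,
                                  stage = c("germination", "survival")) {
  stage <- match.arg(stage)
  req <- c("site_id", "distance_class", "n_sown", "n_germinated",
           "canopy_openness")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records need columns: ",
                         paste(miss, collapse = ", "))
  records$site_id <- factor(records$site_id)
  records$distance_class <- factor(records$distance_class,
                                   levels = c("near", "far"))
  ocenter <- mean(records$canopy_openness)
  records$openness_c <- records$canopy_openness - ocenter
  if (stage == "germination") {
    records$succ <- records$n_germinated
    records$fail <- records$n_sown - records$n_germinated
  } else {
    records <- records[records$n_germinated > 0, , drop = FALSE]
    records$succ <- records$n_surviving
    records$fail <- records$n_germinated - records$n_surviving
  }
  n <- nrow(records)

  forms <- list(
    full = cbind(succ, fail) ~ distance_class * openness_c + site_id,
    distance_openness_site = cbind(succ, fail) ~ distance_class +
      openness_c + site_id,
    distance_site = cbind(succ, fail) ~ distance_class + site_id,
    distance_openness = cbind(succ, fail) ~ distance_class + openness_c,
    openness_site = cbind(succ, fail) ~ openness_c + site_id,
    distance = cbind(succ, fail) ~ distance_class,
    site = cbind(succ, fail) ~ site_id,
    openness = cbind(succ, fail) ~ openness_c,
    null = cbind(succ, fail) ~ 1)
  fitter <- function(f)
    stats::glm(f, family = stats::binomial(), data = records)
  sel <- select_by_aicc(forms, fitter, n = n)
  parms <- grep("^distance_class", names(stats::coef(sel$fit)), value = TRUE)
  ci <- if (length(parms)) profile_ci_table(sel$fit, parms) else NULL
  new_stage_fit(paste0("field_", stage), sel, n, ci = ci,
                extra = list(openness_center = ocenter))
}
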