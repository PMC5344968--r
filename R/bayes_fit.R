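# Hierarchical Bayesian inverse estimation of dispersal kernels from
# seed-trap counts in mapped stands.
#
# Model: counts s_j ~ NB(mu_j, k1, k2) with mu_j from the seed-shadow
# (expected_trap_counts); log beta_s ~ N(mu_beta, sigma_beta^2);
# island kernel scales grouped by hypothesis. Priors: mu_beta and each
# log(a) diffuse Normal(0, var 1e6); sigma_beta, k1, k2 uniform over
# configurable bounds. Sampling is adaptive random-walk Metropolis on
# the unconstrained scale (log transforms for positive parameters, with
# Jacobian terms for the uniform-prior parameters).

#' Island-scale hypotheses
#'
#' Maps islands to kernel-scale groups under the three hypotheses about
#' the scale vector \eqn{a = (a_G, a_R, a_S, a_T)}: \code{"shared"} (one
#' scale for all islands), \code{"guam_vs_rest"} (the bird-free island
#' differs from the three islands with birds, which share a scale), and
#' \code{"all_distinct"} (every island its own scale).
#'
#' @param islands character vector of island names present in the data.
#' @param hypothesis one of \code{"shared"}, \code{"guam_vs_rest"},
#'   \code{"all_distinct"}.
#' @return named character vector mapping each island to its scale-group
#'   label.
#' @export
scale_groups <- function(islands,
                         hypothesis = c("shared", "guam_vs_rest",
                                        "all_distinct")) {
  hypothesis <- match.arg(hypothesis)
  islands <- unique(as.character(islands))
  g <- switch(hypothesis,
    shared = rep("all", length(islands)),
    guam_vs_rest = ifelse(islands == "Guam", "Guam", "birds"),
    all_distinct = islands)
  stats::setNames(g, islands)
}

#' Prior and sampler settings for the dispersal model
#'
#' @param sigma_beta_max,k1_max,k2_max upper bounds of the uniform
#'   priors on the fecundity log-sd and the two dispersion coefficients.
#' @param normal_sd standard deviation of the diffuse normal prior on
#'   \code{mu_beta} and each \code{log(a)} (variance 1e6 by default).
#' @return list of prior settings.
#' @export
dispersal_priors <- function(sigma_beta_max = 10, k1_max = 100,
                             k2_max = 10, normal_sd = 1000) {
  list(sigma_beta_max = sigma_beta_max, k1_max = k1_max, k2_max = k2_max,
       normal_sd = normal_sd)
}

#' Build the unnormalized log-posterior of the dispersal model
#'
#' Assembles the hierarchical model for one kernel family and one
#' island-scale hypothesis into a log-posterior callable over the
#' unconstrained parameter vector
#' \code{(mu_beta, log sigma_beta, log beta_s ..., log a ..., log k1,
#' log k2)}. The likelihood is the negative-binomial seed-shadow model;
#' the site effects contribute their lognormal density; uniform-prior
#' parameters sampled on the log scale carry the log-Jacobian.
#'
#' @param stand a \code{\link{stand_data}} with at least one site, trap
#'   and tree.
#' @param family kernel family (see \code{\link{dispersal_kernel}}).
#' @param hypothesis island-scale hypothesis (see
#'   \code{\link{scale_groups}}).
#' @param priors a \code{\link{dispersal_priors}} list.
#' @return an object of class \code{"dispersal_model"}: the
#'   \code{log_post} and \code{loglik} functions, parameter names and
#'   dimension, the island-to-group map, and an \code{init} function
#'   producing jittered data-driven starting points.
#' @export
build_dispersal_model <- function(stand, family = "power_exponential",
                                  hypothesis = "shared",
                                  priors = dispersal_priors()) {
  stopifnot(inherits(stand, "stand_data"))
  if (nrow(stand$trees) < 1L || nrow(stand$traps) < 1L)
    stop("stand must contain at least one tree and one trap")
  family <- dispersal_kernel(family, a = 1)$family
  islands <- unique(stand$site_island)
  groups <- scale_groups(islands, hypothesis)
  group_levels <- unique(unname(groups))
  n_scale <- length(group_levels)
  S <- length(stand$sites)
  pshape <- if (family == "power_exponential") 0.5 else 1

  # precomputed structures for fast likelihood evaluation
  s_obs <- stand$traps$seed_count
  A <- stand$traps$area_m2
  trap_site <- stand$trap_site
  pair_dist <- stand$pair_dist
  pair_b <- stand$trees$basal_area_m2[stand$pair_tree]
  pair_trap <- stand$pair_trap
  pair_group <- match(groups[stand$site_island[trap_site[pair_trap]]],
                      group_levels)
  group_sel <- lapply(seq_len(n_scale), function(g) pair_group == g)
  n_traps <- nrow(stand$traps)

  kf <- if (family == "power_exponential") {
    function(r, a) pshape / (2 * pi * a^2 * gamma(2 / pshape)) *
      exp(-(r / a)^pshape)
  } else {
    function(r, a) pshape / (pi * a^2) * (1 + (r / a)^2)^(-(pshape + 1))
  }

  # K_j(a) = sum_i b_i f(r_ij; a): kernel-weighted basal area per trap
  K_of <- function(a_vec) {
    f <- numeric(length(pair_dist))
    for (g in seq_len(n_scale)) {
      sel <- group_sel[[g]]
      f[sel] <- kf(pair_dist[sel], a_vec[g])
    }
    contrib <- rowsum(pair_b * f, group = pair_trap)
    K <- numeric(n_traps)
    K[as.integer(rownames(contrib))] <- contrib[, 1]
    K
  }

  mu_of <- function(betas, a_vec) A * betas[trap_site] * K_of(a_vec)

  site_traps <- lapply(seq_len(S), function(s) which(trap_site == s))

  par_names <- c("mu_beta", "sigma_beta",
                 paste0("beta[", stand$sites, "]"),
                 paste0("a[", group_levels, "]"), "k1", "k2")
  i_mu <- 1L; i_lsig <- 2L; i_u <- 2L + seq_len(S)
  i_la <- 2L + S + seq_len(n_scale)
  i_lk1 <- 3L + S + n_scale; i_lk2 <- 4L + S + n_scale
  d <- i_lk2

  loglik <- function(theta) {
    betas <- exp(theta[i_u])
    a_vec <- exp(theta[i_la])
    k1 <- exp(theta[i_lk1]); k2 <- exp(theta[i_lk2])
    sum(nb_loglik(s_obs, mu_of(betas, a_vec), nb_dispersion(k1, k2)))
  }

  log_post <- function(theta) {
    sigma <- exp(theta[i_lsig])
    k1 <- exp(theta[i_lk1]); k2 <- exp(theta[i_lk2])
    if (sigma > priors$sigma_beta_max || k1 > priors$k1_max ||
        k2 > priors$k2_max) return(-Inf)
    lp <- stats::dnorm(theta[i_mu], 0, priors$normal_sd, log = TRUE) +
      sum(stats::dnorm(theta[i_la], 0, priors$normal_sd, log = TRUE)) +
      # uniform priors on sigma, k1, k2 sampled on the log scale:
      # log density = -log(range) + log-Jacobian (the log-parameter)
      theta[i_lsig] - log(priors$sigma_beta_max) +
      theta[i_lk1] - log(priors$k1_max) +
      theta[i_lk2] - log(priors$k2_max) +
      sum(stats::dnorm(theta[i_u], theta[i_mu], sigma, log = TRUE))
    ll <- loglik(theta)
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }

  # per-site moment-matched fecundities for a given common scale
  match_betas <- function(a0) {
    K <- K_of(rep(a0, n_scale))
    denom <- rowsum(A * K, group = trap_site)
    tot <- rowsum(s_obs, group = trap_site)
    beta <- rep(1, S)
    beta[as.integer(rownames(tot))] <-
      (tot[, 1] + 0.5) / pmax(denom[match(rownames(tot),
                                          rownames(denom)), 1], 1e-12)
    pmin(pmax(beta, 1e-6), 1e12)
  }

  init <- function(jitter = 0.3) {
    # coarse likelihood profile over the scale: the misspecified-family
    # posterior can be far from mid-range scales, and chains started
    # off-mode take long to find it
    grid <- exp(seq(log(0.05), log(max(pair_dist, 1)), length.out = 12))
    score <- vapply(grid, function(a0) {
      beta <- match_betas(a0)
      mu <- A * beta[trap_site] * K_of(rep(a0, n_scale))
      sum(nb_loglik(s_obs, mu, nb_dispersion(1, 0.1)))
    }, numeric(1))
    a0 <- grid[which.max(score)]
    beta <- match_betas(a0)
    th <- numeric(d)
    th[i_mu] <- mean(log(beta))
    sd_b <- stats::sd(log(beta))
    th[i_lsig] <- log(if (is.finite(sd_b)) max(sd_b, 0.2) else 0.5)
    th[i_u] <- log(beta)
    th[i_la] <- log(a0)
    th[i_lk1] <- log(1); th[i_lk2] <- log(0.1)
    th + stats::rnorm(d, 0, jitter)
  }

  structure(list(log_post = log_post, loglik = loglik,
                 par_names = par_names, dim = d,
                 idx = list(mu_beta = i_mu, lsig = i_lsig, u = i_u,
                            la = i_la, lk1 = i_lk1, lk2 = i_lk2),
                 family = family, hypothesis = hypothesis,
                 groups = groups, group_levels = group_levels,
                 shape = pshape, priors = priors, init = init,
                 n_traps = n_traps, sites = stand$sites,
                 internals = list(K_of = K_of, site_traps = site_traps,
                                  s_obs = s_obs, A = A,
                                  trap_site = trap_site, n_sites = S,
                                  n_scale = n_scale)),
            class = "dispersal_model")
}

# Blocked Metropolis-within-Gibbs sampler for the dispersal model.
# One sweep updates: (1) the (log a, log k1, log k2) block by adaptive
# multivariate Metropolis (a full-likelihood evaluation, since the
# kernel scales touch every trap); (2) each site's log-fecundity by
# scalar Metropolis against that site's traps only; (3) mu_beta by an
# exact Gibbs draw (normal conditional); (4) log sigma_beta by scalar
# Metropolis against the random-effect density. Proposal scales and
# the block covariance adapt during burn-in and are frozen afterwards.
run_chain_dispersal <- function(model, theta0, n_burn, n_iter, thin, seed) {
  set.seed(seed)
  idx <- model$idx
  pr <- model$priors
  int <- model$internals
  S <- int$n_sites
  nsc <- int$n_scale
  dA <- nsc + 2L  # scales + k1 + k2
  trap_site <- int$trap_site
  s_obs <- int$s_obs

  theta <- theta0
  # lean pointwise NB log-likelihood (validation done upstream)
  nbll_point <- function(mu, k1, k2) {
    out <- numeric(length(mu))
    zero <- mu <= 0
    out[zero] <- ifelse(s_obs[zero] == 0, 0, -Inf)
    if (any(!zero)) {
      m <- mu[!zero]
      denom <- k1 + k2 * m
      out[!zero] <- if (denom[1] <= 0 && all(denom <= 0))
        stats::dpois(s_obs[!zero], m, log = TRUE)
      else
        stats::dnbinom(s_obs[!zero], size = m / denom, mu = m, log = TRUE)
    }
    out
  }
  ll_by_site <- function(mu, k1, k2) {
    pt <- nbll_point(mu, k1, k2)
    res <- rowsum(pt, group = trap_site)
    out <- numeric(S)
    out[as.integer(rownames(res))] <- res[, 1]
    out
  }

  cur <- list()
  refresh <- function() {
    cur$a <<- exp(theta[idx$la])
    cur$k1 <<- exp(theta[idx$lk1]); cur$k2 <<- exp(theta[idx$lk2])
    cur$K <<- int$K_of(cur$a)
    cur$beta <<- exp(theta[idx$u])
    cur$mu <<- int$A * cur$beta[trap_site] * cur$K
    cur$ll_site <<- ll_by_site(cur$mu, cur$k1, cur$k2)
  }
  refresh()
  tries <- 0
  while (!all(is.finite(cur$ll_site)) && tries < 50) {
    theta <- theta0 + stats::rnorm(length(theta0), 0, 0.5)
    refresh(); tries <- tries + 1
  }
  if (!all(is.finite(cur$ll_site)))
    stop("could not find a finite starting point")

  # log-prior of the A block (diffuse normals on log a; uniform k's
  # sampled on the log scale carry the Jacobian)
  lp_A <- function(la, lk1, lk2) {
    if (exp(lk1) > pr$k1_max || exp(lk2) > pr$k2_max) return(-Inf)
    sum(stats::dnorm(la, 0, pr$normal_sd, log = TRUE)) +
      lk1 - log(pr$k1_max) + lk2 - log(pr$k2_max)
  }

  scaleA <- 2.38^2 / dA
  covA <- diag(0.05, dA)
  cholA <- chol(covA)
  histA <- matrix(NA_real_, min(n_burn, 4000L), dA)
  hA <- 0L
  accA <- 0L; winA <- 0L
  step_u <- rep(0.4, S); acc_u <- rep(0L, S)
  step_sig <- 0.5; acc_sig <- 0L
  win <- 0L
  acc_total <- 0L; prop_total <- 0L

  total <- n_burn + n_iter * thin
  keep <- matrix(NA_real_, n_iter, length(theta))
  dev_keep <- numeric(n_iter)
  ki <- 0L

  for (t in seq_len(total)) {
    ## block A: kernel scales + dispersion
    zA <- c(theta[idx$la], theta[idx$lk1], theta[idx$lk2])
    zA_new <- zA + sqrt(scaleA) * drop(stats::rnorm(dA) %*% cholA)
    la_new <- zA_new[seq_len(nsc)]
    lk1_new <- zA_new[nsc + 1L]; lk2_new <- zA_new[nsc + 2L]
    lpA_new <- lp_A(la_new, lk1_new, lk2_new)
    prop_total <- prop_total + 1L
    if (is.finite(lpA_new)) {
      K_new <- int$K_of(exp(la_new))
      mu_new <- int$A * cur$beta[trap_site] * K_new
      ll_new <- ll_by_site(mu_new, exp(lk1_new), exp(lk2_new))
      lr <- sum(ll_new) - sum(cur$ll_site) + lpA_new -
        lp_A(theta[idx$la], theta[idx$lk1], theta[idx$lk2])
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        theta[idx$la] <- la_new
        theta[idx$lk1] <- lk1_new; theta[idx$lk2] <- lk2_new
        cur$a <- exp(la_new); cur$k1 <- exp(lk1_new); cur$k2 <- exp(lk2_new)
        cur$K <- K_new; cur$mu <- mu_new; cur$ll_site <- ll_new
        accA <- accA + 1L; winA <- winA + 1L
        acc_total <- acc_total + 1L
      }
    }

    ## block B: per-site log-fecundity (sites are conditionally
    ## independent given the rest, so propose and accept all at once)
    sig <- exp(theta[idx$lsig])
    mu_b <- theta[idx$mu_beta]
    u_old <- theta[idx$u]
    u_new <- u_old + stats::rnorm(S, 0, step_u)
    mu_new <- int$A * exp(u_new)[trap_site] * cur$K
    ll_new <- ll_by_site(mu_new, cur$k1, cur$k2)
    lr_s <- ll_new - cur$ll_site +
      stats::dnorm(u_new, mu_b, sig, log = TRUE) -
      stats::dnorm(u_old, mu_b, sig, log = TRUE)
    acc_s <- is.finite(lr_s) & log(stats::runif(S)) < lr_s
    prop_total <- prop_total + S
    if (any(acc_s)) {
      theta[idx$u[acc_s]] <- u_new[acc_s]
      cur$beta[acc_s] <- exp(u_new[acc_s])
      touch <- acc_s[trap_site]
      cur$mu[touch] <- mu_new[touch]
      cur$ll_site[acc_s] <- ll_new[acc_s]
      acc_u[acc_s] <- acc_u[acc_s] + 1L
      acc_total <- acc_total + sum(acc_s)
    }

    ## block C: mu_beta exact Gibbs (normal prior x normal RE density)
    prec <- S / sig^2 + 1 / pr$normal_sd^2
    mean_c <- sum(theta[idx$u]) / sig^2 / prec
    theta[idx$mu_beta] <- stats::rnorm(1, mean_c, sqrt(1 / prec))

    ## block D: log sigma_beta scalar Metropolis
    ls_old <- theta[idx$lsig]
    ls_new <- ls_old + stats::rnorm(1, 0, step_sig)
    prop_total <- prop_total + 1L
    if (exp(ls_new) <= pr$sigma_beta_max) {
      re_dens <- function(ls)
        sum(stats::dnorm(theta[idx$u], theta[idx$mu_beta], exp(ls),
                         log = TRUE)) + ls  # Jacobian of the log transform
      lr <- re_dens(ls_new) - re_dens(ls_old)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        theta[idx$lsig] <- ls_new
        acc_sig <- acc_sig + 1L
        acc_total <- acc_total + 1L
      }
    }
    win <- win + 1L

    ## adaptation during burn-in
    if (t <= n_burn) {
      if (hA < nrow(histA)) {
        hA <- hA + 1L
        histA[hA, ] <- c(theta[idx$la], theta[idx$lk1], theta[idx$lk2])
      }
      if (t %% 50L == 0L) {
        scaleA <- scaleA * exp(0.8 * (winA / win - 0.234))
        step_u <- step_u * exp(0.8 * (acc_u / win - 0.44))
        step_sig <- step_sig * exp(0.8 * (acc_sig / win - 0.44))
        winA <- 0L; acc_u[] <- 0L; acc_sig <- 0L; win <- 0L
        if (hA >= max(50L, 4L * dA)) {
          cv <- stats::cov(histA[seq_len(hA), , drop = FALSE]) +
            diag(1e-8, dA)
          ch <- tryCatch(chol(cv), error = function(e) NULL)
          if (!is.null(ch)) cholA <- ch
        }
      }
    } else if ((t - n_burn) %% thin == 0L) {
      ki <- ki + 1L
      keep[ki, ] <- theta
      dev_keep[ki] <- -2 * sum(cur$ll_site)
    }
  }
  list(draws = keep, deviance = dev_keep,
       accept_rate = acc_total / prop_total)
}

# generic adaptive random-walk Metropolis over an arbitrary log
# density: covariance adapted from the chain history during burn-in
# (Haario-style), frozen afterwards. Used for sampler sanity checks and
# as an engine-of-last-resort for custom targets.
run_chain <- function(log_post, theta0, n_burn, n_iter, thin, seed) {
  set.seed(seed)
  d <- length(theta0)
  theta <- theta0
  lp <- log_post(theta)
  tries <- 0
  while (!is.finite(lp) && tries < 50) {
    theta <- theta0 + stats::rnorm(d, 0, 0.5)
    lp <- log_post(theta)
    tries <- tries + 1
  }
  if (!is.finite(lp)) stop("could not find a finite starting point")

  scale <- 2.38^2 / d
  cov_prop <- diag(0.05, d)
  chol_prop <- chol(cov_prop)
  hist_n <- min(n_burn, 4000L)
  history <- matrix(NA_real_, hist_n, d)
  h <- 0L
  acc <- 0L; n_acc_window <- 0L; acc_window <- 0L

  total <- n_burn + n_iter * thin
  keep <- matrix(NA_real_, n_iter, d)
  lp_keep <- numeric(n_iter)
  ki <- 0L
  for (t in seq_len(total)) {
    prop <- theta + sqrt(scale) * drop(stats::rnorm(d) %*% chol_prop)
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      theta <- prop; lp <- lp_prop
      acc <- acc + 1L; acc_window <- acc_window + 1L
    }
    n_acc_window <- n_acc_window + 1L
    if (t <= n_burn) {
      if (h < hist_n) { h <- h + 1L; history[h, ] <- theta }
      if (t %% 100L == 0L) {
        # rescale toward 23% acceptance, re-estimate covariance
        rate <- acc_window / n_acc_window
        scale <- scale * exp(0.7 * (rate - 0.234))
        acc_window <- 0L; n_acc_window <- 0L
        if (h >= max(50L, 2L * d)) {
          cv <- stats::cov(history[seq_len(h), , drop = FALSE])
          cov_prop <- cv + diag(1e-6, d)
          ch <- tryCatch(chol(cov_prop), error = function(e) NULL)
          if (!is.null(ch)) chol_prop <- ch
        }
      }
    } else if ((t - n_burn) %% thin == 0L) {
      ki <- ki + 1L
      keep[ki, ] <- theta
      lp_keep[ki] <- lp
    }
  }
  list(draws = keep, lp = lp_keep, accept_rate = acc / total)
}

#' Fit the dispersal model by MCMC
#'
#' Draws from the posterior of the hierarchical seed-shadow model using
#' seeded adaptive random-walk Metropolis chains. Positivity constraints
#' are respected by sampling on the log scale. Convergence is assessed
#' by the Gelman-Rubin potential scale reduction factor across chains;
#' a fit with any \eqn{\hat R} above the threshold is flagged (not an
#' error). Draws are reported on the natural scale.
#'
#' @param stand a \code{\link{stand_data}}, or a prebuilt
#'   \code{"dispersal_model"} from \code{\link{build_dispersal_model}}.
#' @param family,hypothesis,priors passed to
#'   \code{\link{build_dispersal_model}} when \code{stand} is data.
#' @param n_chains number of parallel chains (default 3).
#' @param n_retain retained draws per chain after burn-in and thinning
#'   (default 1000).
#' @param burn_in burn-in iterations per chain (default 5000).
#' @param thin thinning interval; \code{NULL} picks the smallest value
#'   in 1..20 that brings the lag-1 autocorrelation of the first
#'   log-scale parameter below 0.5, estimated from a pilot run.
#' @param seed integer seed; chains use seeds derived from it, so the
#'   whole fit is reproducible.
#' @param rhat_threshold convergence flag threshold (default 1.1).
#' @return an object of class \code{"dispersal_fit"}: \code{draws}
#'   (data frame on the natural scale with chain and iteration columns),
#'   \code{deviance} per draw, \code{diagnostics} (R-hat, effective
#'   sample size, acceptance rates, convergence and prior-bound flags),
#'   and the model description.
#' @export
fit_dispersal <- function(stand, family = "power_exponential",
                          hypothesis = "shared",
                          priors = dispersal_priors(),
                          n_chains = 3, n_retain = 1000,
                          burn_in = 5000, thin = NULL, seed = 1L,
                          rhat_threshold = 1.1) {
  model <- if (inherits(stand, "dispersal_model")) stand
           else build_dispersal_model(stand, family, hypothesis, priors)
  stopifnot(n_chains >= 1, n_retain >= 2, burn_in >= 0)
  seeds <- derive_seeds(seed, n_chains + 1L)

  if (is.null(thin)) {
    # pilot run from one chain to choose thinning for log a mixing
    set.seed(seeds[n_chains + 1L])
    pilot <- run_chain_dispersal(model, model$init(),
                                 max(200L, burn_in %/% 2L), 300L, 1L,
                                 seeds[n_chains + 1L])
    la <- pilot$draws[, model$idx$la[1]]
    thin <- 1L
    for (cand in c(1L, 2L, 5L, 10L, 20L)) {
      idx <- seq(1L, length(la), by = cand)
      if (length(idx) < 10L) break
      ac <- stats::acf(la[idx], lag.max = 1, plot = FALSE)$acf[2]
      thin <- cand
      if (!is.na(ac) && ac < 0.5) break
    }
  }

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seeds[ch])
    theta0 <- model$init()
    chains[[ch]] <- run_chain_dispersal(model, theta0, burn_in, n_retain,
                                        thin, seeds[ch])
  }

  draws_nat <- do.call(rbind, lapply(seq_len(n_chains), function(ch) {
    th <- chains[[ch]]$draws
    nat <- th
    nat[, model$idx$lsig] <- exp(th[, model$idx$lsig])
    nat[, model$idx$u] <- exp(th[, model$idx$u, drop = FALSE])
    nat[, model$idx$la] <- exp(th[, model$idx$la, drop = FALSE])
    nat[, model$idx$lk1] <- exp(th[, model$idx$lk1])
    nat[, model$idx$lk2] <- exp(th[, model$idx$lk2])
    nat
  }))
  colnames(draws_nat) <- model$par_names
  chain_id <- rep(seq_len(n_chains), each = n_retain)
  iter <- rep(seq_len(n_retain), n_chains)

  deviance <- unlist(lapply(chains, `[[`, "deviance"))

  # diagnostics on the sampling (transformed) scale
  rhat <- vapply(seq_len(model$dim), function(j) {
    m <- vapply(chains, function(cc) cc$draws[, j], numeric(n_retain))
    gelman_rubin(m)
  }, numeric(1))
  ess <- vapply(seq_len(model$dim), function(j) {
    m <- vapply(chains, function(cc) cc$draws[, j], numeric(n_retain))
    effective_size(m)
  }, numeric(1))
  names(rhat) <- names(ess) <- model$par_names
  lag1 <- {
    la <- chains[[1]]$draws[, model$idx$la[1]]
    stats::acf(la, lag.max = 1, plot = FALSE)$acf[2]
  }

  pr <- model$priors
  bound_pile <- c(
    sigma_beta = mean(draws_nat[, "sigma_beta"] >
                        0.99 * pr$sigma_beta_max),
    k1 = mean(draws_nat[, "k1"] > 0.99 * pr$k1_max),
    k2 = mean(draws_nat[, "k2"] > 0.99 * pr$k2_max))
  if (any(bound_pile > 0.1))
    warning("posterior mass piles near a uniform prior bound for: ",
            paste(names(bound_pile)[bound_pile > 0.1], collapse = ", "),
            "; widen the prior bounds")

  fit <- structure(list(
    draws = data.frame(chain = chain_id, iteration = iter,
                       draws_nat, check.names = FALSE),
    deviance = deviance,
    diagnostics = list(
      rhat = rhat, ess = ess,
      accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
      lag1_autocorr_log_a = lag1,
      converged = all(is.finite(rhat)) && max(rhat) < rhat_threshold,
      rhat_threshold = rhat_threshold,
      bound_pileup = bound_pile),
    model = model,
    settings = list(n_chains = n_chains, n_retain = n_retain,
                    burn_in = burn_in, thin = thin, seed = seed)),
    class = "dispersal_fit")
  fit
}

#' @export
print.dispersal_fit <- function(x, ...) {
  cat(sprintf("hierarchical dispersal-kernel fit: %s kernel, %s scales\n",
              x$model$family, x$model$hypothesis))
  cat(sprintf("  %d chains x %d draws (burn-in %d, thin %d)\n",
              x$settings$n_chains, x$settings$n_retain,
              x$settings$burn_in, x$settings$thin))
  a_cols <- grep("^a\\[", names(x$draws), value = TRUE)
  for (ac in a_cols)
    cat(sprintf("  %s: posterior mean %.3g m (95%% CrI %.3g-%.3g)\n", ac,
                mean(x$draws[[ac]]),
                stats::quantile(x$draws[[ac]], 0.025),
                stats::quantile(x$draws[[ac]], 0.975)))
  cat(sprintf("  max R-hat %.3f (%s)\n", max(x$diagnostics$rhat),
              if (x$diagnostics$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.dispersal_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  pars <- object$model$par_names
  tab <- t(vapply(pars, function(p) {
    v <- object$draws[[p]]
    c(mean = mean(v), sd = stats::sd(v), stats::quantile(v, probs),
      rhat = object$diagnostics$rhat[[p]],
      ess = object$diagnostics$ess[[p]])
  }, numeric(4 + length(probs))))
  structure(list(table = tab, model = object$model,
                 converged = object$diagnostics$converged),
            class = "summary.dispersal_fit")
}

#' @export
print.summary.dispersal_fit <- function(x, ...) {
  cat(sprintf("%s kernel, %s island scales\n", x$model$family,
              x$model$hypothesis))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.dispersal_fit <- function(object, ...) {
  pars <- object$model$par_names
  vapply(pars, function(p) mean(object$draws[[p]]), numeric(1))
}

#' Posterior draws of the kernel scale for an island
#'
#' @param fit a \code{\link{fit_dispersal}} result.
#' @param island island name.
#' @return numeric vector of posterior draws of \code{a} (metres).
#' @export
scale_draws <- function(fit, island) {
  g <- fit$model$groups[[island]]
  if (is.null(g)) stop("island not in the fitted stand: ", island)
  fit$draws[[paste0("a[", g, "]")]]
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain convergence diagnostic: with m
#' chains of n draws, \eqn{W} the mean within-chain variance and
#' \eqn{B/n} the variance of the chain means,
#' \eqn{\hat R = \sqrt{((n-1)/n\,W + B/n) / W}}; values near 1 indicate
#' convergence.
#'
#' @param x draws: a matrix with one column per chain, or a 3-d array
#'   (iterations x chains x parameters).
#' @return \eqn{\hat R} (scalar for a matrix, vector for an array).
#' @export
gelman_rubin <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L)
    return(apply(x, 3L, gelman_rubin))
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  if (m < 2L) stop("at least two chains are required")
  means <- colMeans(x)
  W <- mean(apply(x, 2L, stats::var))
  B_over_n <- stats::var(means)
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

# multi-chain effective sample size via pooled autocorrelation
effective_size <- function(x) {
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  if (all(apply(x, 2L, stats::sd) == 0)) return(m * n)
  rho <- rowMeans(vapply(seq_len(m), function(ch) {
    if (stats::sd(x[, ch]) == 0) return(numeric(min(n - 2L, 100L)))
    stats::acf(x[, ch], lag.max = min(n - 2L, 100L),
               plot = FALSE)$acf[-1]
  }, numeric(min(n - 2L, 100L))))
  # sum positive-sequence autocorrelations
  csum <- 0
  for (t in seq_along(rho)) {
    if (is.na(rho[t]) || rho[t] < 0) break
    csum <- csum + rho[t]
  }
  m * n / (1 + 2 * csum)
}

#' Deviance information criterion of a fitted dispersal model
#'
#' Classical Spiegelhalter form: \eqn{\bar D} is the posterior mean
#' deviance (\eqn{D = -2 \log L}), the effective number of parameters is
#' \eqn{p_D = \bar D - D(\bar\theta)} with \eqn{\bar\theta} the
#' posterior mean of the parameters (taken on the sampling/log scale for
#' the positive parameters), and \eqn{DIC = \bar D + p_D}.
#'
#' @param fit a \code{\link{fit_dispersal}} result.
#' @return an object of class \code{"model_score"} with \code{Dbar},
#'   \code{pD} and \code{DIC}.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "dispersal_fit"))
  Dbar <- mean(fit$deviance)
  model <- fit$model
  # posterior mean on the sampling scale
  nat <- as.matrix(fit$draws[, model$par_names, drop = FALSE])
  theta_bar <- numeric(model$dim)
  theta_bar[model$idx$mu_beta] <- mean(nat[, model$idx$mu_beta])
  theta_bar[model$idx$lsig] <- mean(log(nat[, model$idx$lsig]))
  theta_bar[model$idx$u] <- colMeans(log(nat[, model$idx$u, drop = FALSE]))
  theta_bar[model$idx$la] <- colMeans(log(nat[, model$idx$la, drop = FALSE]))
  theta_bar[model$idx$lk1] <- mean(log(nat[, model$idx$lk1]))
  theta_bar[model$idx$lk2] <- mean(log(nat[, model$idx$lk2]))
  Dhat <- -2 * model$loglik(theta_bar)
  pD <- Dbar - Dhat
  structure(list(family = model$family, hypothesis = model$hypothesis,
                 Dbar = Dbar, pD = pD, DIC = Dbar + pD),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("%s / %s: Dbar = %.2f, pD = %.2f, DIC = %.2f\n",
              x$family, x$hypothesis, x$Dbar, x$pD, x$DIC))
  invisible(x)
}

#' Compare the six candidate dispersal models by DIC
#'
#' Fits every combination of the two kernel families
#' (power-exponential, 2Dt) and the three island-scale hypotheses
#' (shared, bird-free island distinct, all distinct) to the same stand
#' and ranks them by DIC.
#'
#' @param stand a \code{\link{stand_data}} spanning the islands needed
#'   by the hypotheses (at least two scale groups for the non-shared
#'   hypotheses).
#' @param families,hypotheses candidate sets (defaults give the six
#'   models).
#' @param ... passed to \code{\link{fit_dispersal}} (chain settings,
#'   seed).
#' @param keep_fits if \code{TRUE}, the fitted objects are returned in
#'   the \code{fits} attribute.
#' @return a data frame of class \code{"dispersal_model_comparison"}
#'   with one row per model (family, hypothesis, Dbar, pD, DIC,
#'   delta-DIC, best flag), sorted by DIC.
#' @export
compare_kernel_models <- function(stand,
                                  families = c("power_exponential", "t2d"),
                                  hypotheses = c("shared", "guam_vs_rest",
                                                 "all_distinct"),
                                  ..., keep_fits = FALSE) {
  grid <- expand.grid(family = families, hypothesis = hypotheses,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  scores <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- fit_dispersal(stand, family = grid$family[i],
                       hypothesis = grid$hypothesis[i], ...)
    scores[[i]] <- dic(f)
    if (keep_fits) fits[[i]] <- f
  }
  tab <- data.frame(
    family = grid$family, hypothesis = grid$hypothesis,
    Dbar = vapply(scores, `[[`, numeric(1), "Dbar"),
    pD = vapply(scores, `[[`, numeric(1), "pD"),
    DIC = vapply(scores, `[[`, numeric(1), "DIC"))
  tab <- tab[order(tab$DIC), ]
  tab$delta_DIC <- tab$DIC - tab$DIC[1]
  tab$best <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  class(tab) <- c("dispersal_model_comparison", "data.frame")
  if (keep_fits) attr(tab, "fits") <- fits
  tab
}

#' @export
print.dispersal_model_comparison <- function(x, ...) {
  need <- c("family", "hypothesis", "Dbar", "pD", "DIC", "delta_DIC")
  if (!all(need %in% names(x))) return(NextMethod())
  cat("DIC comparison of candidate dispersal models\n")
  print.data.frame(cbind(x[, c("family", "hypothesis")],
                         round(x[, c("Dbar", "pD", "DIC", "delta_DIC")], 2),
                         best = x$best))
  invisible(x)
}
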