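#' Basal area from diameter at breast height
#'
#' Circular cross-section basal area in m^2 from dbh in cm:
#' \eqn{b = \pi (dbh / 200)^2}. Basal area is the standard proxy for
#' fecundity: a tree's seed output is taken proportional to \eqn{b}.
#'
#' @param dbh_cm diameter at breast height, centimetres, \code{> 0}.
#' @return basal area, square metres.
#' @export
basal_area <- function(dbh_cm) {
  if (any(!is.finite(dbh_cm)) || any(dbh_cm <= 0))
    stop("dbh must be finite and positive")
  pi * (dbh_cm / 200)^2
}

#' Mapped stand with seed traps
#'
#' Bundles mapped conspecific trees and seed traps into the spatial
#' substrate of the seed-shadow likelihood. Trap-tree distances are
#' Euclidean on planar metre coordinates (sites are tens of metres
#' across; no geodesy). Trees farther than \code{mapping_radius} from a
#' trap contribute nothing to that trap's expected count, mirroring the
#' field protocol of mapping all conspecifics within 20 m of any trap;
#' the resulting edge truncation is a known, documented bias.
#'
#' @param trees data frame with columns \code{tree_id}, \code{site_id},
#'   \code{island}, \code{x_m}, \code{y_m}, \code{dbh_cm}.
#' @param traps data frame with columns \code{trap_id}, \code{site_id},
#'   \code{island}, \code{x_m}, \code{y_m}, \code{area_m2},
#'   \code{seed_count}, and optionally \code{ingested_count},
#'   \code{total_classified}.
#' @param mapping_radius metres; trees beyond this distance from a trap
#'   are excluded from that trap's seed shadow. Default 20.
#' @return An object of class \code{"stand_data"}: the validated tables
#'   (trees gain \code{basal_area_m2}, traps gain
#'   \code{nearest_conspecific_m}), a trap-tree pair list with distances,
#'   and site/island indices.
#' @export
stand_data <- function(trees, traps, mapping_radius = 20) {
  req_tree <- c("tree_id", "site_id", "island", "x_m", "y_m", "dbh_cm")
  req_trap <- c("trap_id", "site_id", "island", "x_m", "y_m", "area_m2",
                "seed_count")
  miss <- setdiff(req_tree, names(trees))
  if (length(miss)) stop("trees table missing columns: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(req_trap, names(traps))
  if (length(miss)) stop("traps table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(trees) < 1L || nrow(traps) < 1L)
    stop("stand must contain at least one tree and one trap")
  if (any(!is.finite(trees$x_m)) || any(!is.finite(trees$y_m)) ||
      any(!is.finite(traps$x_m)) || any(!is.finite(traps$y_m)))
    stop("coordinates must be finite")
  trees$basal_area_m2 <- basal_area(trees$dbh_cm)
  if (any(traps$area_m2 <= 0)) stop("trap area must be positive")
  if (any(traps$seed_count < 0) ||
      any(traps$seed_count != round(traps$seed_count)))
    stop("seed counts must be non-negative integers")
  if (all(c("ingested_count", "total_classified") %in% names(traps))) {
    if (any(traps$ingested_count > traps$total_classified))
      stop("ingested_count cannot exceed total_classified")
  }

  sites <- sort(unique(c(as.character(trees$site_id),
                         as.character(traps$site_id))))
  site_island <- vapply(sites, function(s) {
    isl <- unique(as.character(c(trees$island[trees$site_id == s],
                                 traps$island[traps$site_id == s])))
    if (length(isl) != 1L)
      stop("site ", s, " maps to multiple islands")
    isl
  }, character(1))

  trap_site <- match(as.character(traps$site_id), sites)
  tree_site <- match(as.character(trees$site_id), sites)

  # trap-tree pairs within the mapping radius, same site only
  pair_trap <- integer(0); pair_tree <- integer(0); pair_dist <- numeric(0)
  nearest <- rep(NA_real_, nrow(traps))
  for (j in seq_len(nrow(traps))) {
    i <- which(tree_site == trap_site[j])
    if (!length(i)) next
    d <- sqrt((trees$x_m[i] - traps$x_m[j])^2 +
              (trees$y_m[i] - traps$y_m[j])^2)
    nearest[j] <- min(d)
    keep <- d <= mapping_radius
    pair_trap <- c(pair_trap, rep.int(j, sum(keep)))
    pair_tree <- c(pair_tree, i[keep])
    pair_dist <- c(pair_dist, d[keep])
  }
  traps$nearest_conspecific_m <- nearest

  structure(list(
    trees = trees, traps = traps,
    sites = sites, site_island = site_island,
    trap_site = trap_site, tree_site = tree_site,
    pair_trap = pair_trap, pair_tree = pair_tree, pair_dist = pair_dist,
    mapping_radius = mapping_radius), class = "stand_data")
}

#' @export
print.stand_data <- function(x, ...) {
  cat(sprintf(
    "mapped stand: %d trees, %d traps, %d sites on %d island(s)\n",
    nrow(x$trees), nrow(x$traps), length(x$sites),
    length(unique(x$site_island))))
  cat(sprintf("  total seeds trapped: %d; mapping radius %g m\n",
              sum(x$traps$seed_count), x$mapping_radius))
  invisible(x)
}

#' Site-level fecundity parameters
#'
#' Seed production of tree \eqn{i} at site \eqn{s} is
#' \eqn{Q_i = \beta_s b_i}, with the site multipliers \eqn{\beta_s}
#' (seeds per m^2 of basal area) lognormally distributed across sites:
#' \eqn{\log \beta_s \sim N(\mu_\beta, \sigma_\beta^2)}. When
#' \code{sigma_beta = 0} every site has \eqn{\beta_s = e^{\mu_\beta}}.
#'
#' @param mu_beta log-mean of the site fecundity multiplier.
#' @param sigma_beta log-scale standard deviation, \code{>= 0}.
#' @param beta_s optional named vector of per-site multipliers; if
#'   omitted, all sites get \code{exp(mu_beta)} (valid when
#'   \code{sigma_beta} is 0).
#' @return object of class \code{"fecundity_params"}.
#' @export
fecundity_params <- function(mu_beta, sigma_beta = 0, beta_s = NULL) {
  if (sigma_beta < 0) stop("sigma_beta must be non-negative")
  if (!is.null(beta_s) && any(beta_s <= 0))
    stop("site fecundity multipliers must be positive")
  if (is.null(beta_s) && sigma_beta > 0)
    stop("beta_s must be supplied when sigma_beta > 0")
  structure(list(mu_beta = mu_beta, sigma_beta = sigma_beta,
                 beta_s = beta_s), class = "fecundity_params")
}

site_betas <- function(fec, sites) {
  if (is.null(fec$beta_s)) {
    stats::setNames(rep(exp(fec$mu_beta), length(sites)), sites)
  } else {
    b <- fec$beta_s[sites]
    if (any(is.na(b))) stop("beta_s missing for some sites")
    b
  }
}

# kernel argument: a single dispersal_kernel applied everywhere, or a
# named list of kernels keyed by island.
kernel_for_island <- function(kernel, islands) {
  if (inherits(kernel, "dispersal_kernel"))
    return(stats::setNames(rep(list(kernel), length(islands)), islands))
  if (!is.list(kernel) || is.null(names(kernel)) ||
      !all(islands %in% names(kernel)))
    stop("kernel must be a dispersal_kernel or a named list covering all islands")
  kernel[islands]
}

#' Expected seed count in each trap
#'
#' The seed-shadow observation model: the expected count in trap \eqn{j}
#' is the sum over mapped parent trees of fecundity times kernel density
#' at the trap-tree distance, scaled by trap area:
#' \deqn{\mu_j = A_j \sum_i \beta_{s} b_i f(r_{ij}).}
#' Additive in trees; invariant to rigid motions of the coordinates
#' (only distances enter).
#'
#' @param stand a \code{\link{stand_data}}.
#' @param kernel a \code{\link{dispersal_kernel}}, or a named list of
#'   kernels keyed by island for island-specific scales.
#' @param fecundity a \code{\link{fecundity_params}}.
#' @return numeric vector of expected counts, one per trap.
#' @export
expected_trap_counts <- function(stand, kernel, fecundity) {
  stopifnot(inherits(stand, "stand_data"),
            inherits(fecundity, "fecundity_params"))
  betas <- site_betas(fecundity, stand$sites)
  kl <- kernel_for_island(kernel, unique(stand$site_island))
  mu <- numeric(nrow(stand$traps))
  if (length(stand$pair_trap)) {
    isl_of_pair <- stand$site_island[stand$trap_site[stand$pair_trap]]
    f <- numeric(length(stand$pair_dist))
    for (isl in unique(isl_of_pair)) {
      sel <- isl_of_pair == isl
      f[sel] <- kernel_pdf(kl[[isl]], stand$pair_dist[sel])
    }
    contrib <- stand$trees$basal_area_m2[stand$pair_tree] * f
    agg <- rowsum(contrib, group = stand$pair_trap)
    idx <- as.integer(rownames(agg))
    mu[idx] <- agg[, 1]
  }
  as.numeric(stand$traps$area_m2 * betas[stand$trap_site] * mu)
}

#' Expected count for a single trap
#'
#' Single-trap convenience form of \code{\link{expected_trap_counts}}:
#' \eqn{\mu = A \sum_i \beta_s b_i f(r_i)} over the supplied trees, which
#' must share the trap's site.
#'
#' @param trap one-row data frame with \code{site_id}, \code{x_m},
#'   \code{y_m}, \code{area_m2}.
#' @param trees data frame of trees with \code{site_id}, \code{x_m},
#'   \code{y_m}, and \code{dbh_cm} or \code{basal_area_m2}.
#' @param kernel a \code{\link{dispersal_kernel}}.
#' @param beta_s site fecundity multiplier (seeds per m^2 basal area).
#' @return expected seed count (a single number).
#' @export
expected_trap_count <- function(trap, trees, kernel, beta_s) {
  if (nrow(trees) == 0L) return(0)
  if (any(as.character(trees$site_id) != as.character(trap$site_id)))
    stop("trap and trees must belong to the same site")
  b <- if ("basal_area_m2" %in% names(trees)) trees$basal_area_m2
       else basal_area(trees$dbh_cm)
  r <- sqrt((trees$x_m - trap$x_m)^2 + (trees$y_m - trap$y_m)^2)
  as.numeric(trap$area_m2 * beta_s * sum(b * kernel_pdf(kernel, r)))
}

#' Negative-binomial dispersion with quadratic mean-variance law
#'
#' Overdispersion of trap counts is described by two parameters
#' \eqn{k_1, k_2 \ge 0} giving the mean-variance relation as a
#' second-degree polynomial
#' \deqn{Var(s) = \mu (1 + k_1) + k_2 \mu^2,}
#' implemented as a negative binomial with size
#' \eqn{n = \mu / (k_1 + k_2 \mu)} and mean \eqn{\mu}. The Poisson model
#' is the \eqn{(k_1, k_2) \to (0, 0)} limit.
#'
#' @param k1,k2 non-negative dispersion coefficients.
#' @return object of class \code{"nb_dispersion"}.
#' @export
nb_dispersion <- function(k1 = 0, k2 = 0) {
  if (k1 < 0 || k2 < 0) stop("dispersion coefficients must be non-negative")
  structure(list(k1 = k1, k2 = k2), class = "nb_dispersion")
}

#' Implied variance of the trap-count distribution
#' @param mu expected count(s).
#' @param disp an \code{\link{nb_dispersion}}.
#' @return \eqn{\mu (1 + k_1) + k_2 \mu^2}.
#' @export
nb_variance <- function(mu, disp) {
  mu * (1 + disp$k1) + disp$k2 * mu^2
}

#' Negative-binomial log-likelihood of observed counts
#'
#' Pointwise log-likelihood of observed counts \code{s} given expected
#' counts \code{mu} under the quadratic mean-variance negative binomial.
#' \code{mu = 0} is handled as a limit: log-likelihood 0 when
#' \code{s = 0}, \code{-Inf} otherwise (so samplers and optimizers can
#' reject rather than crash). The total data log-likelihood is the sum
#' over all traps at all sites.
#'
#' @param s observed counts, non-negative integers.
#' @param mu expected counts, \code{>= 0}, recycled against \code{s}.
#' @param disp an \code{\link{nb_dispersion}}.
#' @return vector of pointwise log-likelihood values.
#' @export
nb_loglik <- function(s, mu, disp) {
  if (any(s < 0) || any(s != round(s))) stop("counts must be non-negative integers")
  if (any(mu < 0)) stop("expected counts must be non-negative")
  n <- length(s <- as.numeric(s))
  mu <- rep_len(mu, n)
  out <- numeric(n)
  zero <- mu == 0
  out[zero] <- ifelse(s[zero] == 0, 0, -Inf)
  pos <- !zero
  if (any(pos)) {
    denom <- disp$k1 + disp$k2 * mu[pos]
    pois <- denom <= 0
    idx <- which(pos)
    if (any(pois))
      out[idx[pois]] <- stats::dpois(s[idx[pois]], mu[pos][pois], log = TRUE)
    if (any(!pois))
      out[idx[!pois]] <- stats::dnbinom(
        s[idx[!pois]], size = mu[pos][!pois] / denom[!pois],
        mu = mu[pos][!pois], log = TRUE)
  }
  out
}

#' Simulate trap counts from the seed-shadow model
#'
#' Generative twin of the observation model: draws one count per trap
#' from the quadratic-variance negative binomial around the expected
#' counts of \code{\link{expected_trap_counts}}.
#'
#' @inheritParams expected_trap_counts
#' @param disp an \code{\link{nb_dispersion}}.
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of simulated counts, one per trap.
#' @export
simulate_trap_counts <- function(stand, kernel, fecundity, disp = nb_dispersion(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- expected_trap_counts(stand, kernel, fecundity)
  rnb_counts(mu, disp)
}

# vectorized NB draw with mu = 0 and Poisson-limit handling
rnb_counts <- function(mu, disp) {
  out <- integer(length(mu))
  pos <- mu > 0
  if (any(pos)) {
    denom <- disp$k1 + disp$k2 * mu[pos]
    pois <- denom <= 0
    idx <- which(pos)
    if (any(pois))
      out[idx[pois]] <- stats::rpois(sum(pois), mu[pos][pois])
    if (any(!pois))
      out[idx[!pois]] <- stats::rnbinom(
        sum(!pois), size = mu[pos][!pois] / denom[!pois], mu = mu[pos][!pois])
  }
  out
}
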