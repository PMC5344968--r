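#' Configuration of a synthetic study world
#'
#' Defines the ground truth and design of a simulated island-comparison
#' study: mapped conspecific stands with wedge-shaped 17-trap seed-trap
#' arrays (4 arrays on the frugivore-free island, 3 on each of the three
#' islands with birds, 221 traps in all), negative-binomially
#' overdispersed trap counts generated from a known dispersal kernel
#' with lognormal site fecundity, logistic distance-dependent ingestion
#' (structurally zero where birds are absent), treatment-dependent
#' nursery germination, near/far outplanted seedling survival, and
#' near/far seed-addition plots.
#'
#' Defaults give the generating values used throughout the package's
#' validation: a 2Dt kernel with scales 0.5 m (no birds) versus 3.4 m
#' (birds), i.e. mean dispersal distances of 0.79 versus 5.3 m;
#' fecundity log-mean \code{log(50000)} seeds per m^2 basal area (a
#' typical 20 cm dbh adult sheds about 1,500 seeds over a season,
#' giving under-canopy seed densities of tens per m^2);
#' dispersion \code{k1 = 0.5},
#' \code{k2 = 0.2}, germination roughly 2.5 times higher for ingested
#' seeds than whole fruit, higher survival far from conspecific adults,
#' and an overall far:near seed-addition survival advantage of about
#' five-fold across germination and early seedling survival.
#'
#' @param species \code{"Premna"} or \code{"Psychotria"}; controls the
#'   stage-experiment sample sizes.
#' @param kernel_family kernel family for the true dispersal kernel.
#' @param a_guam,a_birds true kernel scale (m) on the bird-free island
#'   and on islands with birds.
#' @param mu_beta,sigma_beta log-mean and log-sd of site fecundity
#'   (seeds per m^2 basal area).
#' @param k1,k2 true trap-count dispersion coefficients.
#' @param trees_per_site number of mapped conspecific trees per stand.
#' @param dbh_meanlog,dbh_sdlog lognormal dbh distribution (cm).
#' @param stand_extent half-width (m) of the square within which trees
#'   are scattered around the array origin.
#' @param trap_area_m2 seed-trap area (m^2); hoop-trap default 0.5.
#' @param ingestion_intercept,ingestion_slope true logit-scale intercept
#'   and per-metre distance slope of the probability that a trapped seed
#'   was ingested (bird islands only).
#' @param ingestion_island_offsets named logit offsets for the bird
#'   islands relative to Rota.
#' @param germ_probs named germination probabilities for the three
#'   nursery treatments (whole fruit, manually de-pulped, ingested).
#' @param surv_logit_near,surv_far_effect,surv_openness_slope true
#'   seedling-survival model: logit survival in near plots, additive
#'   far-vs-near log-odds, and slope per mean-centred percent canopy
#'   openness.
#' @param openness_mean,openness_sd canopy-openness distribution (%).
#' @param field_germ_near,field_germ_far,field_surv_near,field_surv_far
#'   true seed-addition germination and early-survival probabilities in
#'   near and far plots.
#' @param near_m,far_m representative dispersal distances (m) assigned
#'   to the categorical near/far experimental classes.
#' @param seed global seed; all component seeds are derived from it.
#' @return a \code{"world_config"} list.
#' @export
world_config <- function(
    species = "Premna",
    kernel_family = "t2d",
    a_guam = 0.5, a_birds = 3.4,
    mu_beta = log(5e4), sigma_beta = 0.3,
    k1 = 0.5, k2 = 0.2,
    trees_per_site = 8,
    dbh_meanlog = log(20), dbh_sdlog = 0.4,
    stand_extent = 25,
    trap_area_m2 = 0.5,
    ingestion_intercept = -1.0, ingestion_slope = 0.15,
    ingestion_island_offsets = c(Rota = 0, Saipan = 0.4, Tinian = 0.8),
    germ_probs = c(whole_fruit = 0.20, depulped = 0.28, ingested = 0.50),
    surv_logit_near = -0.6, surv_far_effect = 0.8,
    surv_openness_slope = 0.05,
    openness_mean = 12, openness_sd = 4,
    field_germ_near = 0.12, field_germ_far = 0.28,
    field_surv_near = 0.30, field_surv_far = 0.65,
    near_m = 0.5, far_m = 10,
    seed = 1L) {
  species <- match.arg(species, c("Premna", "Psychotria"))
  stopifnot(a_guam > 0, a_birds > 0, sigma_beta >= 0, k1 >= 0, k2 >= 0,
            trap_area_m2 > 0, trees_per_site >= 0,
            all(germ_probs > 0 & germ_probs < 1),
            all(c(field_germ_near, field_germ_far,
                  field_surv_near, field_surv_far) > 0),
            all(c(field_germ_near, field_germ_far,
                  field_surv_near, field_surv_far) < 1),
            near_m >= 0, far_m > near_m)
  cfg <- as.list(environment())
  # per-species stage designs, mirroring the field study
  cfg$trap_sites <- c(Guam = 4L, Rota = 3L, Saipan = 3L, Tinian = 3L)
  if (species == "Premna") {
    cfg$germ_n <- c(whole_fruit = 117L, depulped = 104L, ingested = 150L)
    cfg$outplant_sites <- c(Guam = 5L, Rota = 3L, Saipan = 3L, Tinian = 3L)
  } else {
    cfg$germ_n <- c(whole_fruit = 155L, depulped = 143L, ingested = 173L)
    cfg$outplant_sites <- c(Guam = 3L, Rota = 3L, Saipan = 3L, Tinian = 0L)
  }
  cfg$plots_per_site <- 8L       # 4 near + 4 far
  cfg$seedlings_per_plot <- 10L
  cfg$seed_addition_sites <- 3L  # near-bird island only
  cfg$seed_addition_plots_per_distance <- 6L
  cfg$seeds_per_addition_plot <- 50L
  class(cfg) <- "world_config"
  cfg
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf("synthetic world config: %s, %s kernel, a = %.2f/%.2f m (no birds/birds)\n",
              x$species, x$kernel_family, x$a_guam, x$a_birds))
  cat(sprintf("  %d trap arrays x 17 traps; seed %d\n",
              sum(x$trap_sites), x$seed))
  invisible(x)
}

# deterministic fan-out of the global seed into component seeds
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

islands_of <- function(counts) rep(names(counts), counts)

true_kernels <- function(config) {
  list(Guam = dispersal_kernel(config$kernel_family, config$a_guam),
       Rota = dispersal_kernel(config$kernel_family, config$a_birds),
       Saipan = dispersal_kernel(config$kernel_family, config$a_birds),
       Tinian = dispersal_kernel(config$kernel_family, config$a_birds))
}

#' Generate a mapped conspecific stand
#'
#' Scatters \code{trees_per_site} conspecific trees uniformly in a
#' square of half-width \code{stand_extent} around the origin, draws dbh
#' from a lognormal, and flags the largest tree as the focal tree of the
#' trap array.
#'
#' @param config a \code{\link{world_config}}.
#' @param site_id site label.
#' @param island island label.
#' @param seed integer seed.
#' @return data frame of tree records with a logical \code{focal} column.
#' @export
generate_stand <- function(config, site_id, island, seed = 1L) {
  set.seed(seed)
  n <- config$trees_per_site
  if (n == 0L)
    return(data.frame(tree_id = character(0), site_id = character(0),
                      island = character(0), x_m = numeric(0),
                      y_m = numeric(0), dbh_cm = numeric(0),
                      focal = logical(0)))
  x <- stats::runif(n, -config$stand_extent, config$stand_extent)
  y <- stats::runif(n, -config$stand_extent, config$stand_extent)
  dbh <- stats::rlnorm(n, config$dbh_meanlog, config$dbh_sdlog)
  focal <- which.max(dbh)
  # centre the array on the focal tree
  x <- x - x[focal]; y <- y - y[focal]
  data.frame(
    tree_id = paste0(site_id, "-T", seq_len(n)),
    site_id = site_id, island = island,
    x_m = x, y_m = y, dbh_cm = dbh,
    focal = seq_len(n) == focal)
}

#' Generate a wedge-shaped 17-trap array
#'
#' Places 17 seed traps radiating from the focal tree within a 60-degree
#' sector, with distances emphasizing near-canopy positions (1-20 m,
#' denser close to the tree) as in the field design.
#'
#' @param config a \code{\link{world_config}}.
#' @param focal_tree one-row data frame (the focal tree) supplying the
#'   array origin, site and island.
#' @param seed integer seed for the trap bearings.
#' @return data frame of 17 trap records.
#' @export
generate_trap_array <- function(config, focal_tree, seed = 1L) {
  set.seed(seed)
  dists <- c(1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 7, 8, 9, 10, 12, 14, 17, 20)
  angles <- stats::runif(17, 0, pi / 3)
  data.frame(
    trap_id = paste0(focal_tree$site_id, "-P", seq_along(dists)),
    site_id = focal_tree$site_id, island = focal_tree$island,
    x_m = focal_tree$x_m + dists * cos(angles),
    y_m = focal_tree$y_m + dists * sin(angles),
    area_m2 = config$trap_area_m2,
    seed_count = 0L, ingested_count = 0L, total_classified = 0L)
}

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

ingestion_logit <- function(config, island, distance) {
  if (island == "Guam") return(rep(-Inf, length(distance)))
  config$ingestion_intercept +
    config$ingestion_island_offsets[[island]] +
    config$ingestion_slope * distance
}

# true stage-probability functions of dispersal distance r, used by the
# forward-simulation oracle; the categorical near/far truth is mapped to
# a log-odds ramp between the representative distances.
logit_ramp <- function(r, near_val, far_val, near_m, far_m) {
  w <- pmin(pmax((r - near_m) / (far_m - near_m), 0), 1)
  near_val + w * (far_val - near_val)
}

true_stage_funs <- function(config) {
  cfg <- config
  list(
    p_ingest = function(r, island = "Rota")
      invlogit(ingestion_logit(cfg, island, r)),
    p_germ = function(r, ingested) {
      base <- ifelse(ingested, logit(cfg$germ_probs[["ingested"]]),
                     logit(cfg$germ_probs[["whole_fruit"]]))
      if (cfg$species == "Premna") {
        delta <- logit(cfg$field_germ_far) - logit(cfg$field_germ_near)
        base <- base + logit_ramp(r, 0, delta, cfg$near_m, cfg$far_m)
      }
      invlogit(base)
    },
    p_s1 = function(r) {
      if (cfg$species != "Premna") return(rep(1, length(r)))
      invlogit(logit_ramp(r, logit(cfg$field_surv_near),
                          logit(cfg$field_surv_far), cfg$near_m, cfg$far_m))
    },
    p_s2 = function(r)
      invlogit(logit_ramp(r, cfg$surv_logit_near,
                          cfg$surv_logit_near + cfg$surv_far_effect,
                          cfg$near_m, cfg$far_m)))
}

#' Simulate a complete synthetic study
#'
#' Generates every dataset of the study design from a single seeded
#' configuration: mapped trees and trap arrays with negative-binomial
#' seed counts from the true kernel and fecundity model, per-seed
#' Bernoulli ingestion classification (zero where birds are absent),
#' nursery germination trials, outplanted seedling-survival plots, and
#' (for Premna) seed-addition plots. The true seed-to-seedling survival
#' ratio between the frugivore-absent and frugivore-present scenarios is
#' computed by forward simulation and stored alongside the data.
#'
#' @param config a \code{\link{world_config}}.
#' @param oracle_n number of seeds in the forward-simulated truth
#'   (0 skips the oracle computation).
#' @return a list of class \code{"synthetic_world"} with elements
#'   \code{trees}, \code{traps}, \code{stand} (a
#'   \code{\link{stand_data}}), \code{germination}, \code{survival},
#'   \code{seed_addition} (Premna only), and \code{truth} (generating
#'   parameters, per-site fecundities, and the oracle phi-ratio).
#' @export
simulate_world <- function(config, oracle_n = 200000L) {
  stopifnot(inherits(config, "world_config"))
  seeds <- derive_seeds(config$seed, 8L)

  ## --- stands and trap arrays ---
  trap_islands <- islands_of(config$trap_sites)
  site_ids <- paste0(substr(trap_islands, 1, 1), "-",
                     stats::ave(seq_along(trap_islands), trap_islands,
                                FUN = seq_along))
  stand_seeds <- derive_seeds(seeds[1], 2L * length(site_ids))
  trees <- list(); traps <- list()
  for (i in seq_along(site_ids)) {
    tr <- generate_stand(config, site_ids[i], trap_islands[i],
                         seed = stand_seeds[2 * i - 1])
    traps[[i]] <- generate_trap_array(config, tr[tr$focal, , drop = FALSE],
                                      seed = stand_seeds[2 * i])
    trees[[i]] <- tr
  }
  trees <- do.call(rbind, trees)
  traps <- do.call(rbind, traps)

  ## --- site fecundities and trap counts ---
  set.seed(seeds[2])
  beta_s <- stats::setNames(
    stats::rlnorm(length(site_ids), config$mu_beta, config$sigma_beta),
    site_ids)
  fec <- fecundity_params(config$mu_beta, config$sigma_beta, beta_s)
  disp <- nb_dispersion(config$k1, config$k2)
  stand0 <- stand_data(trees[, setdiff(names(trees), "focal")], traps)
  traps$seed_count <- simulate_trap_counts(stand0, true_kernels(config),
                                           fec, disp, seed = seeds[3])

  ## --- ingestion classification (per-seed Bernoulli; zero on Guam) ---
  set.seed(seeds[4])
  nearest <- stand0$traps$nearest_conspecific_m
  traps$total_classified <- traps$seed_count
  traps$ingested_count <- vapply(seq_len(nrow(traps)), function(j) {
    n <- traps$seed_count[j]
    if (n == 0L || traps$island[j] == "Guam") return(0L)
    p <- invlogit(ingestion_logit(config, traps$island[j], nearest[j]))
    as.integer(stats::rbinom(1, n, p))
  }, integer(1))
  stand <- stand_data(trees[, setdiff(names(trees), "focal")], traps)

  ## --- nursery germination trials ---
  set.seed(seeds[5])
  germ <- do.call(rbind, lapply(names(config$germ_n), function(tr) {
    n <- config$germ_n[[tr]]
    data.frame(species = config$species, treatment = tr,
               germinated = stats::rbinom(n, 1, config$germ_probs[[tr]]))
  }))

  ## --- outplanted seedling survival ---
  set.seed(seeds[6])
  surv_islands <- islands_of(config$outplant_sites)
  surv <- do.call(rbind, lapply(seq_along(surv_islands), function(i) {
    isl <- surv_islands[i]
    sid <- paste0("S", substr(isl, 1, 1), "-",
                  sum(surv_islands[seq_len(i)] == isl))
    dist_class <- rep(c("near", "far"), each = config$plots_per_site / 2)
    openness <- stats::rnorm(config$plots_per_site, config$openness_mean,
                             config$openness_sd)
    lp <- config$surv_logit_near +
      (dist_class == "far") * config$surv_far_effect +
      config$surv_openness_slope * (openness - config$openness_mean)
    data.frame(site_id = sid, island = isl,
               birds_present = as.integer(isl != "Guam"),
               distance_class = dist_class,
               n_planted = config$seedlings_per_plot,
               n_survived = stats::rbinom(config$plots_per_site,
                                          config$seedlings_per_plot,
                                          invlogit(lp)),
               canopy_openness = openness)
  }))

  ## --- seed-addition (field germination + early survival), Premna ---
  seed_add <- NULL
  if (config$species == "Premna") {
    set.seed(seeds[7])
    rows <- expand.grid(site_id = paste0("A", 1:config$seed_addition_sites),
                        distance_class = c("near", "far"),
                        plot = seq_len(config$seed_addition_plots_per_distance),
                        stringsAsFactors = FALSE)
    n <- config$seeds_per_addition_plot
    pg <- ifelse(rows$distance_class == "far",
                 config$field_germ_far, config$field_germ_near)
    ps <- ifelse(rows$distance_class == "far",
                 config$field_surv_far, config$field_surv_near)
    germd <- stats::rbinom(nrow(rows), n, pg)
    survd <- stats::rbinom(nrow(rows), germd, ps)
    seed_add <- data.frame(
      site_id = rows$site_id, distance_class = rows$distance_class,
      n_sown = n, n_germinated = germd, n_surviving = survd,
      canopy_openness = stats::rnorm(nrow(rows), config$openness_mean,
                                     config$openness_sd))
  }

  ## --- true phi ratio by forward simulation ---
  truth <- list(config = config, beta_s = beta_s,
                kernels = true_kernels(config))
  if (oracle_n > 0) {
    funs <- true_stage_funs(config)
    phi_present <- forward_simulate_phi(
      true_kernels(config)$Rota,
      p_ingest = function(r) {
        # birds-present scenario averages the three bird islands
        (funs$p_ingest(r, "Rota") + funs$p_ingest(r, "Saipan") +
           funs$p_ingest(r, "Tinian")) / 3
      },
      p_germ = funs$p_germ, p_s1 = funs$p_s1, p_s2 = funs$p_s2,
      n = oracle_n, seed = seeds[8])
    phi_absent <- forward_simulate_phi(
      true_kernels(config)$Guam,
      p_ingest = function(r) rep(0, length(r)),
      p_germ = funs$p_germ, p_s1 = funs$p_s1, p_s2 = funs$p_s2,
      n = oracle_n, seed = seeds[8] + 1L)
    truth$phi_present <- phi_present$phi
    truth$phi_absent <- phi_absent$phi
    truth$phi_ratio <- phi_absent$phi / phi_present$phi
  }

  structure(list(trees = trees, traps = traps, stand = stand,
                 germination = germ, survival = surv,
                 seed_addition = seed_add, truth = truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic %s study: %d traps, %d trees, %d germination trials\n",
              x$truth$config$species, nrow(x$traps), nrow(x$trees),
              nrow(x$germination)))
  if (!is.null(x$truth$phi_ratio))
    cat(sprintf("  true seed-to-seedling survival ratio (no birds : birds): %.3f\n",
                x$truth$phi_ratio))
  invisible(x)
}
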