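# Plain-CSV interchange for the study's tables and JSON serialization
# of fitted objects. Coordinates are planar metres (UTM-like); no CRS
# handling.

tree_schema <- c("tree_id", "site_id", "island", "x_m", "y_m", "dbh_cm")
trap_schema <- c("trap_id", "site_id", "island", "x_m", "y_m", "area_m2",
                 "seed_count", "ingested_count", "total_classified")

check_schema <- function(df, schema, what) {
  miss <- setdiff(schema, names(df))
  if (length(miss))
    stop(what, " file missing columns: ", paste(miss, collapse = ", "))
  df
}

bad_rows <- function(cond) which(cond)

#' Read a mapped-tree table
#'
#' Reads and validates the trees CSV
#' (\code{tree_id,site_id,island,x_m,y_m,dbh_cm}); malformed rows are
#' reported by row number.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_trees <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, tree_schema, "trees")
  bad <- bad_rows(!is.finite(df$dbh_cm) | df$dbh_cm <= 0)
  if (length(bad))
    stop("trees: non-positive or missing dbh at row(s) ",
         paste(bad, collapse = ", "))
  bad <- bad_rows(!is.finite(df$x_m) | !is.finite(df$y_m))
  if (length(bad))
    stop("trees: non-finite coordinates at row(s) ",
         paste(bad, collapse = ", "))
  df
}

#' Read a seed-trap table
#'
#' Reads and validates the traps CSV
#' (\code{trap_id,site_id,island,x_m,y_m,area_m2,seed_count,
#' ingested_count,total_classified}); malformed rows are reported by
#' row number.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_traps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, trap_schema, "traps")
  bad <- bad_rows(!is.finite(df$area_m2) | df$area_m2 <= 0)
  if (length(bad))
    stop("traps: non-positive trap area at row(s) ",
         paste(bad, collapse = ", "))
  cnt <- df[c("seed_count", "ingested_count", "total_classified")]
  bad <- bad_rows(apply(cnt, 1, function(v)
    any(!is.finite(v) | v < 0 | v != round(v))))
  if (length(bad))
    stop("traps: counts must be non-negative integers; bad row(s) ",
         paste(bad, collapse = ", "))
  bad <- bad_rows(df$ingested_count > df$total_classified)
  if (length(bad))
    stop("traps: ingested_count exceeds total_classified at row(s) ",
         paste(bad, collapse = ", "))
  df
}

#' Read a mapped stand (trees + traps) from CSV files
#'
#' Validates both tables and assembles them into a
#' \code{\link{stand_data}}, computing trap-tree distances and each
#' trap's nearest-conspecific distance.
#'
#' @param trees_path,traps_path CSV paths.
#' @param mapping_radius passed to \code{\link{stand_data}}.
#' @return a \code{\link{stand_data}}.
#' @export
read_stand <- function(trees_path, traps_path, mapping_radius = 20) {
  stand_data(read_trees(trees_path), read_traps(traps_path),
             mapping_radius = mapping_radius)
}

#' Write the synthetic (or assembled) study tables to CSV
#'
#' Writes the trees, traps, germination, survival and (if present)
#' seed-addition tables of a \code{\link{simulate_world}} result into a
#' directory, plus the ground truth as JSON.
#'
#' @param world a \code{"synthetic_world"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trees = file.path(dir, "trees.csv"),
             traps = file.path(dir, "traps.csv"),
             germination = file.path(dir, "germination.csv"),
             survival = file.path(dir, "survival_plots.csv"))
  utils::write.csv(world$trees[, tree_schema], paths["trees"],
                   row.names = FALSE)
  utils::write.csv(world$traps[, trap_schema], paths["traps"],
                   row.names = FALSE)
  utils::write.csv(world$germination, paths["germination"],
                   row.names = FALSE)
  utils::write.csv(world$survival, paths["survival"], row.names = FALSE)
  if (!is.null(world$seed_addition)) {
    paths["seed_addition"] <- file.path(dir, "seed_addition.csv")
    utils::write.csv(world$seed_addition, paths["seed_addition"],
                     row.names = FALSE)
  }
  truth <- world$truth
  truth$kernels <- NULL
  truth$config <- unclass(truth$config)
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Write posterior draws to CSV
#'
#' One row per retained draw: chain, iteration, all parameters on the
#' natural scale, and the deviance.
#'
#' @param fit a \code{\link{fit_dispersal}} result.
#' @param path CSV path.
#' @return invisibly, \code{path}.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "dispersal_fit"))
  out <- cbind(fit$draws, deviance = fit$deviance)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a stage fit to JSON
#'
#' Coefficients, fixed-effect covariance, AICc table and profile CIs of
#' a \code{"stage_fit"}, written as JSON.
#'
#' @param fit a \code{"stage_fit"}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_stage_fit <- function(fit, path) {
  stopifnot(inherits(fit, "stage_fit"))
  jsonlite::write_json(list(
    stage = fit$stage, formula_tag = fit$formula_tag,
    coefficients = as.list(fit$coefficients),
    vcov = fit$vcov, aicc_table = fit$aicc_table,
    profile_ci = fit$ci, n = fit$n, notes = fit$notes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
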