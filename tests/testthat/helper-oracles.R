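# Independent oracles used across the suite. These deliberately avoid
# the package's own closed forms: integrals are computed by adaptive
# quadrature on a transformed axis (u = sqrt(r/a) tames the
# power-exponential cusp at the origin), and NB probabilities by
# brute-force pmf summation.

# quadrature of h(r) over [0, upper): u = sqrt(r) transform near the
# origin (tames the power-exponential cusp), direct adaptive quadrature
# with an infinite upper limit for the tail (handles the slow algebraic
# decay of the 2Dt integrands)
quad_radial <- function(h, upper = Inf, split = 1, rel.tol = 1e-12) {
  if (upper <= split)
    return(stats::integrate(function(u) h(u^2) * 2 * u, 0, sqrt(upper),
                            rel.tol = rel.tol, subdivisions = 400L)$value)
  head_part <- stats::integrate(function(u) h(u^2) * 2 * u, 0, sqrt(split),
                                rel.tol = rel.tol, subdivisions = 400L)$value
  tail_part <- stats::integrate(h, split, upper, rel.tol = rel.tol,
                                subdivisions = 400L)$value
  head_part + tail_part
}

oracle_norm <- function(kernel) {
  quad_radial(function(r) radial_pdf(kernel, r))
}

oracle_mean <- function(kernel) {
  quad_radial(function(r) r * radial_pdf(kernel, r))
}

oracle_cdf <- function(kernel, R) {
  quad_radial(function(r) radial_pdf(kernel, r), upper = R)
}

# numerically locate the mode of the radial pdf
oracle_mode <- function(kernel, upper = 50 * kernel$a) {
  stats::optimize(function(r) radial_pdf(kernel, r),
                  c(0, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# tiny two-trap, two-tree stand for hand-checkable likelihood sums
toy_stand <- function(counts = c(3L, 0L)) {
  trees <- data.frame(
    tree_id = c("t1", "t2"), site_id = "s1", island = "Rota",
    x_m = c(0, 4), y_m = c(0, 0), dbh_cm = c(20, 10))
  traps <- data.frame(
    trap_id = c("p1", "p2"), site_id = "s1", island = "Rota",
    x_m = c(1, 3), y_m = c(0, 0), area_m2 = 0.5,
    seed_count = counts, ingested_count = 0L,
    total_classified = counts)
  stand_data(trees, traps)
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
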