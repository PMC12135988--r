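# Independent oracles and small fixtures shared across the test files.
# Everything here is built in code at test time; no stored binaries.

# Debye-sum form factor of a weighted point cloud: P(q) normalized to 1 at
# q = 0, computed from the pair-distance histogram (exact for the cloud).
debye_pointcloud <- function(xyz, w, q, nbins = 400) {
  d <- as.vector(stats::dist(xyz))
  ww <- tcrossprod(w)
  wpair <- 2 * ww[lower.tri(ww)]  # dist() returns lower-triangle order
  rmax <- max(d)
  bin <- pmin(floor(d / rmax * nbins) + 1L, nbins)
  hw <- vapply(seq_len(nbins), function(b) sum(wpair[bin == b]), numeric(1))
  rmid <- (seq_len(nbins) - 0.5) * rmax / nbins
  self_term <- sum(w^2)
  tot <- sum(w)^2
  vapply(q, function(qq) {
    x <- qq * rmid
    sinc <- ifelse(x < 1e-8, 1, sin(x) / x)
    (self_term + sum(hw * sinc)) / tot
  }, numeric(1))
}

# uniform random points in a ball of radius R
sample_ball <- function(n, R) {
  u <- stats::runif(n)^(1 / 3) * R
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v * u
}

# uniform random points in a cylinder (radius R, length L, centred at z0)
sample_cylinder <- function(n, R, L, z0 = 0) {
  r <- sqrt(stats::runif(n)) * R
  th <- stats::runif(n, 0, 2 * pi)
  z <- stats::runif(n, -L / 2, L / 2) + z0
  cbind(r * cos(th), r * sin(th), z)
}

# point cloud for the core + 3 shell sphere: points uniform in the outer
# ball, weighted by the contrast of the region they fall in
coreshell_cloud <- function(n, radii, rho_all) {
  xyz <- sample_ball(n, max(radii))
  rr <- sqrt(rowSums(xyz^2))
  region <- findInterval(rr, radii) + 1L  # 1 = core, ... inside radii[k]
  w <- rho_all[pmin(region, length(rho_all))]
  list(xyz = xyz, w = w)
}

# standard benchmark pair: one simulated SAXS-like + SANS-like dataset
sim_pair <- function(seed = 1, M_saxs = 400, M_sans = 50, k = 5e6) {
  m <- sas_model("coreshell3")
  th <- truth_coreshell()
  set.seed(seed)
  list(model = m, truth = th,
       curves = list(
         simulate_dataset(m, th, 1, make_qgrid(1e-3, 0.5, M_saxs),
                          noise_spec("saxs", k = k), label = "SAXS"),
         simulate_dataset(m, th, 2, make_qgrid(1e-3, 0.5, M_sans),
                          noise_spec("sans", k = k), label = "SANS")))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
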