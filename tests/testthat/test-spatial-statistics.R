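make_site <- function(center, n = 150, sd = 100, seed = 1) {
  set.seed(seed)
  P <- sweep(matrix(rnorm(3 * n, 0, sd), ncol = 3), 2, center, "+")
  tab <- loc_table(P[, 1], P[, 2], P[, 3], 0L, "edu")
  detect_replication_sites(tab, dbscan_params(eps_nm = 150, min_pts = 10))
}

test_that("recycling scores implement h / (e * H_total) with its invariances", {
  sites <- make_site(c(0, 0, 0))
  expect_equal(nrow(sites), 1L)
  hull <- attr(sites, "hulls")[[1]]

  set.seed(2)
  inside <- sample_in_mask(20, nucleus_mask(rbind(c(-20, -20), c(20, -20),
                                                  c(20, 20), c(-20, 20)),
                                            c(-20, 20)))
  outside <- sweep(matrix(rnorm(300, 0, 50), ncol = 3), 2, c(5000, 0, 0), "+")
  par <- rbind(inside, outside)
  tab <- loc_table(par[, 1], par[, 2], par[, 3], 0L, "histone")
  stopifnot(all(points_in_hull(hull, inside)))

  rs <- recycling_scores(tab, sites)
  expect_equal(rs$h, 20L)
  expect_equal(rs$score, 20 / (sites$n * nrow(tab)))

  ## worked example: h=20, e=400, H=10000 -> 5e-6
  expect_equal(20 / (400 * 10000), 5e-6)

  ## doubling the parental signal everywhere leaves scores unchanged
  tab2 <- rbind(tab, tab); class(tab2) <- c("loc_table", "data.frame")
  rs2 <- recycling_scores(tab2, sites)
  expect_equal(rs2$score, rs$score)

  ## h = 0 -> score 0; H_total = 0 -> error
  far <- loc_table(9000, 9000, 9000, 0L, "histone")
  expect_equal(recycling_scores(far, sites)$score, 0)
  expect_error(recycling_scores(tab[0, ], sites), "H_total")
})

test_that("radial profiles bin by 50 nm shells and normalize by shell volume", {
  set.seed(3)
  ## all detections within 25 nm of the center: only shell [0,50) populated
  P <- matrix(rnorm(300, 0, 8), ncol = 3)
  P <- P[sqrt(rowSums(P^2)) < 25, , drop = FALSE]
  tab <- loc_table(P[, 1], P[, 2], P[, 3], 0L, "h")
  rp <- radial_profile(tab, c(0, 0, 0), 500)
  expect_equal(rp$count[1], nrow(P))
  expect_true(all(rp$count[-1] == 0))
  expect_equal(rp$volume_nm3[2], 4 / 3 * pi * (100^3 - 50^3))
  expect_equal(sum(rp$count), nrow(P)) # conservation

  ## slab clipping reduces shell volumes beyond the half-thickness
  mask <- nucleus_mask(ellipse_polygon(8000, 5000), c(-300, 300))
  rp_slab <- radial_profile(tab, c(0, 0, 0), 500, clip_mode = "slab", mask = mask)
  expect_equal(rp_slab$volume_nm3[1:6], rp$volume_nm3[1:6]) # shells inside slab
  expect_lt(rp_slab$volume_nm3[10], rp$volume_nm3[10])
  expect_equal(sum(rp_slab$count), nrow(P))

  expect_warning(radial_profile(tab, c(9000, 0, 0), 200, mask = mask), "outside")
})

test_that("uniform scenes give flat volume-normalized radial densities", {
  set.seed(4)
  n <- 60000
  R <- 1000
  P <- matrix(runif(3 * n, -R, R), ncol = 3)
  P <- P[sqrt(rowSums(P^2)) <= R, , drop = FALSE]
  tab <- loc_table(P[, 1], P[, 2], P[, 3], 0L, "h")
  rp <- radial_profile(tab, c(0, 0, 0), 800)
  lambda <- nrow(P) / (4 / 3 * pi * R^3)
  ## each shell count is Poisson(lambda * V): all within 4 sigma of flat
  zs <- (rp$count - lambda * rp$volume_nm3) / sqrt(lambda * rp$volume_nm3)
  expect_true(all(abs(zs) < 4))
  ## pooled profile over several centers stays flat too
  sites <- make_site(c(0, 0, 0))
  sites2 <- rbind(sites, sites)
  sites2$cx <- c(-300, 300); sites2$cy <- 0; sites2$cz <- 0
  attr(sites2, "hulls") <- rep(attr(sites, "hulls"), 2)
  class(sites2) <- c("site_set", "data.frame")
  rp2 <- radial_profile_sites(tab, sites2, 600)
  z2 <- (rp2$count - lambda * rp2$volume_nm3) / sqrt(lambda * rp2$volume_nm3)
  expect_true(all(abs(z2) < 4))
})

test_that("m-function calibrates to 1, detects attraction and repulsion", {
  mask <- nucleus_mask(ellipse_polygon(4000, 2500), c(-300, 300))
  set.seed(5)
  A <- sample_in_mask(3000, mask)
  B <- sample_in_mask(3000, mask)
  mf <- m_function(A, B, mask, n_baseline = 10, seed = 17)
  expect_equal(mean(mf$m), 1, tolerance = 0.05)

  ## B at A's positions: strong attraction at small radii
  mf_co <- m_function(A, A + matrix(rnorm(length(A), 0, 10), ncol = 3), mask,
                      radii = seq(50, 300, 25), n_baseline = 5, seed = 17)
  expect_gt(mf_co$m[1], 1.5)

  ## disjoint halves: repulsion at small radii
  left <- A[A[, 1] < -500, , drop = FALSE]
  right <- B[B[, 1] > 500, , drop = FALSE]
  mf_rep <- m_function(left, right, mask, radii = seq(50, 300, 25),
                       n_baseline = 5, seed = 17)
  expect_lt(mf_rep$m[1], 0.5)

  expect_error(m_function(A, B, mask, n_baseline = 0), "n_baseline")
  expect_error(m_function(A[0, , drop = FALSE], B, mask), "non-empty")
})

test_that("m-function is invariant under a common translation of A, B and mask", {
  mask <- nucleus_mask(ellipse_polygon(3000, 2000), c(-300, 300))
  set.seed(6)
  A <- sample_in_mask(1500, mask)
  B <- sample_in_mask(1500, mask)
  mf <- m_function(A, B, mask, radii = seq(50, 300, 50), n_baseline = 5, seed = 3)
  shift <- c(12345, -6789, 111)
  mask2 <- nucleus_mask(sweep(mask$polygon, 2, shift[1:2], "+"),
                        mask$z_range + shift[3])
  mf2 <- m_function(sweep(A, 2, shift, "+"), sweep(B, 2, shift, "+"), mask2,
                    radii = seq(50, 300, 50), n_baseline = 5, seed = 3)
  ## baseline rejection sampling shifts with the bbox, so equality is exact
  expect_equal(mf2$m, mf$m, tolerance = 1e-9)
})

test_that("voronoi densities partition the mask and track local density", {
  mask <- nucleus_mask(rbind(c(0, 0), c(4000, 0), c(4000, 4000), c(0, 4000)),
                       c(-300, 300))
  ## regular interior grid: equal cell areas
  g <- as.matrix(expand.grid(seq(500, 3500, 500), seq(500, 3500, 500)))
  tab <- loc_table(g[, 1], g[, 2], 0, 0L, "h")
  vd <- voronoi_density(tab, mask)
  expect_equal(nrow(vd), nrow(g)) # one polygon per detection
  interior <- g[, 1] > 500 & g[, 1] < 3500 & g[, 2] > 500 & g[, 2] < 3500
  expect_equal(max(vd$area_nm2[interior]) - min(vd$area_nm2[interior]), 0,
               tolerance = 1e-6)
  expect_equal(sum(vd$area_nm2), mask$area_nm2, tolerance = 1e-3)

  ## two-density mosaic: dense half has smaller median polygon area
  set.seed(7)
  dense <- cbind(runif(400, 0, 2000), runif(400, 0, 4000))
  sparse <- cbind(runif(100, 2000, 4000), runif(100, 0, 4000))
  P <- rbind(dense, sparse)
  tab2 <- loc_table(P[, 1], P[, 2], 0, 0L, "h")
  vd2 <- voronoi_density(tab2, mask, small_area_cutoff_nm2 = 2e4)
  expect_equal(sum(vd2$area_nm2), mask$area_nm2, tolerance = 1e-3)
  expect_lt(median(vd2$area_nm2[1:400]), median(vd2$area_nm2[401:500]))
  expect_true(attr(vd2, "small_area_fraction") >= 0)

  ## duplicated detections are jittered with a warning, not dropped
  dup <- loc_table(c(100, 100, 500, 900, 1500), c(100, 100, 700, 300, 1200),
                   0, 0L, "h")
  expect_warning(vd3 <- voronoi_density(dup, mask), "jitter")
  expect_equal(nrow(vd3), 5L)
})

test_that("compare_distributions reports peaks, shifts, p values and stars", {
  set.seed(8)
  a <- rnorm(2000, 1, 0.02)
  same <- compare_distributions(a, a)
  expect_equal(same$peak_shift_percent, 0)
  expect_equal(same$stars, "ns")
  expect_gt(same$p_value, 0.9)

  ## peaks at 1.00 and 0.67: the reported shift convention gives -33%
  b <- rnorm(2000, 0.67, 0.02)
  cmp <- compare_distributions(a, b)
  expect_equal(cmp$peak_shift_percent, -33, tolerance = 0.03)
  ## swapping A and B gives the shift on the swapped reference
  rev <- compare_distributions(b, a)
  expect_equal(rev$peak_shift_percent,
               100 * (cmp$peak_A - cmp$peak_B) / cmp$peak_B, tolerance = 1e-9)

  ## disjoint 10-vs-10: exact two-sided Mann-Whitney p = 2 / C(20,10)
  ex <- compare_distributions(as.numeric(1:10), as.numeric(101:110))
  expect_equal(ex$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(ex$stars, "***")

  ## star thresholds
  expect_equal(star_code(c(0.2, 0.04, 0.005, 5e-4)), c("ns", "*", "**", "***"))

  ## constant sample degenerates to a point mass at that value
  const <- compare_distributions(rep(2, 10), rnorm(10, 2, 0.1))
  expect_equal(const$peak_A, 2)
})

test_that("periphery classification uses the centroid-to-boundary distance", {
  mask <- nucleus_mask(ellipse_polygon(8000, 5000, n = 720), c(-300, 300))
  sites <- make_site(c(0, 0, 0))
  centered <- classify_periphery(sites, mask)
  expect_false(centered$peripheral) # mask centroid of a large nucleus

  edge <- sites
  edge$cx <- 7999; edge$cy <- 0
  expect_true(classify_periphery(edge, mask)$peripheral)
  on_boundary <- sites
  on_boundary$cx <- 8000; on_boundary$cy <- 0
  expect_true(classify_periphery(on_boundary, mask)$peripheral)
  expect_true(classify_periphery(sites, mask, peripheral_band_nm = Inf)$peripheral)
})
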