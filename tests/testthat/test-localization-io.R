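test_that("localization tables round-trip through CSV", {
  tab <- rand_table(10000, seed = 11, channels = c("A", "B"))
  tab$intensity <- rexp(10000, 1e-3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations(tab, path)
  back <- read_localizations(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)

  small <- utils::read.csv(path)[1:3, ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(small, p2, row.names = FALSE)
  expect_equal(nrow(read_localizations(p2)), 3L)
})

test_that("read_localizations reports format problems precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,frame,channel", "1,2,0,A"), path)
  expect_error(read_localizations(path), "missing required column 'z'")

  writeLines(c("x,y,z,frame,channel", "1,2,3,0,A", "1,oops,3,0,A"), path)
  expect_error(read_localizations(path), "non-numeric y at line 3")

  ## ThunderSTORM-style headers, pixel-unit conversion at read time
  writeLines(c("\"frame\",\"x [nm]\",\"y [nm]\",\"z [nm]\"", "1,2,3,50"), path)
  ts <- read_localizations(path, dialect = "thunderstorm", pixel_size_nm = 160)
  expect_equal(ts$x, 320)
  expect_equal(ts$z, 50) # z is already nm; only xy are pixel-scaled
  expect_equal(ts$channel, "A")
})

test_that("drift estimation recovers constant, linear and noisy sinusoidal drift", {
  frames <- 0:999
  ## constant positions -> all offsets zero
  b <- bead_track("b1", frames, 100, 200, 300)
  m <- estimate_drift(b, smoothing_window = 1)
  expect_true(all(abs(c(m$dx, m$dy, m$dz)) < 1e-12))

  ## single bead, linear 1 nm/frame
  b <- bead_track("b1", frames, 100 + frames, 200, 300)
  m <- estimate_drift(b, smoothing_window = 1)
  expect_equal(m$dx, as.numeric(frames))
  expect_equal(m$dy, rep(0, 1000))

  ## endpoint displacement of a 1 nm/frame truth over 1000 frames is 999 nm
  fid <- generate_fiducials(0, 1000, 3, seed = 5, noise_nm = 0,
                            drift_series = data.frame(frame = frames, dx = frames,
                                                      dy = 0, dz = 0))
  expect_equal(fid$drift$dx[1000] - fid$drift$dx[1], 999)

  ## 3 noisy beads, sinusoidal truth: RMS error below noise / sqrt(n_beads)
  noise <- 3
  fid <- generate_fiducials(40, 2000, 3, seed = 9, noise_nm = noise)
  m <- estimate_drift(fid$beads, smoothing_window = 25)
  err <- sqrt(mean((m$dx - fid$drift$dx)^2 + (m$dy - fid$drift$dy)^2 +
                     (m$dz - fid$drift$dz)^2) / 3)
  expect_lt(err, noise / sqrt(3))
})

test_that("apply_drift translates, inverts exactly, and validates coverage", {
  tab <- rand_table(200, seed = 3, frames = 50L)
  zero <- data.frame(frame = 0:49, dx = 0, dy = 0, dz = 0)
  expect_equal(apply_drift(tab, zero), tab)

  model <- data.frame(frame = 0:49, dx = rnorm(50), dy = rnorm(50), dz = rnorm(50))
  out <- apply_drift(tab, model)
  expect_equal(nrow(out), nrow(tab))
  expect_equal(apply_drift(out, model, invert = TRUE), tab, tolerance = 1e-12)

  expect_error(apply_drift(tab, model[1:10, ]), "does not cover frames")
})

test_that("register_channels recovers identity, translation and noisy rigid maps", {
  fid <- generate_fiducials(0, 50, 10, seed = 2, noise_nm = 0)
  A <- fid$beads
  expect_error(register_channels(A[A$bead == "bead01", ], A, "affine"),
               "at least 3")

  tr <- register_channels(A, A, "rigid")
  expect_equal(tr$A, diag(3), tolerance = 1e-9)
  expect_equal(tr$t, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(tr$rms, 1e-9)

  B <- A; B$x <- B$x - 10; B$y <- B$y + 5
  tr <- register_channels(A, B, "translation")
  expect_equal(tr$t, c(10, -5, 0), tolerance = 1e-9)

  ## random rigid motion + 5 nm bead noise: recovered within the noise bound
  set.seed(21)
  th <- 0.02
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- A
  xyz <- t(R %*% t(as.matrix(A[, c("x", "y", "z")]))) +
    matrix(rnorm(3 * nrow(A), 0, 5), ncol = 3)
  B$x <- xyz[, 1]; B$y <- xyz[, 2]; B$z <- xyz[, 3]
  tr <- register_channels(B, A, "rigid") # maps A onto the rotated copy
  expect_equal(tr$A, R, tolerance = 0.02)
  expect_lt(tr$rms, 3 * 5)
  corrected <- apply_transform(tr, A)
  expect_lt(sqrt(mean((corrected$x - B$x)^2)), 2 * 5)
})

test_that("merge_consecutive follows the 50 nm consecutive-frame rule", {
  two <- loc_table(c(0, 30), c(0, 0), c(0, 0), c(5L, 6L), "A")
  merged <- merge_consecutive(two)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$x, 15) # unweighted mean position
  expect_equal(merged$frame, 5L) # first frame of the chain

  ## same distance but frames 5 and 7: not consecutive, no merge
  gap <- loc_table(c(0, 30), c(0, 0), c(0, 0), c(5L, 7L), "A")
  expect_equal(nrow(merge_consecutive(gap)), 2L)

  ## 60 nm apart in consecutive frames: outside the radius
  far <- loc_table(c(0, 60), c(0, 0), c(0, 0), c(5L, 6L), "A")
  expect_equal(nrow(merge_consecutive(far)), 2L)

  ## chain over frames 5,6,7 with < 50 nm hops collapses to one mean record
  chain <- loc_table(c(0, 40, 80), c(0, 0, 0), c(0, 0, 0), 5:7, "A")
  merged <- merge_consecutive(chain)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$x, 40)
  expect_equal(merged$frame, 5L)

  ## channels never merge with each other
  cross <- loc_table(c(0, 10), c(0, 0), c(0, 0), c(5L, 6L), c("A", "B"))
  expect_equal(nrow(merge_consecutive(cross)), 2L)

  expect_error(merge_consecutive(two, radius_nm = -1), "non-negative")
})

test_that("merge_consecutive matches the brute-force oracle and is idempotent", {
  for (seed in 1:20) {
    tab <- rand_table(18, seed = 100 + seed, box = 150, frames = 6L,
                      channels = c("A", "B"))
    got <- merge_consecutive(tab)
    want <- brute_merge(tab, 50)
    expect_equal(as.data.frame(got)[, c("x", "y", "z", "frame", "channel")],
                 as.data.frame(want)[, c("x", "y", "z", "frame", "channel")],
                 tolerance = 1e-12)
    expect_lte(nrow(got), nrow(tab))
    expect_equal(merge_consecutive(got), got) # idempotent
    ## permutation invariance
    perm <- tab[sample(nrow(tab)), ]
    expect_equal(as.data.frame(merge_consecutive(perm)), as.data.frame(got),
                 tolerance = 1e-12)
  }
})

test_that("clip_z_section keeps the half-open interval", {
  tab <- loc_table(1:5, 1:5, c(-100, 0, 299.9, 300, 500), 0L, "A")
  out <- clip_z_section(tab, -300, 300)
  expect_equal(out$z, c(-100, 0, 299.9)) # z = z_max dropped
  expect_equal(clip_z_section(tab, -1000, 1000), tab)
  expect_error(clip_z_section(tab, 10, 10))

  ## uniform z over 1200 nm clipped to 600 nm keeps about half
  set.seed(4)
  u <- loc_table(runif(20000), runif(20000), runif(20000, -600, 600), 0L, "A")
  frac <- nrow(clip_z_section(u, -300, 300)) / 20000
  expect_equal(frac, 0.5, tolerance = 0.02)
})

test_that("segment_nucleus builds a hull mask containing the detections", {
  sq <- loc_table(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000), c(0, 10, 20, 30), 0L, "A")
  mask <- segment_nucleus(sq)
  expect_equal(mask$area_nm2, 1e6)
  expect_equal(mask$z_range, c(0, 30))

  tab <- rand_table(2000, seed = 6)
  mask <- segment_nucleus(tab)
  xy <- cbind(tab$x, tab$y)
  inside <- point_in_polygon(xy, mask$polygon) |
    dist_to_polygon_boundary(xy, mask$polygon) < 1e-6
  expect_true(all(inside))

  ## dense uniform square: hull area within 2% of the true square
  set.seed(12)
  dense <- loc_table(runif(20000, 0, 1000), runif(20000, 0, 1000), runif(20000), 0L, "A")
  expect_equal(segment_nucleus(dense)$area_nm2, 1e6, tolerance = 0.02)

  expect_error(segment_nucleus(loc_table(c(0, 1, 2), c(0, 1, 2), 0:2, 0L, "A")),
               "collinear")
})
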