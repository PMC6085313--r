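# Quantitative spatial analyses around replication sites: recycling scores,
# 50 nm concentric-shell radial profiles, the Monte-Carlo-normalized
# m-function, Voronoi density maps, KDE peak-shift comparisons and the
# periphery/interior split.

#' Parental-histone recycling scores at replication sites
#'
#' For each site, `h` = parental detections inside the site hull, `e` = EdU
#' detections of the site, `H_total` = parental detections in the whole
#' nucleus; score = `h / (e * H_total)`.
#'
#' @param parental_table `loc_table` of the parental-histone channel (whole
#'   nucleus).
#' @param sites a `site_set` of replication sites (EdU clusters).
#' @param H_total total parental detections; default `nrow(parental_table)`.
#' @return data.frame (site, h, e, H_total, score), one row per site.
#' @export
recycling_scores <- function(parental_table, sites, H_total = nrow(parental_table)) {
  if (H_total == 0L) stop("recycling_scores: no parental signal (H_total = 0)")
  P <- cbind(parental_table$x, parental_table$y, parental_table$z)
  hulls <- attr(sites, "hulls")
  h <- vapply(seq_len(nrow(sites)), function(k) {
    sum(points_in_hull(hulls[[k]], P))
  }, numeric(1L))
  data.frame(site = sites$cluster, h = as.integer(h), e = sites$n,
             H_total = H_total, score = h / (sites$n * H_total))
}

#' Radial profile of detections around a site center
#'
#' Detections are assigned to 50 nm wide concentric shells by 3D Euclidean
#' distance to the center; each shell count is normalized by the shell
#' volume — the full spherical shell (`clip_mode = "none"`) or its analytic
#' intersection with the optical z slab (`clip_mode = "slab"`).
#'
#' @param table `loc_table` of the surrounding signal.
#' @param center length-3 site center of gravity (nm).
#' @param max_radius_nm outermost shell edge (nm).
#' @param shell_width_nm shell width; default 50.
#' @param clip_mode `"none"` or `"slab"`.
#' @param mask optional `nucleus_mask`; supplies the slab for
#'   `clip_mode = "slab"` and triggers a warning when the center lies outside
#'   the mask polygon.
#' @return a `radial_profile`: data.frame (r_lo, r_hi, count, volume_nm3,
#'   density).
#' @export
radial_profile <- function(table, center, max_radius_nm, shell_width_nm = 50,
                           clip_mode = c("none", "slab"), mask = NULL) {
  clip_mode <- match.arg(clip_mode)
  stopifnot(shell_width_nm > 0, max_radius_nm > 0, length(center) == 3L)
  if (!is.null(mask) && !point_in_polygon(center[1:2], mask$polygon)) {
    warning("radial_profile: site center lies outside the nucleus mask")
  }
  if (clip_mode == "slab" && is.null(mask))
    stop("radial_profile: clip_mode 'slab' needs a mask with a z range")
  edges <- seq(0, max_radius_nm, by = shell_width_nm)
  if (edges[length(edges)] < max_radius_nm) edges <- c(edges, max_radius_nm)
  k <- length(edges) - 1L
  d <- sqrt((table$x - center[1L])^2 + (table$y - center[2L])^2 +
            (table$z - center[3L])^2)
  counts <- tabulate(findInterval(d[d < edges[k + 1L]], edges), nbins = k)
  vols <- if (clip_mode == "none") {
    shell_volume(edges[-(k + 1L)], edges[-1L])
  } else {
    zl <- mask$z_range[1L] - center[3L]
    zh <- mask$z_range[2L] - center[3L]
    vapply(seq_len(k), function(i) shell_volume(edges[i], edges[i + 1L], zl, zh),
           numeric(1L))
  }
  out <- data.frame(r_lo = edges[-(k + 1L)], r_hi = edges[-1L],
                    count = counts, volume_nm3 = vols,
                    density = ifelse(vols > 0, counts / vols, NA_real_))
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Pooled radial profile over all replication sites of a cell
#'
#' Counts are summed across sites per shell and divided by the summed shell
#' volumes (`aggregate = "pooled"`, the default), or profiles are averaged
#' per site (`aggregate = "per_site"`).
#'
#' @inheritParams radial_profile
#' @param sites a `site_set`; the centers of gravity are used.
#' @param aggregate `"pooled"` or `"per_site"`.
#' @return a `radial_profile` data.frame.
#' @export
radial_profile_sites <- function(table, sites, max_radius_nm,
                                 shell_width_nm = 50,
                                 clip_mode = c("none", "slab"), mask = NULL,
                                 aggregate = c("pooled", "per_site")) {
  clip_mode <- match.arg(clip_mode)
  aggregate <- match.arg(aggregate)
  stopifnot(nrow(sites) >= 1L)
  profs <- lapply(seq_len(nrow(sites)), function(k) {
    suppressWarnings(radial_profile(
      table, c(sites$cx[k], sites$cy[k], sites$cz[k]), max_radius_nm,
      shell_width_nm, clip_mode, mask))
  })
  base <- profs[[1L]][, c("r_lo", "r_hi")]
  if (aggregate == "pooled") {
    counts <- Reduce(`+`, lapply(profs, `[[`, "count"))
    vols <- Reduce(`+`, lapply(profs, `[[`, "volume_nm3"))
    out <- cbind(base, count = counts, volume_nm3 = vols,
                 density = ifelse(vols > 0, counts / vols, NA_real_))
  } else {
    dens <- rowMeans(do.call(cbind, lapply(profs, `[[`, "density")), na.rm = TRUE)
    out <- cbind(base, count = Reduce(`+`, lapply(profs, `[[`, "count")),
                 volume_nm3 = NA_real_, density = dens)
  }
  class(out) <- c("radial_profile", "data.frame")
  out
}

# ---- m-function -----------------------------------------------------------

## All A-B pair distances not exceeding `cutoff`, via a uniform grid of cell
## size `cutoff` (27-cell probe). Returns a numeric vector of distances.
pair_distances_within <- function(A, B, cutoff) {
  key3 <- function(M) cbind(floor(M[, 1L] / cutoff), floor(M[, 2L] / cutoff),
                            floor(M[, 3L] / cutoff))
  ca <- key3(A); cb <- key3(B)
  kb <- paste(cb[, 1L], cb[, 2L], cb[, 3L])
  b_by_cell <- split(seq_len(nrow(B)), kb)
  ka <- paste(ca[, 1L], ca[, 2L], ca[, 3L])
  a_by_cell <- split(seq_len(nrow(A)), ka)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", length(a_by_cell))
  cell_ids <- do.call(rbind, strsplit(names(a_by_cell), " "))
  storage.mode(cell_ids) <- "double"
  for (g in seq_along(a_by_cell)) {
    keys <- paste(cell_ids[g, 1L] + offs[, 1L], cell_ids[g, 2L] + offs[, 2L],
                  cell_ids[g, 3L] + offs[, 3L])
    cand <- unlist(b_by_cell[keys], use.names = FALSE)
    if (!length(cand)) next
    ai <- a_by_cell[[g]]
    d2 <- outer(A[ai, 1L], B[cand, 1L], "-")^2 +
      outer(A[ai, 2L], B[cand, 2L], "-")^2 +
      outer(A[ai, 3L], B[cand, 3L], "-")^2
    d2 <- d2[d2 <= cutoff^2]
    out[[g]] <- sqrt(d2)
  }
  unlist(out, use.names = FALSE)
}

## Gaussian kernel sum of the A-B distance distribution at `radii`,
## normalized by nA * nB * bandwidth (pairs beyond max(radii) + 4 bw
## contribute nothing at the evaluated radii and are skipped exactly).
cross_distance_density <- function(A, B, radii, bandwidth) {
  cutoff <- max(radii) + 4 * bandwidth
  d <- pair_distances_within(A, B, cutoff)
  if (!length(d)) return(rep(0, length(radii)))
  ## binned kernel evaluation: distances land in fine bins, kernel applied to
  ## bin centers (bin width bandwidth/10 -> negligible smoothing error)
  bw10 <- bandwidth / 10
  nb <- ceiling(cutoff / bw10)
  h <- tabulate(pmin(nb, 1L + floor(d / bw10)), nbins = nb)
  centers <- (seq_len(nb) - 0.5) * bw10
  ksum <- vapply(radii, function(r) {
    sum(h * stats::dnorm((r - centers) / bandwidth))
  }, numeric(1L))
  ksum / (nrow(A) * nrow(B) * bandwidth)
}

#' Sample points uniformly inside a nucleus mask
#' @param n number of points.
#' @param mask a `nucleus_mask`.
#' @return n x 3 matrix (nm).
#' @export
sample_in_mask <- function(n, mask) {
  poly <- mask$polygon
  bx <- range(poly[, 1L]); by <- range(poly[, 2L])
  out <- matrix(NA_real_, 0L, 3L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, bx[1L], bx[2L]), stats::runif(m, by[1L], by[2L]))
    cand <- cand[point_in_polygon(cand, poly), , drop = FALSE]
    if (nrow(cand)) {
      z <- stats::runif(nrow(cand), mask$z_range[1L], mask$z_range[2L])
      out <- rbind(out, cbind(cand, z))
    }
  }
  out[seq_len(n), , drop = FALSE]
}

#' Distance-resolved enrichment between two channels (m-function)
#'
#' The numerator is the kernel-smoothed density of all A-B pairwise
#' distances evaluated at `radii`; the denominator is the mean of the same
#' statistic over `n_baseline` paired uniform samples of the same sizes drawn
#' inside the nucleus mask. m = 1 indicates independence, > 1 attraction,
#' < 1 repulsion.
#'
#' @param table_A,table_B `loc_table`s (or n x 3 matrices) of the two signals.
#' @param mask a `nucleus_mask` for baseline sampling.
#' @param radii evaluation radii (nm); default 50-500 nm in 25 nm steps.
#' @param bandwidth_nm Gaussian kernel bandwidth; default 25 nm.
#' @param n_baseline number of Monte-Carlo baseline replicates; default 20.
#' @param seed RNG seed for the baseline draws.
#' @return an `m_function_curve`: data.frame (radius, m, observed, baseline)
#'   with attributes `n_baseline` and `seed`.
#' @export
m_function <- function(table_A, table_B, mask, radii = seq(50, 500, by = 25),
                       bandwidth_nm = 25, n_baseline = 20L, seed = NULL) {
  if (n_baseline < 1L) stop("m_function: n_baseline must be >= 1")
  as_mat <- function(t) if (is.matrix(t)) t else cbind(t$x, t$y, t$z)
  A <- as_mat(table_A); B <- as_mat(table_B)
  if (!nrow(A) || !nrow(B)) stop("m_function: both tables must be non-empty")
  obs <- cross_distance_density(A, B, radii, bandwidth_nm)
  base <- with_seed(seed, {
    rowMeans(vapply(seq_len(n_baseline), function(j) {
      Au <- sample_in_mask(nrow(A), mask)
      Bu <- sample_in_mask(nrow(B), mask)
      cross_distance_density(Au, Bu, radii, bandwidth_nm)
    }, numeric(length(radii))))
  })
  out <- data.frame(radius = radii, m = ifelse(base > 0, obs / base, NA_real_),
                    observed = obs, baseline = base)
  attr(out, "n_baseline") <- as.integer(n_baseline)
  attr(out, "seed") <- seed
  class(out) <- c("m_function_curve", "data.frame")
  out
}

# ---- Voronoi density ------------------------------------------------------

#' Voronoi density map of a localization table
#'
#' 2D Voronoi tessellation of the xy coordinates, every cell clipped to the
#' (convex) nucleus mask so each detection owns one finite polygon whose area
#' is inversely proportional to local density. Cells are built by clipping
#' the mask with the perpendicular-bisector half-planes of neighbors in
#' distance order, stopping once the security radius proves the cell final.
#'
#' @param table a `loc_table` (>= 4 xy points).
#' @param mask a convex `nucleus_mask`.
#' @param small_area_cutoff_nm2 optional cutoff; the summary reports the
#'   fraction of polygons below it.
#' @return a `voronoi_density_map`: data.frame (x, y, area_nm2) plus
#'   attributes `mask_area_nm2` and `small_area_fraction`.
#' @export
voronoi_density <- function(table, mask, small_area_cutoff_nm2 = NULL) {
  xy <- cbind(table$x, table$y)
  if (nrow(xy) < 4L) stop("voronoi_density: need at least 4 points")
  dup <- duplicated(xy)
  if (any(dup)) {
    warning("voronoi_density: ", sum(dup), " duplicate xy points jittered by < 0.1 nm")
    k <- ave(seq_len(nrow(xy)), paste(xy[, 1L], xy[, 2L]), FUN = seq_along) - 1L
    xy[, 1L] <- xy[, 1L] + 0.01 * k
    xy[, 2L] <- xy[, 2L] + 0.013 * k
  }
  n <- nrow(xy)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xy[, 1L] - xy[i, 1L])^2 + (xy[, 2L] - xy[i, 2L])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    cell <- mask$polygon
    for (j in ord) {
      dj <- sqrt(d2[j])
      ## security radius: no farther neighbor can cut the current cell
      rmax <- sqrt(max((cell[, 1L] - xy[i, 1L])^2 + (cell[, 2L] - xy[i, 2L])^2))
      if (dj / 2 > rmax) break
      mid <- (xy[i, ] + xy[j, ]) / 2
      dir <- xy[j, ] - xy[i, ]
      cell <- clip_polygon_halfplane(cell, dir[1L], dir[2L], sum(dir * mid))
      if (nrow(cell) < 3L) break
    }
    areas[i] <- if (nrow(cell) >= 3L) polygon_area(cell) else 0
  }
  out <- data.frame(x = xy[, 1L], y = xy[, 2L], area_nm2 = areas)
  attr(out, "mask_area_nm2") <- mask$area_nm2
  if (!is.null(small_area_cutoff_nm2))
    attr(out, "small_area_fraction") <- mean(areas < small_area_cutoff_nm2)
  class(out) <- c("voronoi_density_map", "data.frame")
  out
}

# ---- KDE comparisons ------------------------------------------------------

#' Significance star code for a p value
#'
#' `"ns"` for p > 0.05; `*` 0.01 < p <= 0.05; `**` 0.001 < p <= 0.01;
#' `***` p <= 0.001.
#'
#' @param p p value(s).
#' @return character vector of star codes.
#' @export
star_code <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "ns")))
}

#' Compare two sample distributions: KDE peaks, peak shift, Mann-Whitney
#'
#' Gaussian KDE per group (Silverman bandwidth by default) on a common
#' 512-point grid spanning the pooled range; the peak is the grid argmax.
#' `peak_shift_percent = 100 * (peak_B - peak_A) / peak_A`, the convention
#' used to report e.g. a -33% density shift. The p value is a two-sided
#' Mann-Whitney U test with tie correction.
#'
#' @param samples_A,samples_B numeric vectors (each of length >= 5).
#' @param bandwidth_rule `"silverman"` (`bw.nrd0`) or `"sj"`.
#' @return a `distribution_comparison` list: `peak_A`, `peak_B`,
#'   `peak_shift_percent`, `p_value`, `stars`, `kde` (grid data.frame).
#' @export
compare_distributions <- function(samples_A, samples_B,
                                  bandwidth_rule = c("silverman", "sj")) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  stopifnot(length(samples_A) >= 5L, length(samples_B) >= 5L)
  rng <- range(c(samples_A, samples_B))
  peak_of <- function(s) {
    if (stats::sd(s) == 0) return(list(peak = s[1L], kde = NULL)) # point mass
    bw <- if (bandwidth_rule == "silverman") stats::bw.nrd0(s) else stats::bw.SJ(s)
    de <- stats::density(s, bw = bw, n = 512L, from = rng[1L], to = rng[2L])
    list(peak = de$x[which.max(de$y)], kde = data.frame(x = de$x, y = de$y))
  }
  a <- peak_of(samples_A); b <- peak_of(samples_B)
  p <- suppressWarnings(stats::wilcox.test(samples_A, samples_B,
                                           alternative = "two.sided"))$p.value
  structure(list(
    peak_A = a$peak, peak_B = b$peak,
    peak_shift_percent = 100 * (b$peak - a$peak) / a$peak,
    p_value = p, stars = star_code(p),
    kde = list(A = a$kde, B = b$kde),
    n_A = length(samples_A), n_B = length(samples_B)),
    class = "distribution_comparison")
}

#' Flag peripheral replication sites
#'
#' A site is peripheral iff the 2D distance from its centroid to the mask
#' boundary is under `peripheral_band_nm` (default 500 nm).
#'
#' @param sites a `site_set`.
#' @param mask a `nucleus_mask`.
#' @param peripheral_band_nm band width (nm); `Inf` flags everything.
#' @return the `site_set` with logical column `peripheral` added.
#' @export
classify_periphery <- function(sites, mask, peripheral_band_nm = 500) {
  if (nrow(sites) == 0L) {
    sites$peripheral <- logical(0)
    return(sites)
  }
  d <- dist_to_polygon_boundary(cbind(sites$cx, sites$cy), mask$polygon)
  sites$peripheral <- d < peripheral_band_nm
  sites
}
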