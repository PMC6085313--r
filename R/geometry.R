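# ---- 3D convex hull -------------------------------------------------------

#' Convex hull of a 3D point set
#'
#' Incremental convex hull. For each new point outside the current hull the
#' visible faces are removed and the horizon is re-triangulated. Visibility on
#' a convex polytope is decided per face by the signed distance, so no face
#' adjacency structure is needed.
#'
#' @param pts numeric matrix with 3 columns (nm).
#' @param tol numeric degeneracy tolerance, relative to the coordinate range.
#' @return an object of class `hull3d`: list with `vertices` (indices into
#'   `pts` on the hull), `faces` (k x 3 vertex-index matrix), `normals`
#'   (k x 3, outward unit normals), `offsets` (k, `normal . x = offset` on the
#'   face plane), `volume` (nm^3) and `degenerate` (TRUE when the set is
#'   affinely degenerate; volume is then 0).
#' @export
convex_hull_3d <- function(pts, tol = 1e-10) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 1L) stop("convex_hull_3d: need at least one point")
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("convex_hull_3d: points must be 3D")
  if (anyNA(pts) || any(!is.finite(pts))) stop("convex_hull_3d: non-finite coordinates")

  scale <- max(apply(pts, 2L, function(v) diff(range(v))), 1)
  eps <- tol * scale + 1e-12

  degen <- list(vertices = seq_len(nrow(pts)), faces = NULL, normals = NULL,
                offsets = NULL, volume = 0, degenerate = TRUE)
  class(degen) <- "hull3d"
  if (nrow(pts) < 4L) return(degen)

  ## initial simplex: two extreme points, farthest from the line, farthest
  ## from the plane
  i1 <- which.min(pts[, 1L]); i2 <- which.max(pts[, 1L])
  if (max(abs(pts[i1, ] - pts[i2, ])) < eps) {
    d <- rowSums(sweep(pts, 2L, pts[i1, ])^2)
    i2 <- which.max(d)
    if (sqrt(d[i2]) < eps) return(degen)
  }
  ab <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2L, pts[i1, ])
  cr <- cbind(rel[, 2L] * ab[3L] - rel[, 3L] * ab[2L],
              rel[, 3L] * ab[1L] - rel[, 1L] * ab[3L],
              rel[, 1L] * ab[2L] - rel[, 2L] * ab[1L])
  dline <- sqrt(rowSums(cr^2)) / sqrt(sum(ab^2))
  i3 <- which.max(dline)
  if (dline[i3] < eps) return(degen)
  n0 <- crossprod3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  n0 <- n0 / sqrt(sum(n0^2))
  dplane <- abs(rel %*% n0)
  i4 <- which.max(dplane)
  if (dplane[i4] < eps) return(degen)

  verts <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[verts, ])

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  norms <- matrix(0, 4L, 3L); offs <- numeric(4L)
  for (f in 1:4) {
    g <- face_plane(pts, faces[f, ], interior)
    norms[f, ] <- g$n; offs[f] <- g$o
  }

  n <- nrow(pts)
  remaining <- setdiff(seq_len(n), verts)
  repeat {
    if (!length(remaining)) break
    ## farthest remaining point outside any face
    d <- pts[remaining, , drop = FALSE] %*% t(norms) -
      rep(offs, each = length(remaining))
    dmax <- apply(d, 1L, max)
    keep <- dmax > eps
    remaining <- remaining[keep]
    if (!length(remaining)) break
    dmax <- dmax[keep]
    p_i <- remaining[which.max(dmax)]
    p <- pts[p_i, ]

    vis <- which((norms %*% p) - offs > eps)
    if (!length(vis)) { remaining <- setdiff(remaining, p_i); next }
    ## horizon: edges used by exactly one visible face
    edges <- do.call(rbind, lapply(vis, function(f) {
      v <- faces[f, ]
      rbind(sort(c(v[1L], v[2L])), sort(c(v[1L], v[3L])), sort(c(v[2L], v[3L])))
    }))
    key <- paste(edges[, 1L], edges[, 2L])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]

    faces <- faces[-vis, , drop = FALSE]
    norms <- norms[-vis, , drop = FALSE]
    offs <- offs[-vis]
    for (e in seq_len(nrow(horizon))) {
      tri <- c(horizon[e, ], p_i)
      g <- face_plane(pts, tri, interior)
      faces <- rbind(faces, tri); norms <- rbind(norms, g$n); offs <- c(offs, g$o)
    }
    remaining <- setdiff(remaining, p_i)
  }

  vol <- 0
  for (f in seq_len(nrow(faces))) {
    a <- pts[faces[f, 1L], ] - interior
    b <- pts[faces[f, 2L], ] - interior
    cc <- pts[faces[f, 3L], ] - interior
    vol <- vol + abs(sum(a * crossprod3(b, cc))) / 6
  }
  out <- list(vertices = sort(unique(as.vector(faces))), faces = faces,
              normals = norms, offsets = offs, volume = vol, degenerate = FALSE)
  class(out) <- "hull3d"
  out
}

crossprod3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

face_plane <- function(pts, tri, interior) {
  nrm <- crossprod3(pts[tri[2L], ] - pts[tri[1L], ], pts[tri[3L], ] - pts[tri[1L], ])
  len <- sqrt(sum(nrm^2))
  if (len == 0) return(list(n = c(0, 0, 0), o = 0))
  nrm <- nrm / len
  if (sum(nrm * (pts[tri[1L], ] - interior)) < 0) nrm <- -nrm
  list(n = nrm, o = sum(nrm * pts[tri[1L], ]))
}

#' Volume of the convex hull of a 3D point set
#'
#' Degenerate (collinear/coplanar) sets return 0 with attribute
#' `degenerate = TRUE` rather than an error.
#'
#' @param points numeric matrix (n x 3), nm.
#' @return hull volume in nm^3, with a logical `degenerate` attribute.
#' @export
hull_volume <- function(points) {
  h <- convex_hull_3d(points)
  structure(h$volume, degenerate = h$degenerate)
}

#' Test points for containment in a 3D convex hull
#'
#' @param hull a `hull3d` object from [convex_hull_3d()].
#' @param pts n x 3 matrix.
#' @param tol slack in nm on the face-plane inequalities.
#' @return logical vector; all `FALSE` for a degenerate hull.
#' @export
points_in_hull <- function(hull, pts, tol = 1e-6) {
  pts <- as.matrix(pts)
  if (isTRUE(hull$degenerate) || is.null(hull$normals)) {
    return(rep(FALSE, nrow(pts)))
  }
  d <- pts %*% t(hull$normals)
  rowSums(d > rep(hull$offsets + tol, each = nrow(pts))) == 0L
}

#' Diameter of the sphere with a given volume
#'
#' Reporting convenience: cluster hull volumes are commonly summarized as
#' equivalent-sphere diameters (e.g. 1.5e7 nm^3 ~ 300 nm).
#'
#' @param volume_nm3 volume(s) in nm^3.
#' @return diameter(s) in nm.
#' @export
equivalent_sphere_diameter <- function(volume_nm3) {
  2 * (3 * volume_nm3 / (4 * pi))^(1 / 3)
}

# ---- polygons (2D, nm) ----------------------------------------------------

#' Area of a simple polygon (shoelace formula)
#' @param poly n x 2 matrix of vertices, not closed.
#' @return area in the square of the coordinate unit.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Point-in-polygon test (ray casting)
#' @param pts n x 2 matrix.
#' @param poly m x 2 polygon vertex matrix.
#' @return logical vector (points exactly on an edge may go either way).
#' @export
point_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  poly <- as.matrix(poly)
  m <- nrow(poly)
  px <- poly[, 1L]; py <- poly[, 2L]
  qx <- px[c(2:m, 1L)]; qy <- py[c(2:m, 1L)]
  inside <- rep(FALSE, nrow(pts))
  for (e in seq_len(m)) {
    crosses <- ((py[e] > pts[, 2L]) != (qy[e] > pts[, 2L]))
    if (any(crosses)) {
      xint <- px[e] + (pts[crosses, 2L] - py[e]) / (qy[e] - py[e]) * (qx[e] - px[e])
      flip <- pts[crosses, 1L] < xint
      inside[crosses] <- xor(inside[crosses], flip)
    }
  }
  inside
}

#' Distance from points to a polygon boundary
#' @param pts n x 2 matrix.
#' @param poly m x 2 polygon vertex matrix.
#' @return numeric vector of Euclidean distances to the nearest edge.
#' @export
dist_to_polygon_boundary <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  poly <- as.matrix(poly)
  m <- nrow(poly)
  dmin <- rep(Inf, nrow(pts))
  for (e in seq_len(m)) {
    a <- poly[e, ]; b <- poly[if (e == m) 1L else e + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d <- sqrt((pts[, 1L] - a[1L])^2 + (pts[, 2L] - a[2L])^2)
    } else {
      t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L]) / len2
      t <- pmin(pmax(t, 0), 1)
      d <- sqrt((pts[, 1L] - (a[1L] + t * ab[1L]))^2 +
                (pts[, 2L] - (a[2L] + t * ab[2L]))^2)
    }
    dmin <- pmin(dmin, d)
  }
  dmin
}

#' Clip a convex polygon by a half-plane
#'
#' One Sutherland-Hodgman step: keeps the side `a*x + b*y <= c`. Low-level
#' utility behind the Voronoi cell construction.
#'
#' @param poly n x 2 vertex matrix.
#' @param a,b,c half-plane coefficients.
#' @return the clipped (possibly empty) vertex matrix.
#' @export
clip_polygon_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  out <- matrix(numeric(0), ncol = 2L)
  s <- a * poly[, 1L] + b * poly[, 2L] - c
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pin <- s[i] <= 0; qin <- s[j] <= 0
    if (pin) out <- rbind(out, poly[i, ])
    if (xor(pin, qin)) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Ellipse boundary polygon
#' @param a,b semi-axes (nm).
#' @param center ellipse center.
#' @param n number of vertices.
#' @return n x 2 vertex matrix (counter-clockwise).
#' @export
ellipse_polygon <- function(a, b, center = c(0, 0), n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + a * cos(th), center[2L] + b * sin(th))
}

# ---- spherical shells -----------------------------------------------------

#' Volume of a sphere clipped by a z slab
#'
#' Volume of `{x : |x| <= r, z_lo <= z <= z_hi}` with the sphere centered at
#' z = 0: `pi * integral (r^2 - z^2) dz` over the clipped interval.
#'
#' @param r sphere radius (nm).
#' @param z_lo,z_hi slab limits relative to the sphere center (nm).
#' @return volume in nm^3.
#' @export
sphere_slab_volume <- function(r, z_lo = -r, z_hi = r) {
  lo <- pmax(-r, z_lo); hi <- pmin(r, z_hi)
  out <- ifelse(hi > lo,
                pi * ((r^2 * hi - hi^3 / 3) - (r^2 * lo - lo^3 / 3)),
                0)
  as.numeric(out)
}

#' Volume of a spherical shell, optionally clipped by a z slab
#' @param r_lo,r_hi inner/outer shell radii (nm).
#' @param z_lo,z_hi optional slab limits relative to the shell center (nm).
#' @return shell volume in nm^3.
#' @export
shell_volume <- function(r_lo, r_hi, z_lo = NULL, z_hi = NULL) {
  if (is.null(z_lo)) {
    4 / 3 * pi * (r_hi^3 - r_lo^3)
  } else {
    sphere_slab_volume(r_hi, z_lo, z_hi) - sphere_slab_volume(r_lo, z_lo, z_hi)
  }
}
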