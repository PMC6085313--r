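# DBSCAN segmentation of histone conglomerates and EdU replication sites,
# convex-hull volumes and nucleus-normalized densities. Parameters follow the
# STORM analysis: Eps 75 nm, MinPts 10 (self-inclusive), and a 100-detection
# minimum for replication foci.

#' DBSCAN parameters
#' @param eps_nm neighborhood radius (nm); default 75.
#' @param min_pts minimum neighbors within eps for a core point, counting the
#'   point itself; default 10.
#' @param site_min_detections minimum cluster size for an EdU replication
#'   site; default 100.
#' @return a `dbscan_params` list.
#' @export
dbscan_params <- function(eps_nm = 75, min_pts = 10L, site_min_detections = 100L) {
  stopifnot(eps_nm > 0, min_pts >= 1L, site_min_detections >= 1L)
  structure(list(eps_nm = eps_nm, min_pts = as.integer(min_pts),
                 site_min_detections = as.integer(site_min_detections)),
            class = "dbscan_params")
}

## neighbor lists within eps via uniform grid of cell size eps (27-cell probe)
grid_neighbors <- function(xyz, eps) {
  n <- nrow(xyz)
  cell <- cbind(floor(xyz[, 1L] / eps), floor(xyz[, 2L] / eps), floor(xyz[, 3L] / eps))
  key <- paste(cell[, 1L], cell[, 2L], cell[, 3L])
  idx_by_cell <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  eps2 <- eps^2
  lapply(seq_len(n), function(i) {
    keys <- paste(cell[i, 1L] + offs[, 1L], cell[i, 2L] + offs[, 2L],
                  cell[i, 3L] + offs[, 3L])
    cand <- unlist(idx_by_cell[keys], use.names = FALSE)
    d2 <- (xyz[cand, 1L] - xyz[i, 1L])^2 + (xyz[cand, 2L] - xyz[i, 2L])^2 +
      (xyz[cand, 3L] - xyz[i, 3L])^2
    cand[d2 <= eps2]
  })
}

#' DBSCAN cluster labels for a localization table
#'
#' Standard DBSCAN semantics in 3D Euclidean metric: a record is core iff at
#' least `min_pts` records (itself included) lie within `eps_nm`; clusters
#' are the connected components of core points at distance <= eps, plus
#' border points, each assigned to the cluster of its first core neighbor in
#' canonical record order. Remaining records are noise (label 0). Cluster ids
#' are numbered by first core member in canonical order, so the labeling is
#' permutation-invariant.
#'
#' @param table a `loc_table` (or any data.frame with x, y, z).
#' @param params a [dbscan_params()] object.
#' @return integer vector of labels aligned with `table` rows; 0 = noise.
#' @export
dbscan <- function(table, params = dbscan_params()) {
  n <- nrow(table)
  if (n == 0L) stop("dbscan: empty table")
  ## canonical scan order; results mapped back to input order at the end
  o <- order(table$frame %||% rep(0L, n), table$x, table$y, table$z)
  xyz <- cbind(table$x, table$y, table$z)[o, , drop = FALSE]

  nb <- grid_neighbors(xyz, params$eps_nm)
  core <- lengths(nb) >= params$min_pts

  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      cores_new <- nb[[j]][core[nb[[j]]] & labels[nb[[j]]] == 0L]
      if (length(cores_new)) {
        labels[cores_new] <- cl
        queue <- c(queue, cores_new)
      }
    }
  }
  ## border points: first core neighbor in scan order decides
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  out <- integer(n)
  out[o] <- labels
  out
}

#' Per-cluster metrics: centroid, hull volume, normalized density
#'
#' Density of a cluster is its detection count, normalized by the total
#' number of detections in the nucleus, divided by its convex-hull volume:
#' `(n / N_nucleus) / hull_volume`. Clusters with degenerate (zero-volume)
#' hulls are flagged and get `NA` density.
#'
#' @param table the `loc_table` that was clustered.
#' @param labels integer labels from [dbscan()].
#' @param n_nucleus total number of detections in the nucleus for this
#'   channel; defaults to `nrow(table)`.
#' @return a `site_set`: data.frame with one row per cluster (cluster, n,
#'   cx, cy, cz, hull_volume_nm3, degenerate, normalized_density,
#'   equiv_diameter_nm) and attributes `hulls` (list of `hull3d`) and
#'   `members` (list of row-index vectors).
#' @export
conglomerate_metrics <- function(table, labels, n_nucleus = nrow(table)) {
  if (n_nucleus == 0L) stop("conglomerate_metrics: N_nucleus must be positive")
  clustered <- sum(labels != 0L)
  if (n_nucleus < clustered)
    stop("conglomerate_metrics: N_nucleus (", n_nucleus,
         ") smaller than the number of clustered detections (", clustered, ")")
  ids <- sort(unique(labels[labels != 0L]))
  hulls <- vector("list", length(ids))
  members <- vector("list", length(ids))
  rows <- lapply(seq_along(ids), function(k) {
    idx <- which(labels == ids[k])
    members[[k]] <<- idx
    P <- cbind(table$x[idx], table$y[idx], table$z[idx])
    h <- convex_hull_3d(P)
    hulls[[k]] <<- h
    vol <- h$volume
    data.frame(cluster = ids[k], n = length(idx),
               cx = mean(P[, 1L]), cy = mean(P[, 2L]), cz = mean(P[, 3L]),
               hull_volume_nm3 = vol, degenerate = h$degenerate,
               normalized_density = if (h$degenerate || vol == 0) NA_real_ else
                 (length(idx) / n_nucleus) / vol,
               equiv_diameter_nm = if (vol > 0) equivalent_sphere_diameter(vol) else NA_real_)
  })
  out <- do.call(rbind, rows) %||% data.frame(
    cluster = integer(0), n = integer(0), cx = numeric(0), cy = numeric(0),
    cz = numeric(0), hull_volume_nm3 = numeric(0), degenerate = logical(0),
    normalized_density = numeric(0), equiv_diameter_nm = numeric(0))
  rownames(out) <- NULL
  attr(out, "hulls") <- hulls
  attr(out, "members") <- members
  attr(out, "n_nucleus") <- n_nucleus
  class(out) <- c("site_set", "data.frame")
  out
}

site_subset <- function(sites, keep) {
  out <- as.data.frame(sites)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hulls") <- attr(sites, "hulls")[keep]
  attr(out, "members") <- attr(sites, "members")[keep]
  attr(out, "n_nucleus") <- attr(sites, "n_nucleus")
  class(out) <- c("site_set", "data.frame")
  out
}

#' Detect EdU replication sites
#'
#' DBSCAN clusters of the EdU channel passing the minimum-detection threshold
#' (default >= 100; `strict = TRUE` switches to > 100).
#'
#' @param edu_table `loc_table` of the EdU channel.
#' @param params a [dbscan_params()].
#' @param n_nucleus total EdU detections in the nucleus; default `nrow(edu_table)`.
#' @param strict use a strict `>` threshold instead of `>=`.
#' @return a `site_set` of replication sites.
#' @export
detect_replication_sites <- function(edu_table, params = dbscan_params(),
                                     n_nucleus = nrow(edu_table), strict = FALSE) {
  if (nrow(edu_table) == 0L) {
    return(conglomerate_metrics(
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0)),
      integer(0), n_nucleus = max(1L, n_nucleus)))
  }
  labels <- dbscan(edu_table, params)
  m <- conglomerate_metrics(edu_table, labels, n_nucleus)
  keep <- if (strict) m$n > params$site_min_detections else
    m$n >= params$site_min_detections
  site_subset(m, keep)
}

#' Select conglomerates near replication sites
#'
#' `"centroid_distance"` keeps a conglomerate iff its centroid lies strictly
#' under `max_distance_nm` (default 200 nm) from any site centroid;
#' `"hull_containment"` keeps it iff its centroid lies inside any site hull.
#'
#' @param conglomerates a `site_set` of histone conglomerates.
#' @param sites a `site_set` of replication sites.
#' @param max_distance_nm centroid-distance threshold (nm).
#' @param mode `"centroid_distance"` or `"hull_containment"`.
#' @return the filtered conglomerate `site_set`.
#' @export
select_near_sites <- function(conglomerates, sites, max_distance_nm = 200,
                              mode = c("centroid_distance", "hull_containment")) {
  mode <- match.arg(mode)
  if (nrow(conglomerates) == 0L || nrow(sites) == 0L)
    return(site_subset(conglomerates, logical(nrow(conglomerates))))
  C <- as.matrix(conglomerates[, c("cx", "cy", "cz")])
  if (mode == "centroid_distance") {
    S <- as.matrix(sites[, c("cx", "cy", "cz")])
    keep <- vapply(seq_len(nrow(C)), function(i) {
      d2 <- (S[, 1L] - C[i, 1L])^2 + (S[, 2L] - C[i, 2L])^2 + (S[, 3L] - C[i, 3L])^2
      any(sqrt(d2) < max_distance_nm)
    }, logical(1L))
  } else {
    hulls <- attr(sites, "hulls")
    keep <- rep(FALSE, nrow(C))
    for (h in hulls) keep <- keep | points_in_hull(h, C)
  }
  site_subset(conglomerates, keep)
}
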