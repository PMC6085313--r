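# Localization tables and the pre-analysis corrections applied before any
# clustering: drift correction from fiducial beads, two-channel registration,
# consecutive-frame merging of re-blinking molecules, optical-section
# clipping, and nucleus segmentation. Coordinates are nm throughout.

#' Construct a localization table
#'
#' The atomic input of the pipeline: one row per fitted single-molecule
#' detection with 3D position (nm), acquisition frame and channel.
#'
#' @param x,y,z numeric coordinates in nm.
#' @param frame integer frame indices (>= 0).
#' @param channel channel identifiers (e.g. `"histone"`, `"edu"`).
#' @param intensity optional numeric intensities (arbitrary units).
#' @return a `loc_table` (also a `data.frame`).
#' @export
loc_table <- function(x, y, z, frame, channel = "A", intensity = NULL) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (length(y) == 1L) y <- rep_len(y, n)
  if (length(z) == 1L) z <- rep_len(z, n)
  stopifnot(length(y) == n, length(z) == n)
  frame <- as.integer(rep_len(frame, n))
  channel <- as.character(rep_len(channel, n))
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("loc_table: coordinates must be finite")
  if (any(is.na(frame)) || any(frame < 0L))
    stop("loc_table: frames must be non-negative integers")
  df <- data.frame(x = x, y = y, z = z, frame = frame, channel = channel,
                   stringsAsFactors = FALSE)
  if (!is.null(intensity)) df$intensity <- as.numeric(rep_len(intensity, n))
  class(df) <- c("loc_table", "data.frame")
  df
}

as_loc_table <- function(df) {
  loc_table(df$x, df$y, df$z, df$frame, df$channel, df$intensity)
}

#' Canonical record order
#'
#' Sorts by (frame, x, y, z, channel). Deterministic operations sort their
#' output this way so results are independent of input record permutation.
#'
#' @param table a `loc_table`.
#' @return the reordered table.
#' @export
order_records <- function(table) {
  o <- order(table$frame, table$x, table$y, table$z, table$channel)
  out <- table[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a localization table from delimited text
#'
#' @param path CSV file path.
#' @param dialect `"generic"` expects columns named x, y, z, frame, channel
#'   (intensity optional); `"thunderstorm"` accepts ThunderSTORM-style headers
#'   (`"x [nm]"`, `"y [nm]"`, `"z [nm]"`, `"frame"`) with a single implied
#'   channel.
#' @param pixel_size_nm if the file stores x/y in pixels, the nm-per-pixel
#'   factor applied at read time (e.g. 160); `NULL` means already nm.
#' @return a `loc_table`.
#' @export
read_localizations <- function(path, dialect = c("generic", "thunderstorm"),
                               pixel_size_nm = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_localizations: no such file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- if (dialect == "generic") {
    c(x = "x", y = "y", z = "z", frame = "frame", channel = "channel")
  } else {
    c(x = "x [nm]", y = "y [nm]", z = "z [nm]", frame = "frame")
  }
  for (col in map) {
    if (!col %in% names(raw))
      stop("read_localizations: missing required column '", col, "'")
  }
  num <- function(col, name) {
    v <- raw[[col]]
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) & !is.na(v))
    if (length(bad))
      stop("read_localizations: non-numeric ", name, " at line ",
           bad[1L] + 1L, ": '", v[bad[1L]], "'")
    vn
  }
  x <- num(map[["x"]], "x"); y <- num(map[["y"]], "y"); z <- num(map[["z"]], "z")
  if (!is.null(pixel_size_nm)) {
    x <- x * pixel_size_nm
    y <- y * pixel_size_nm
  }
  channel <- if (dialect == "generic") as.character(raw[[map[["channel"]]]]) else "A"
  intensity <- if ("intensity" %in% names(raw)) {
    suppressWarnings(as.numeric(raw[["intensity"]]))
  } else NULL
  loc_table(x, y, z, num(map[["frame"]], "frame"), channel, intensity)
}

#' Write a localization table as CSV
#' @param table a `loc_table`.
#' @param path output path.
#' @return `path`, invisibly. Round-trips with [read_localizations()].
#' @export
write_localizations <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- fiducial beads and drift ---------------------------------------------

#' Construct a bead track
#' @param bead bead identifiers.
#' @param frame integer frame indices.
#' @param x,y,z positions (nm).
#' @return a `bead_track` data.frame with one row per (bead, frame).
#' @export
bead_track <- function(bead, frame, x, y, z) {
  df <- data.frame(bead = as.character(bead), frame = as.integer(frame),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("bead", "frame")]))
    stop("bead_track: duplicate (bead, frame) position")
  class(df) <- c("bead_track", "data.frame")
  df
}

#' Estimate per-frame drift from fiducial bead tracks
#'
#' The per-frame offset is the mean over beads of (position - position at the
#' reference frame), smoothed with a centered moving average; the offset at
#' the reference frame is 0 by construction.
#'
#' @param beads a `bead_track`.
#' @param smoothing_window centered moving-average width in frames.
#' @param reference_frame defaults to the earliest frame observed for all
#'   beads.
#' @return a `drift_model`: data.frame (frame, dx, dy, dz).
#' @export
estimate_drift <- function(beads, smoothing_window = 100L,
                           reference_frame = NULL) {
  stopifnot(nrow(beads) >= 2L)
  ids <- unique(beads$bead)
  common <- Reduce(intersect, lapply(ids, function(b) beads$frame[beads$bead == b]))
  if (!length(common)) stop("estimate_drift: no frames in common across beads")
  ref <- if (is.null(reference_frame)) min(common) else as.integer(reference_frame)
  if (!ref %in% common)
    stop("estimate_drift: reference frame ", ref, " not observed for all beads")

  bdt <- data.table::as.data.table(beads)
  refpos <- bdt[bdt$frame == ref, c("bead", "x", "y", "z")]
  data.table::setnames(refpos, c("x", "y", "z"), c("x0", "y0", "z0"))
  bdt <- merge(bdt, refpos, by = "bead")
  frame <- NULL # NSE note for R CMD check
  off <- bdt[, list(dx = mean(x - x0), dy = mean(y - y0), dz = mean(z - z0)),
             by = frame]
  data.table::setorderv(off, "frame")

  w <- max(1L, as.integer(smoothing_window))
  ## centered moving average; series ends use the available frames only (no
  ## re-extension, which would bias the reference-frame value)
  smooth1 <- function(v) {
    n <- length(v)
    h1 <- (w - 1L) %/% 2L
    h2 <- w - 1L - h1
    vapply(seq_len(n), function(i) {
      mean(v[max(1L, i - h1):min(n, i + h2)])
    }, numeric(1L))
  }
  out <- data.frame(frame = off$frame,
                    dx = smooth1(off$dx), dy = smooth1(off$dy), dz = smooth1(off$dz))
  i0 <- match(ref, out$frame)
  out$dx <- out$dx - out$dx[i0]
  out$dy <- out$dy - out$dy[i0]
  out$dz <- out$dz - out$dz[i0]
  attr(out, "reference_frame") <- ref
  class(out) <- c("drift_model", "data.frame")
  out
}

#' Apply (or undo) a drift model to a localization table
#'
#' Each record is translated by minus the offset at its frame.
#'
#' @param table a `loc_table`.
#' @param model a `drift_model` covering every frame present in `table`.
#' @param invert if `TRUE`, adds the offset back (exact inverse).
#' @return the corrected `loc_table` (record count unchanged).
#' @export
apply_drift <- function(table, model, invert = FALSE) {
  idx <- match(table$frame, model$frame)
  if (anyNA(idx)) {
    missing <- sort(unique(table$frame[is.na(idx)]))
    stop("apply_drift: drift model does not cover frames: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "")
  }
  s <- if (invert) 1 else -1
  table$x <- table$x + s * model$dx[idx]
  table$y <- table$y + s * model$dy[idx]
  table$z <- table$z + s * model$dz[idx]
  table
}

# ---- channel registration -------------------------------------------------

#' Estimate the transform aligning channel B onto channel A
#'
#' Beads are matched by id; the per-bead time-averaged positions are used as
#' the matched landmark set. `"translation"` needs >= 1 bead, `"rigid"`
#' (rotation + uniform scale + translation, least squares via SVD) >= 2, and
#' `"affine"` >= 3 non-collinear beads.
#'
#' @param beads_A,beads_B `bead_track`s of the same fiducials in each channel.
#' @param model_kind `"translation"`, `"rigid"` or `"affine"`.
#' @return a `channel_transform`: list with 3x3 matrix `A`, offset `t`
#'   (maps B as `A %*% p + t`), `kind` and residual `rms` (nm).
#' @export
register_channels <- function(beads_A, beads_B,
                              model_kind = c("rigid", "translation", "affine")) {
  model_kind <- match.arg(model_kind)
  mean_pos <- function(b) {
    sp <- split(b[, c("x", "y", "z")], b$bead)
    t(vapply(sp, function(d) colMeans(as.matrix(d)), numeric(3L)))
  }
  PA <- mean_pos(beads_A); PB <- mean_pos(beads_B)
  ids <- intersect(rownames(PA), rownames(PB))
  need <- c(translation = 1L, rigid = 2L, affine = 3L)[[model_kind]]
  if (length(ids) < need)
    stop("register_channels: model '", model_kind, "' needs at least ", need,
         " matched beads, got ", length(ids))
  PA <- PA[ids, , drop = FALSE]; PB <- PB[ids, , drop = FALSE]

  dimnames(PA) <- dimnames(PB) <- NULL
  if (model_kind == "translation") {
    A <- diag(3)
    tvec <- colMeans(PA) - colMeans(PB)
  } else if (model_kind == "rigid") {
    ca <- colMeans(PA); cb <- colMeans(PB)
    Xa <- sweep(PA, 2L, ca); Xb <- sweep(PB, 2L, cb)
    H <- t(Xb) %*% Xa
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, d))
    R <- sv$v %*% D %*% t(sv$u)
    denom <- sum(Xb^2)
    s <- if (denom > 0) sum(diag(D) * sv$d) / denom else 1
    A <- s * R
    tvec <- ca - as.vector(A %*% cb)
  } else {
    fit <- lm.fit(cbind(1, PB), PA)
    cf <- fit$coefficients
    A <- t(cf[-1L, , drop = FALSE])
    tvec <- as.numeric(cf[1L, ])
  }
  dimnames(A) <- NULL; names(tvec) <- NULL
  pred <- t(A %*% t(PB) + tvec)
  rms <- sqrt(mean(rowSums((PA - pred)^2)))
  structure(list(kind = model_kind, A = A, t = tvec, rms = rms, n_beads = length(ids)),
            class = "channel_transform")
}

#' Apply a channel transform to a localization table or coordinate matrix
#' @param transform a `channel_transform`.
#' @param table a `loc_table` or n x 3 matrix of B-channel coordinates.
#' @param invert map A coordinates back onto B.
#' @return object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(transform, table, invert = FALSE) {
  A <- transform$A; tv <- transform$t
  if (invert) {
    A <- solve(transform$A)
    tv <- -as.vector(A %*% transform$t)
  }
  if (is.matrix(table)) {
    return(t(A %*% t(table) + tv))
  }
  xyz <- t(A %*% t(as.matrix(table[, c("x", "y", "z")])) + tv)
  table$x <- xyz[, 1L]; table$y <- xyz[, 2L]; table$z <- xyz[, 3L]
  table
}

# ---- consecutive-frame merging --------------------------------------------

#' Merge re-detections of one molecule in consecutive frames
#'
#' Localizations detected in consecutive frames within `radius_nm` (default
#' 50 nm) are considered the same molecule. Linking is greedy nearest-first
#' per frame pair and per channel, each record getting at most one successor
#' and one predecessor; a linked chain collapses to a single record at the
#' unweighted mean position with the frame of its first member. Passes are
#' iterated to a fixed point, which makes the operation idempotent.
#'
#' @param table a `loc_table`.
#' @param radius_nm linking radius (nm).
#' @param position `"mean"` (default) or `"first"` chain position.
#' @return the merged `loc_table`, in canonical record order.
#' @export
merge_consecutive <- function(table, radius_nm = 50, position = c("mean", "first")) {
  position <- match.arg(position)
  if (radius_nm < 0) stop("merge_consecutive: radius must be non-negative")
  out <- order_records(table)
  repeat {
    merged <- merge_pass(out, radius_nm, position)
    if (nrow(merged) == nrow(out)) break
    out <- merged
  }
  out
}

merge_pass <- function(table, radius_nm, position) {
  n <- nrow(table)
  if (n < 2L) return(table)
  succ <- rep(NA_integer_, n)
  has_pred <- rep(FALSE, n)
  for (ch in unique(table$channel)) {
    ci <- which(table$channel == ch)
    by_frame <- split(ci, table$frame[ci])
    frames <- as.integer(names(by_frame))
    for (k in seq_along(frames)) {
      tgt_key <- as.character(frames[k] + 1L)
      if (!tgt_key %in% names(by_frame)) next
      src <- by_frame[[k]]
      tgt <- by_frame[[tgt_key]]
      dx <- outer(table$x[src], table$x[tgt], "-")
      dy <- outer(table$y[src], table$y[tgt], "-")
      dz <- outer(table$z[src], table$z[tgt], "-")
      d <- sqrt(dx^2 + dy^2 + dz^2)
      cand <- which(d <= radius_nm, arr.ind = TRUE)
      if (!nrow(cand)) next
      ord <- order(d[cand], cand[, 1L], cand[, 2L])
      for (kk in ord) {
        i <- src[cand[kk, 1L]]; j <- tgt[cand[kk, 2L]]
        if (is.na(succ[i]) && !has_pred[j]) {
          succ[i] <- j; has_pred[j] <- TRUE
        }
      }
    }
  }
  ## chain components: links always go frame f -> f+1, so propagating in
  ## canonical (frame-sorted) row order finalizes each head before its tail
  comp <- seq_len(n)
  linked <- which(!is.na(succ))
  for (i in linked) comp[succ[i]] <- comp[i]
  dt <- data.table::as.data.table(table)
  dt$.comp <- comp
  .comp <- NULL
  if (position == "mean") {
    agg <- dt[, c(list(x = mean(x), y = mean(y), z = mean(z),
                       frame = min(frame), channel = channel[1L]),
                  if ("intensity" %in% names(dt)) list(intensity = mean(intensity))),
              by = .comp]
  } else {
    agg <- dt[dt[, .I[which.min(frame)], by = .comp]$V1]
  }
  agg$.comp <- NULL
  out <- as.data.frame(agg)
  class(out) <- c("loc_table", "data.frame")
  order_records(out)
}

# ---- section clipping and nucleus segmentation ----------------------------

#' Restrict a table to a z section
#'
#' Keeps records with `z_min <= z < z_max` (half-open), matching a 600 nm
#' optical section.
#'
#' @param table a `loc_table`.
#' @param z_min,z_max section limits (nm), `z_min < z_max`.
#' @return the clipped `loc_table`.
#' @export
clip_z_section <- function(table, z_min, z_max) {
  stopifnot(z_min < z_max)
  out <- table[table$z >= z_min & table$z < z_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a nucleus mask
#' @param polygon n x 2 boundary vertex matrix (nm).
#' @param z_range length-2 z interval (nm).
#' @return a `nucleus_mask`: list with `polygon`, `z_range`, `area_nm2`,
#'   `volume_nm3`.
#' @export
nucleus_mask <- function(polygon, z_range) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2L, nrow(polygon) >= 3L,
            length(z_range) == 2L, z_range[1L] < z_range[2L])
  if (anyDuplicated(polygon)) polygon <- polygon[!duplicated(polygon), , drop = FALSE]
  area <- polygon_area(polygon)
  structure(list(polygon = polygon, z_range = as.numeric(z_range),
                 area_nm2 = area,
                 volume_nm3 = area * diff(as.numeric(z_range))),
            class = "nucleus_mask")
}

#' Segment the nucleus from the detections themselves
#'
#' Boundary = 2D convex hull of all detections (both channels); z interval =
#' observed z range. Used for density normalization and periphery calls.
#'
#' @param table a `loc_table` with at least 3 non-collinear xy positions.
#' @return a `nucleus_mask`.
#' @export
segment_nucleus <- function(table) {
  xy <- unique(cbind(table$x, table$y))
  if (nrow(xy) < 3L) stop("segment_nucleus: need at least 3 distinct xy points")
  h <- grDevices::chull(xy[, 1L], xy[, 2L])
  if (length(h) < 3L) stop("segment_nucleus: points are collinear")
  poly <- xy[h, , drop = FALSE]
  zr <- range(table$z)
  if (zr[1L] == zr[2L]) zr <- zr + c(-0.5, 0.5) # flat section: nominal 1 nm slab
  nucleus_mask(poly, zr)
}
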