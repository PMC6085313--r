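# Generators for every input the real study obtained from microscopes and
# sequencers, with planted ground truth: two-channel clustered 3D
# localizations inside a nucleus slab (Thomas process), fiducial bead tracks
# with shared drift, genomic coverage tracks with planted
# timing/transcription/enrichment structure, and pulse-chase intensity
# series. Identical seed + spec gives identical output.

#' Scene specification for the localization generator
#'
#' The stated world: conglomerates are a Thomas process (Gaussian-dispersed
#' offspring around uniform parent centers) inside an ellipse x z-slab
#' nucleus; the slab is 600 nm thick like the optical sections the analysis
#' assumes. `channel_coupling` controls the placement of channel-A parents
#' relative to channel-B parents: 1 = independent, > 1 attraction (a fraction
#' `1 - 1/coupling` of A parents sits on B parents), < 1 repulsion (parents
#' within `interaction_radius_nm` of a B parent are thinned with probability
#' `1 - coupling`; 0 = hard exclusion).
#'
#' @param nucleus_semi_axes c(a, b, half-thickness) in nm; default
#'   c(8000, 5000, 300), plausible HeLa values with a 600 nm slab.
#' @param n_conglomerates parent clusters per channel.
#' @param conglomerate_radius_nm Gaussian offspring sigma (nm).
#' @param detections_per_conglomerate mean offspring count (Poisson).
#' @param background_fraction fraction of each channel's molecules that are
#'   uniform background, in `[0, 1]`.
#' @param channel_coupling coupling of A parents to B parents (>= 0).
#' @param interaction_radius_nm attraction/repulsion range (nm).
#' @param min_parent_sep_nm minimum distance between parent centers within a
#'   channel (hard-core thinning; 0 = none). Parameter-recovery criteria
#'   assume well-separated clusters, i.e. a separation much larger than the
#'   DBSCAN eps.
#' @param drift_amplitude_nm per-axis sinusoidal drift amplitude.
#' @param n_frames number of acquisition frames.
#' @param blink_repeat_prob probability a molecule re-appears in the next
#'   frame (geometric chain).
#' @param loc_precision_nm per-appearance localization jitter sd (nm).
#' @param seed integer RNG seed.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(nucleus_semi_axes = c(8000, 5000, 300),
                       n_conglomerates = 30L,
                       conglomerate_radius_nm = 50,
                       detections_per_conglomerate = 200,
                       background_fraction = 0.1,
                       channel_coupling = 1,
                       interaction_radius_nm = 300,
                       min_parent_sep_nm = 0,
                       drift_amplitude_nm = 0,
                       n_frames = 10000L,
                       blink_repeat_prob = 0.3,
                       loc_precision_nm = 15,
                       seed = 1L) {
  if (any(nucleus_semi_axes <= 0)) stop("scene_spec: nucleus axes must be positive")
  stopifnot(n_conglomerates >= 0L, conglomerate_radius_nm > 0,
            detections_per_conglomerate > 0,
            background_fraction >= 0, background_fraction <= 1,
            channel_coupling >= 0, n_frames >= 1L,
            blink_repeat_prob >= 0, blink_repeat_prob < 1,
            loc_precision_nm >= 0, drift_amplitude_nm >= 0,
            min_parent_sep_nm >= 0)
  structure(as.list(environment()), class = "scene_spec")
}

#' Nucleus mask implied by a scene spec
#' @param spec a [scene_spec()].
#' @return a `nucleus_mask` (ellipse polygon x z slab).
#' @export
scene_mask <- function(spec) {
  ax <- spec$nucleus_semi_axes
  nucleus_mask(ellipse_polygon(ax[1L], ax[2L]), c(-ax[3L], ax[3L]))
}

in_ellipse <- function(xy, a, b) (xy[, 1L] / a)^2 + (xy[, 2L] / b)^2 <= 1

sample_in_region <- function(n, ax) {
  out <- matrix(NA_real_, 0L, 3L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    xy <- cbind(stats::runif(m, -ax[1L], ax[1L]), stats::runif(m, -ax[2L], ax[2L]))
    xy <- xy[in_ellipse(xy, ax[1L], ax[2L]), , drop = FALSE]
    if (nrow(xy))
      out <- rbind(out, cbind(xy, stats::runif(nrow(xy), -ax[3L], ax[3L])))
  }
  out[seq_len(n), , drop = FALSE]
}

## Dart-throwing parent sampler with an optional hard-core separation.
sample_parents <- function(n, ax, min_sep = 0) {
  if (min_sep <= 0 || n <= 1L) return(sample_in_region(n, ax))
  out <- matrix(NA_real_, 0L, 3L)
  guard <- 0L
  while (nrow(out) < n && guard < 10000L) {
    guard <- guard + 1L
    cand <- sample_in_region(1L, ax)
    if (nrow(out) == 0L ||
        min((out[, 1L] - cand[1L])^2 + (out[, 2L] - cand[2L])^2 +
              (out[, 3L] - cand[3L])^2) >= min_sep^2) {
      out <- rbind(out, cand)
    }
  }
  if (nrow(out) < n)
    stop("generate_scene: cannot place parents with the requested separation")
  out
}

## Gaussian offspring around `center`, resampled until inside the region.
offspring <- function(n, center, sigma, ax) {
  out <- matrix(NA_real_, 0L, 3L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 8L)
    p <- cbind(stats::rnorm(m, center[1L], sigma), stats::rnorm(m, center[2L], sigma),
               stats::rnorm(m, center[3L], sigma))
    ok <- in_ellipse(p[, 1:2, drop = FALSE], ax[1L], ax[2L]) &
      abs(p[, 3L]) <= ax[3L]
    out <- rbind(out, p[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

## A-channel parent centers under the coupling rule, given B parents.
coupled_parents <- function(n, coupling, centers_B, r_int, sigma, ax,
                            min_sep = 0) {
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  if (coupling == 1 || nrow(centers_B) == 0L) return(sample_parents(n, ax, min_sep))
  if (coupling > 1) {
    on_B <- stats::runif(n) < (1 - 1 / coupling)
    out <- sample_in_region(n, ax)
    if (any(on_B)) {
      pick <- sample.int(nrow(centers_B), sum(on_B), replace = TRUE)
      out[on_B, ] <- centers_B[pick, , drop = FALSE] +
        matrix(stats::rnorm(3L * sum(on_B), 0, sigma), ncol = 3L)
      out[on_B, 3L] <- pmin(pmax(out[on_B, 3L], -ax[3L]), ax[3L])
    }
    return(out)
  }
  ## coupling < 1: thin candidates near B centers
  out <- matrix(NA_real_, 0L, 3L)
  guard <- 0L
  while (nrow(out) < n && guard < 1000L) {
    guard <- guard + 1L
    cand <- sample_in_region(max(2L * (n - nrow(out)), 8L), ax)
    near <- vapply(seq_len(nrow(cand)), function(i) {
      any((centers_B[, 1L] - cand[i, 1L])^2 + (centers_B[, 2L] - cand[i, 2L])^2 +
            (centers_B[, 3L] - cand[i, 3L])^2 <= r_int^2)
    }, logical(1L))
    keep <- !near | stats::runif(nrow(cand)) < coupling
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  if (nrow(out) < n) stop("generate_scene: exclusion region leaves no room for channel A")
  out[seq_len(n), , drop = FALSE]
}

#' Generate a two-channel localization scene with ground truth
#'
#' Channel "B" emulates EdU replication sites, channel "A" the histone
#' signal. Each molecule appears in a geometric chain of consecutive frames
#' (blinking) with localization jitter and optional shared sinusoidal drift.
#'
#' @param spec a [scene_spec()].
#' @return list with `locs` (a `loc_table`, one row per detection, carrying
#'   hidden per-row truth in attribute `truth_rows`), `truth` (list:
#'   `centers_A`, `centers_B`, `molecules` data.frame with true positions,
#'   cluster and molecule ids, `coupling`, `drift` data.frame, `spec`) and
#'   `mask` (the nucleus mask).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  ax <- spec$nucleus_semi_axes
  with_seed(spec$seed, {
    centers_B <- if (spec$n_conglomerates > 0L)
      sample_parents(spec$n_conglomerates, ax, spec$min_parent_sep_nm) else
        matrix(numeric(0), 0L, 3L)
    centers_A <- coupled_parents(spec$n_conglomerates, spec$channel_coupling,
                                 centers_B, spec$interaction_radius_nm,
                                 spec$conglomerate_radius_nm, ax,
                                 spec$min_parent_sep_nm)

    gen_channel <- function(centers) {
      pts <- list(); labs <- integer(0)
      if (nrow(centers)) {
        for (k in seq_len(nrow(centers))) {
          nk <- stats::rpois(1L, spec$detections_per_conglomerate)
          if (nk > 0L) {
            pts[[length(pts) + 1L]] <-
              offspring(nk, centers[k, ], spec$conglomerate_radius_nm, ax)
            labs <- c(labs, rep(k, nk))
          }
        }
      }
      clustered <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0L, 3L)
      n_cl <- nrow(clustered)
      n_bg <- if (spec$background_fraction >= 1) {
        round(spec$detections_per_conglomerate * max(1L, spec$n_conglomerates))
      } else {
        round(n_cl * spec$background_fraction / (1 - spec$background_fraction))
      }
      bg <- if (n_bg > 0L) sample_in_region(n_bg, ax) else matrix(numeric(0), 0L, 3L)
      list(pos = rbind(clustered, bg), cluster = c(labs, rep(0L, n_bg)))
    }
    chA <- gen_channel(centers_A)
    chB <- gen_channel(centers_B)

    drift <- data.frame(frame = 0:(spec$n_frames - 1L))
    if (spec$drift_amplitude_nm > 0) {
      ph <- stats::runif(3L, 0, 2 * pi)
      tt <- 2 * pi * drift$frame / spec$n_frames
      drift$dx <- spec$drift_amplitude_nm * sin(tt + ph[1L])
      drift$dy <- spec$drift_amplitude_nm * sin(tt + ph[2L])
      drift$dz <- spec$drift_amplitude_nm * sin(tt + ph[3L])
    } else {
      drift$dx <- drift$dy <- drift$dz <- 0
    }

    blink_channel <- function(ch, label) {
      n <- nrow(ch$pos)
      if (n == 0L) {
        return(list(tab = loc_table(numeric(0), numeric(0), numeric(0),
                                    integer(0), label),
                    rows = data.frame(molecule = integer(0), cluster = integer(0))))
      }
      start <- sample.int(spec$n_frames, n, replace = TRUE) - 1L
      len <- 1L + stats::rgeom(n, 1 - spec$blink_repeat_prob)
      len <- pmin(len, spec$n_frames - start)
      mol <- rep(seq_len(n), len)
      frame <- start[mol] + sequence(len) - 1L
      true <- ch$pos[mol, , drop = FALSE]
      m <- length(mol)
      jit <- if (spec$loc_precision_nm > 0) {
        ## resample jitter that would leave the nucleus region
        p <- true + matrix(stats::rnorm(3L * m, 0, spec$loc_precision_nm), ncol = 3L)
        bad <- which(!(in_ellipse(p[, 1:2, drop = FALSE], ax[1L], ax[2L]) &
                         abs(p[, 3L]) <= ax[3L]))
        guard <- 0L
        while (length(bad) && guard < 100L) {
          guard <- guard + 1L
          p[bad, ] <- true[bad, , drop = FALSE] +
            matrix(stats::rnorm(3L * length(bad), 0, spec$loc_precision_nm), ncol = 3L)
          ok <- in_ellipse(p[bad, 1:2, drop = FALSE], ax[1L], ax[2L]) &
            abs(p[bad, 3L]) <= ax[3L]
          bad <- bad[!ok]
        }
        if (length(bad)) p[bad, ] <- true[bad, , drop = FALSE]
        p
      } else true
      di <- match(frame, drift$frame)
      tab <- loc_table(jit[, 1L] + drift$dx[di], jit[, 2L] + drift$dy[di],
                       jit[, 3L] + drift$dz[di], frame, label)
      list(tab = tab,
           rows = data.frame(molecule = mol, cluster = ch$cluster[mol]))
    }
    bA <- blink_channel(chA, "A")
    bB <- blink_channel(chB, "B")
    locs <- rbind(bA$tab, bB$tab)
    class(locs) <- c("loc_table", "data.frame")
    truth_rows <- rbind(cbind(bA$rows, channel = "A"), cbind(bB$rows, channel = "B"))
    attr(locs, "truth_rows") <- truth_rows

    molecules <- rbind(
      data.frame(channel = "A", cluster = chA$cluster,
                 x = chA$pos[, 1L], y = chA$pos[, 2L], z = chA$pos[, 3L]),
      data.frame(channel = "B", cluster = chB$cluster,
                 x = chB$pos[, 1L], y = chB$pos[, 2L], z = chB$pos[, 3L]))

    list(locs = locs,
         truth = list(centers_A = centers_A, centers_B = centers_B,
                      molecules = molecules, coupling = spec$channel_coupling,
                      drift = drift, spec = spec),
         mask = scene_mask(spec))
  })
}

#' Generate fiducial bead tracks with shared drift
#'
#' Each bead's per-frame position is its fixed true position plus the shared
#' drift series plus localization noise.
#'
#' @param drift_amplitude_nm sinusoidal drift amplitude per axis (ignored
#'   when `drift_series` is given).
#' @param n_frames number of frames (>= 2).
#' @param n_beads number of beads (>= 1).
#' @param seed RNG seed.
#' @param noise_nm per-frame localization noise sd (nm).
#' @param drift_series optional data.frame (frame, dx, dy, dz) overriding the
#'   generated drift.
#' @return list with `beads` (a `bead_track`) and `drift` (the truth series,
#'   zeroed at frame 0).
#' @export
generate_fiducials <- function(drift_amplitude_nm, n_frames, n_beads, seed = 1L,
                               noise_nm = 2, drift_series = NULL) {
  if (n_beads < 1L) stop("generate_fiducials: need at least one bead")
  if (n_frames < 2L) stop("generate_fiducials: need at least two frames")
  with_seed(seed, {
    frames <- 0:(n_frames - 1L)
    if (is.null(drift_series)) {
      ph <- stats::runif(3L, 0, 2 * pi)
      tt <- 2 * pi * frames / n_frames
      drift_series <- data.frame(
        frame = frames,
        dx = drift_amplitude_nm * (sin(tt + ph[1L]) - sin(ph[1L])),
        dy = drift_amplitude_nm * (sin(tt + ph[2L]) - sin(ph[2L])),
        dz = drift_amplitude_nm * (sin(tt + ph[3L]) - sin(ph[3L])))
    }
    stopifnot(nrow(drift_series) == n_frames)
    true <- cbind(stats::runif(n_beads, -5000, 5000),
                  stats::runif(n_beads, -5000, 5000),
                  stats::runif(n_beads, -200, 200))
    rows <- lapply(seq_len(n_beads), function(b) {
      data.frame(bead = sprintf("bead%02d", b), frame = frames,
                 x = true[b, 1L] + drift_series$dx + stats::rnorm(n_frames, 0, noise_nm),
                 y = true[b, 2L] + drift_series$dy + stats::rnorm(n_frames, 0, noise_nm),
                 z = true[b, 3L] + drift_series$dz + stats::rnorm(n_frames, 0, noise_nm))
    })
    df <- do.call(rbind, rows)
    list(beads = bead_track(df$bead, df$frame, df$x, df$y, df$z),
         drift = drift_series)
  })
}

# ---- genomic tracks -------------------------------------------------------

#' Genomic track specification
#'
#' Plants per-bin replication timing (S1-S6), a transcription class whose
#' proportions are exactly consistent with the downstream percentile rule
#' (so recovery is exact), and a log2 ChIP enrichment effect by
#' (timing, class).
#'
#' @param n_bins number of 10 kb bins (>= 6).
#' @param bin_size_bp fixed 10000.
#' @param timing optional per-bin integer 1..6 (NA = no Repli-seq signal);
#'   default uniform random.
#' @param effect either a 6 x 4 matrix of log2 effects indexed by
#'   (timing, class none/low/mid/high), a per-bin numeric vector, or NULL
#'   (no effect).
#' @param prop_zero_txn fraction of bins with no measurable transcription.
#' @param noise_dispersion coefficient of variation of the multiplicative
#'   log-normal coverage noise.
#' @param seed RNG seed.
#' @return a `track_spec` list.
#' @export
track_spec <- function(n_bins, bin_size_bp = 10000L, timing = NULL,
                       effect = NULL, prop_zero_txn = 0.3,
                       noise_dispersion = 0.05, seed = 1L) {
  if (n_bins < 6L) stop("track_spec: need at least 6 bins")
  stopifnot(bin_size_bp == 10000L, noise_dispersion >= 0,
            prop_zero_txn >= 0, prop_zero_txn < 1)
  structure(as.list(environment()), class = "track_spec")
}

## Counts of non-zero bins that fall at-or-below p10 / at-or-above p90 under
## type-7 quantiles when the planted value blocks are separated by gaps.
percentile_block_counts <- function(n_nz) {
  h10 <- 1 + 0.1 * (n_nz - 1)
  h90 <- 1 + 0.9 * (n_nz - 1)
  n_low <- if (h10 == floor(h10)) as.integer(h10) else floor(h10)
  n_high <- if (h90 == floor(h90)) n_nz - as.integer(h90) + 1L else n_nz - ceiling(h90) + 1L
  c(low = as.integer(n_low), high = as.integer(n_high))
}

#' Generate synthetic genomic coverage tracks with planted structure
#'
#' Emits bedGraph-style tracks (chrom, start, end, value; 0-based half-open)
#' for a ChIP sample, its input, six Repli-seq S-phase fractions and nascent
#' RNA, on one synthetic chromosome, together with the per-bin ground truth.
#'
#' @param spec a [track_spec()].
#' @return list with `tracks` (named list of bedGraph data.frames: input,
#'   sample, S1..S6, nascent) and `truth` (data.frame bin, start, timing,
#'   txn_class, effect).
#' @export
generate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  n <- spec$n_bins
  bs <- spec$bin_size_bp
  with_seed(spec$seed, {
    timing <- spec$timing %||% sample(1:6, n, replace = TRUE)
    stopifnot(length(timing) == n)

    ## transcription: plant none/low/mid/high with percentile-consistent counts
    n_none <- round(spec$prop_zero_txn * n)
    nz <- sort(sample.int(n, n - n_none))
    n_nz <- length(nz)
    if (n_nz < 10L) stop("generate_tracks: too few transcribed bins")
    bc <- percentile_block_counts(n_nz)
    cls_nz <- rep("mid", n_nz)
    ord <- sample.int(n_nz) # random placement of the blocks over bins
    cls_nz[ord[seq_len(bc["low"])]] <- "low"
    cls_nz[ord[seq.int(n_nz - bc["high"] + 1L, n_nz)]] <- "high"
    txn_class <- rep("none", n)
    txn_class[nz] <- cls_nz
    nascent <- numeric(n)
    nascent[txn_class == "low"] <- stats::runif(sum(txn_class == "low"), 1, 2)
    nascent[txn_class == "mid"] <- stats::runif(sum(txn_class == "mid"), 8, 16)
    nascent[txn_class == "high"] <- stats::runif(sum(txn_class == "high"), 60, 120)

    ## planted log2 enrichment effect
    cls_idx <- match(txn_class, c("none", "low", "mid", "high"))
    eff <- if (is.null(spec$effect)) {
      rep(0, n)
    } else if (is.matrix(spec$effect)) {
      ifelse(is.na(timing), 0, spec$effect[cbind(pmax(timing, 1L), cls_idx)])
    } else {
      rep_len(as.numeric(spec$effect), n)
    }

    lognoise <- function(m) {
      if (spec$noise_dispersion == 0) return(rep(1, m))
      sdl <- sqrt(log(1 + spec$noise_dispersion^2))
      exp(stats::rnorm(m, -sdl^2 / 2, sdl))
    }
    input <- stats::rgamma(n, shape = 25, rate = 2.5) # mean 10 per-base coverage
    sample_cov <- input * 2^eff * lognoise(n)

    ## sharp falloff (factor ~7 between the planted fraction and its
    ## neighbors) so the argmax survives per-track depth normalization
    s_tracks <- lapply(1:6, function(f) {
      v <- ifelse(is.na(timing), 0, 10 * exp(-2 * (f - timing)^2)) * lognoise(n)
      v[is.na(timing)] <- 0
      v
    })

    bg <- function(v) data.frame(chrom = "chrS", start = (seq_len(n) - 1L) * bs,
                                 end = seq_len(n) * bs, value = v)
    tracks <- c(list(input = bg(input), sample = bg(sample_cov)),
                stats::setNames(lapply(s_tracks, bg), paste0("S", 1:6)),
                list(nascent = bg(nascent)))
    list(tracks = tracks,
         truth = data.frame(bin = seq_len(n), start = (seq_len(n) - 1L) * bs,
                            timing = timing, txn_class = txn_class, effect = eff))
  })
}

#' Write a bedGraph data.frame to disk
#' @param track data.frame (chrom, start, end, value).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- pulse-chase series ---------------------------------------------------

#' Generate per-nucleus pulse-chase intensity tables
#'
#' Mean intensity after `c` cycles follows
#' `initial * 0.5^c * exp(-extra_turnover_rate * c)` with mean-one
#' multiplicative log-normal noise per nucleus; replication-independent
#' turnover (`extra_turnover_rate > 0`) pushes the mean below the
#' dilution-only expectation.
#'
#' @param initial_signal mean intensity at chase 0 (arbitrary units or %).
#' @param n_cells nuclei per chase time.
#' @param cycles vector of chase times in cell cycles (>= 0).
#' @param extra_turnover_rate replication-independent loss rate per cycle
#'   (>= 0).
#' @param noise_cv coefficient of variation of per-nucleus noise.
#' @param cell_cycle_h cell-cycle length used to report chase hours.
#' @param seed RNG seed.
#' @return data.frame (nucleus_id, chase_cycles, chase_time_h, intensity).
#' @export
generate_dilution_series <- function(initial_signal = 100, n_cells = 120L,
                                     cycles = c(0, 1, 2),
                                     extra_turnover_rate = 0, noise_cv = 0.2,
                                     cell_cycle_h = 24, seed = 1L) {
  if (any(cycles < 0)) stop("generate_dilution_series: cycles must be >= 0")
  if (extra_turnover_rate < 0) stop("generate_dilution_series: negative turnover rate")
  stopifnot(n_cells >= 1L, noise_cv >= 0)
  with_seed(seed, {
    rows <- lapply(cycles, function(cc) {
      mu <- initial_signal * 0.5^cc * exp(-extra_turnover_rate * cc)
      noise <- if (noise_cv == 0) rep(1, n_cells) else {
        sdl <- sqrt(log(1 + noise_cv^2))
        exp(stats::rnorm(n_cells, -sdl^2 / 2, sdl))
      }
      data.frame(nucleus_id = sprintf("c%g_n%03d", cc, seq_len(n_cells)),
                 chase_cycles = cc, chase_time_h = cc * cell_cycle_h,
                 intensity = mu * noise)
    })
    do.call(rbind, rows)
  })
}
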