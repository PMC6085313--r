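# 10 kb-bin enrichment of ChIP coverage vs input, replication-timing
# assignment from six Repli-seq fractions, and stratification by nascent
# transcription class.

#' Read a 4-column bedGraph file
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @return data.frame (chrom, start, end, value).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score)
}

bedgraph_to_granges <- function(track) {
  if (is.character(track) && length(track) == 1L) track <- read_bedgraph(track)
  if (inherits(track, "GRanges")) return(track)
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(track$start + 1L, track$end),
                         score = track$value)
}

#' Mean per-base coverage in consecutive fixed-size bins
#'
#' Intervals straddling a bin edge contribute pro rata (the coverage is
#' expanded to a per-base Rle and averaged per bin). With
#' `normalize = TRUE`, values are scaled by `1e6 / total signal` (total
#' signal = sum of value x width over the track), a
#' counts-per-million-equivalent depth normalization that cancels in any
#' log2 ratio of two tracks.
#'
#' @param track bedGraph data.frame, file path, or `GRanges` with a `score`.
#' @param bin_size bin width in bp; default 10000.
#' @param seqlengths optional named chromosome lengths; default: max end per
#'   chromosome, rounded up to a bin boundary.
#' @param normalize apply depth normalization.
#' @return data.frame (chrom, start, end, mean_cov), 0-based half-open bins.
#' @export
bin_coverage <- function(track, bin_size = 10000L, seqlengths = NULL,
                         normalize = TRUE) {
  gr <- bedgraph_to_granges(track)
  if (length(gr) == 0L) stop("bin_coverage: empty track")
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits)) stop("bin_coverage: overlapping intervals in track")
  if (is.null(seqlengths)) {
    ends <- tapply(GenomicRanges::end(gr),
                   as.character(GenomicRanges::seqnames(gr)), max)
    seqlengths <- ceiling(ends / bin_size) * bin_size
    seqlengths <- stats::setNames(as.integer(seqlengths), names(ends))
  }
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr) <- seqlengths
  total <- sum(as.numeric(gr$score) * GenomicRanges::width(gr))
  cov <- GenomicRanges::coverage(gr, weight = "score")
  bins <- GenomicRanges::tileGenome(seqlengths, tilewidth = bin_size,
                                    cut.last.tile.in.chrom = TRUE)
  means <- GenomicRanges::binnedAverage(bins, cov, "mean_cov")
  v <- means$mean_cov
  if (normalize) {
    if (total <= 0) stop("bin_coverage: track has no signal to normalize to")
    v <- v * 1e6 / total
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(means)),
             start = GenomicRanges::start(means) - 1L,
             end = GenomicRanges::end(means),
             mean_cov = v)
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$chrom != b$chrom) || any(a$start != b$start))
    stop("bin grids do not match")
}

#' Per-bin log2 enrichment of sample over input, with smoothing
#'
#' The ratio is defined only at bins where both tracks are positive.
#' Smoothing is a centered moving average over the nearest `smooth_window`
#' defined (non-zero) bins in genomic order per chromosome, skipping
#' undefined bins; chromosome ends use the available bins.
#'
#' @param sample_bins,input_bins outputs of [bin_coverage()] on the same grid.
#' @param smooth_window number of defined bins averaged; default 5.
#' @return data.frame (chrom, start, end, log2_ratio, log2_smooth).
#' @export
log2_enrichment <- function(sample_bins, input_bins, smooth_window = 5L) {
  check_same_grid(sample_bins, input_bins)
  ok <- sample_bins$mean_cov > 0 & input_bins$mean_cov > 0
  lr <- ifelse(ok, log2(sample_bins$mean_cov / input_bins$mean_cov), NA_real_)
  sm <- rep(NA_real_, length(lr))
  w <- max(1L, as.integer(smooth_window))
  half <- (w - 1L) %/% 2L
  for (ch in unique(sample_bins$chrom)) {
    ci <- which(sample_bins$chrom == ch)
    def <- ci[!is.na(lr[ci])]
    nd <- length(def)
    if (!nd) next
    for (k in seq_len(nd)) {
      lo <- max(1L, k - half)
      hi <- min(nd, lo + w - 1L)
      lo <- max(1L, hi - w + 1L)
      sm[def[k]] <- mean(lr[def[lo:hi]])
    }
  }
  data.frame(chrom = sample_bins$chrom, start = sample_bins$start,
             end = sample_bins$end, log2_ratio = lr, log2_smooth = sm)
}

#' Assign each bin to an S-phase fraction
#'
#' The fraction with the highest mean coverage wins; ties break toward the
#' earlier fraction; all-zero bins are unassigned (`NA`).
#'
#' @param repli_bins data.frame or matrix with six coverage columns S1..S6
#'   (one row per bin), or a list of six [bin_coverage()] outputs.
#' @return factor with levels S1..S6 (NA = unassigned).
#' @export
assign_timing <- function(repli_bins) {
  if (is.list(repli_bins) && !is.data.frame(repli_bins)) {
    for (i in seq_along(repli_bins)[-1L]) check_same_grid(repli_bins[[1L]], repli_bins[[i]])
    M <- do.call(cbind, lapply(repli_bins, `[[`, "mean_cov"))
  } else {
    cols <- paste0("S", 1:6)
    M <- as.matrix(if (all(cols %in% colnames(repli_bins)))
      repli_bins[, cols] else repli_bins)
  }
  stopifnot(ncol(M) == 6L)
  idx <- apply(M, 1L, function(v) if (all(v <= 0)) NA_integer_ else which.max(v))
  factor(paste0("S", idx), levels = paste0("S", 1:6))
}

#' Classify bins by nascent-transcription level
#'
#' Zero-coverage bins are `"none"`. Among non-zero bins, percentiles of the
#' log2-transformed coverage define the classes: at or below the 10th
#' percentile `"low"`, at or above the 90th `"high"`, otherwise `"mid"`.
#'
#' @param nascent_cov numeric per-bin nascent coverage (or a
#'   [bin_coverage()] output).
#' @return factor with levels none/low/mid/high.
#' @export
classify_transcription <- function(nascent_cov) {
  if (is.data.frame(nascent_cov)) nascent_cov <- nascent_cov$mean_cov
  nz <- which(nascent_cov > 0)
  if (length(nz) < 10L)
    stop("classify_transcription: fewer than 10 non-zero bins")
  lv <- log2(nascent_cov[nz])
  p10 <- stats::quantile(lv, 0.10, names = FALSE)
  p90 <- stats::quantile(lv, 0.90, names = FALSE)
  cls <- rep("none", length(nascent_cov))
  cls[nz] <- ifelse(lv <= p10, "low", ifelse(lv >= p90, "high", "mid"))
  factor(cls, levels = c("none", "low", "mid", "high"))
}

#' Summarize enrichment by timing fraction and transcription class
#'
#' @param bins data.frame with columns `log2_ratio` (or `log2_smooth`),
#'   `s_fraction` and `txn_class`.
#' @param value which enrichment column to summarize.
#' @return a `timing_summary` list: `by_fraction` (s_fraction, mean_log2,
#'   n) and `by_fraction_class` (s_fraction, txn_class, mean_log2, n);
#'   empty strata carry `NA` means and zero counts.
#' @export
summarize_by_timing <- function(bins, value = "log2_ratio") {
  stopifnot(value %in% names(bins), all(c("s_fraction", "txn_class") %in% names(bins)))
  v <- bins[[value]]
  frs <- paste0("S", 1:6)
  clss <- c("none", "low", "mid", "high")
  cells <- expand.grid(s_fraction = frs, txn_class = clss,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stat <- function(sel) {
    x <- v[sel & !is.na(v)]
    c(mean = if (length(x)) mean(x) else NA_real_, n = length(x))
  }
  bfc <- cbind(cells, t(mapply(function(f, cl) {
    stat(!is.na(bins$s_fraction) & bins$s_fraction == f &
           !is.na(bins$txn_class) & bins$txn_class == cl)
  }, cells$s_fraction, cells$txn_class)))
  names(bfc)[3:4] <- c("mean_log2", "n")
  bf <- data.frame(s_fraction = frs, t(vapply(frs, function(f) {
    stat(!is.na(bins$s_fraction) & bins$s_fraction == f)
  }, numeric(2L))))
  names(bf)[2:3] <- c("mean_log2", "n")
  rownames(bf) <- NULL
  structure(list(by_fraction = bf, by_fraction_class = bfc),
            class = "timing_summary")
}
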