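# Independent brute-force oracles used to validate the optimized
# implementations. These deliberately use the simplest possible data
# structures (full distance matrices, per-base expansions, repeated scans).

## O(n^2) DBSCAN: full distance matrix, BFS over core points, border points
## assigned to the cluster of their first core neighbor in scan order.
brute_dbscan <- function(xyz, eps, min_pts) {
  n <- nrow(xyz)
  D <- as.matrix(dist(xyz))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    stack <- i
    while (length(stack)) {
      j <- stack[1L]; stack <- stack[-1L]
      if (labels[j] != 0L) next
      labels[j] <- cl
      stack <- c(stack, setdiff(nb[[j]][core[nb[[j]]]], which(labels != 0L)))
    }
  }
  for (i in which(!core)) {
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  labels
}

## Two labelings agree up to relabeling iff the co-membership relations match
## and noise sets are identical.
same_clustering <- function(a, b) {
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ka <- match(a, unique(a[a != 0L]))
  kb <- match(b, unique(b[b != 0L]))
  identical(ka, kb)
}

## Brute-force consecutive-frame merging: repeated greedy nearest-first
## linking on the full pair list until nothing merges.
brute_merge <- function(tab, radius) {
  repeat {
    tab <- tab[order(tab$frame, tab$x, tab$y, tab$z, tab$channel), , drop = FALSE]
    rownames(tab) <- NULL
    n <- nrow(tab)
    succ <- rep(NA_integer_, n); pred <- rep(FALSE, n)
    pairs <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (tab$channel[i] == tab$channel[j] && tab$frame[j] == tab$frame[i] + 1L) {
        d <- sqrt(sum((unlist(tab[i, c("x", "y", "z")]) -
                         unlist(tab[j, c("x", "y", "z")]))^2))
        if (d <= radius) pairs <- rbind(pairs, c(i, j, d))
      }
    }
    if (is.null(pairs)) return(tab)
    pairs <- pairs[order(pairs[, 3L], pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (is.na(succ[i]) && !pred[j]) { succ[i] <- j; pred[j] <- TRUE }
    }
    if (all(is.na(succ))) return(tab)
    rows <- list()
    for (h in which(!pred)) {
      chain <- h
      while (!is.na(succ[chain[length(chain)]]))
        chain <- c(chain, succ[chain[length(chain)]])
      r <- tab[h, , drop = FALSE]
      r$x <- mean(tab$x[chain]); r$y <- mean(tab$y[chain]); r$z <- mean(tab$z[chain])
      rows[[length(rows) + 1L]] <- r
    }
    tab2 <- do.call(rbind, rows)
    if (nrow(tab2) == nrow(tab)) return(tab)
    tab <- tab2
  }
}

## Per-base binning oracle: expand a bedGraph to a per-base vector and take
## plain means over fixed bins (no normalization).
perbase_bin_means <- function(track, bin_size, chrom_len) {
  v <- numeric(chrom_len)
  for (i in seq_len(nrow(track))) {
    v[(track$start[i] + 1L):track$end[i]] <- track$value[i]
  }
  n_bins <- ceiling(chrom_len / bin_size)
  vapply(seq_len(n_bins), function(b) {
    mean(v[((b - 1L) * bin_size + 1L):min(b * bin_size, chrom_len)])
  }, numeric(1L))
}

## Smoothing oracle: drop undefined bins, centered rolling mean of width w
## over the remaining series (ends truncated), values put back in place.
filter_then_average <- function(lr, w) {
  out <- rep(NA_real_, length(lr))
  def <- which(!is.na(lr))
  v <- lr[def]
  half <- (w - 1L) %/% 2L
  for (k in seq_along(v)) {
    lo <- max(1L, k - half)
    hi <- min(length(v), lo + w - 1L)
    lo <- max(1L, hi - w + 1L)
    out[def[k]] <- mean(v[lo:hi])
  }
  out
}

## Small deterministic two-channel table builder for merge/clustering tests.
rand_table <- function(n, seed, box = 1000, frames = 20L, channels = "A") {
  set.seed(seed)
  loc_table(runif(n, 0, box), runif(n, 0, box), runif(n, 0, box),
            sample(0:(frames - 1L), n, replace = TRUE),
            sample(channels, n, replace = TRUE))
}
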