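# Hand-written, loop-based oracles.  These deliberately share no code with
# the package implementations: smoothing, dilation, and labeling are written
# as plain nested loops so the fast implementations can be checked against
# them event-for-event.

# 3x3 boxcar mean with in-bounds normalization, plain loops.
oracle_boxcar3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0; cnt <- 0
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          acc <- acc + m[ii, jj]; cnt <- cnt + 1
        }
      }
      out[i, j] <- acc / cnt
    }
  }
  out
}

# Chebyshev (square-neighborhood) dilation by brute force.
oracle_dilate <- function(binary, gap) {
  if (gap <= 0) return(binary)
  nr <- nrow(binary); nc <- ncol(binary)
  out <- matrix(FALSE, nr, nc)
  on <- which(binary, arr.ind = TRUE)
  for (k in seq_len(nrow(on))) {
    i0 <- max(1, on[k, 1] - gap); i1 <- min(nr, on[k, 1] + gap)
    j0 <- max(1, on[k, 2] - gap); j1 <- min(nc, on[k, 2] + gap)
    out[i0:i1, j0:j1] <- TRUE
  }
  out
}

# 4-connected components by stack-based flood fill; labels assigned in
# column-major scan order of the first pixel reached (matching bwlabel).
oracle_flood_label <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!binary[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k4 in 1:4) {
        di <- c(-1, 1, 0, 0)[k4]; dj <- c(0, 0, -1, 1)[k4]
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            binary[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Full spark-candidate oracle mirroring the documented detection contract:
# smooth, threshold, mask, dilate, label (4-connected), map labels back to
# the original supra-threshold pixels, drop small components, one candidate
# per component at the smoothed maximum.  Returns the same columns as
# detect_sparks(), sorted the same way, with labels renumbered in sorted
# order ignored (labels are compared via pixel sets, not numbers).
oracle_detect_sparks <- function(norm, cfg) {
  sm <- oracle_boxcar3(norm$dff0)
  thr <- norm$background_mean + cfg$criteria * norm$background_sd
  binary <- (sm > thr) & norm$analyzed_mask
  if (!any(binary)) {
    return(data.frame(peak_i = integer(), peak_j = integer(),
                      area_px = integer(), peak_smoothed = numeric()))
  }
  work <- oracle_dilate(binary, cfg$merge_gap_px)
  lab <- oracle_flood_label(work)
  lab[!binary] <- 0L
  out <- list()
  for (lb in sort(unique(lab[lab > 0L]))) {
    idx <- which(lab == lb)
    if (length(idx) < cfg$min_area_px) next
    pk <- idx[which.max(sm[idx])]
    out[[length(out) + 1L]] <- data.frame(
      peak_i = ((pk - 1L) %% nrow(sm)) + 1L,
      peak_j = ((pk - 1L) %/% nrow(sm)) + 1L,
      area_px = length(idx),
      peak_smoothed = sm[pk])
  }
  if (!length(out)) {
    return(data.frame(peak_i = integer(), peak_j = integer(),
                      area_px = integer(), peak_smoothed = numeric()))
  }
  out <- do.call(rbind, out)
  out[order(out$peak_j, out$peak_i), , drop = FALSE]
}

# Build a normalized_linescan object directly from a dF/F0 matrix with known
# background statistics, bypassing estimation, for detector-level tests.
make_norm <- function(dff0, bg_mean = 0, bg_sd = 1, mask = NULL,
                      pixel_size_um = 0.155, line_rate_hz = 500) {
  structure(list(
    dff0 = dff0, f0_profile = rep(1, nrow(dff0)),
    background_mean = bg_mean, background_sd = bg_sd,
    analyzed_mask = mask %||% matrix(TRUE, nrow(dff0), ncol(dff0)),
    pixel_size_um = pixel_size_um, line_rate_hz = line_rate_hz),
    class = "normalized_linescan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-way ANOVA F statistic from first principles (sums of squares).
oracle_anova_f <- function(groups) {
  all_v <- unlist(groups, use.names = FALSE)
  grand <- mean(all_v)
  k <- length(groups)
  n <- length(all_v)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# Unadjusted pooled-SD pairwise t-test p-value for a labeled pair, from the
# triangular matrix pairwise.t.test returns.
oracle_pairwise_p <- function(raw, a, b) {
  if (a %in% rownames(raw) && b %in% colnames(raw) &&
      !is.na(raw[a, b])) return(raw[a, b])
  raw[b, a]
}

# Mann-Whitney AUROC of a score against a binary truth, from pair counts.
oracle_auroc <- function(score, truth) {
  pos <- score[truth]; neg <- score[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
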