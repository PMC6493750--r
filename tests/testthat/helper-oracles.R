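# Independent oracles used across test files. Kept deliberately naive and
# separate from the package implementations they check.

# 8-connected component labeling by breadth-first flood fill, pure R.
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || labels[i, j] != 0L) next
    lab <- lab + 1L
    queue <- list(c(i, j))
    labels[i, j] <- lab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        r <- p[1] + di; cc <- p[2] + dj
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && labels[r, cc] == 0L) {
          labels[r, cc] <- lab
          queue <- c(queue, list(c(r, cc)))
        }
      }
    }
  }
  labels
}

oracle_component_stats <- function(mask) {
  labels <- oracle_label(mask)
  n <- max(labels)
  do.call(rbind, lapply(seq_len(n), function(l) {
    px <- which(labels == l, arr.ind = TRUE)
    data.frame(area = nrow(px), centroid_row = mean(px[, 1]),
               centroid_col = mean(px[, 2]))
  }))
}

# Centroid of all foreground pixels of a mask (for rendered-frame checks).
oracle_centroid <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  c(mean(px[, 1]), mean(px[, 2]))
}

# Exhaustive Otsu: sweep every candidate threshold, maximise between-class
# variance.
oracle_otsu <- function(image) {
  vals <- sort(unique(as.vector(image)))
  best <- NA; best_v <- -Inf
  for (t in vals[-1]) {
    lo <- image[image < t]; hi <- image[image >= t]
    w0 <- length(lo) / length(image); w1 <- 1 - w0
    v <- w0 * w1 * (mean(hi) - mean(lo))^2
    if (v > best_v) { best_v <- v; best <- t }
  }
  best
}

# Exhaustive minimal-total-distance assignment between two point sets
# (n, m <= 3), returning matched index pairs.
oracle_assignment <- function(prev, curr) {
  np <- nrow(prev); nc <- nrow(curr)
  k <- min(np, nc)
  d <- function(i, j) sqrt(sum((prev[i, ] - curr[j, ])^2))
  best <- NULL; best_cost <- Inf
  pidx <- utils::combn(np, k)
  for (pc in seq_len(ncol(pidx))) {
    perms <- if (k == 1) matrix(1) else do.call(
      rbind, lapply(seq_len(factorial(k)), function(x) NULL))
    # enumerate permutations of k current indices over combinations
    cidx <- utils::combn(nc, k)
    for (cc in seq_len(ncol(cidx))) {
      perm_all <- perms_of(cidx[, cc])
      for (r in seq_len(nrow(perm_all))) {
        cost <- sum(vapply(seq_len(k), function(x)
          d(pidx[x, pc], perm_all[r, x]), numeric(1)))
        if (cost < best_cost) {
          best_cost <- cost
          best <- cbind(prev_idx = pidx[, pc], curr_idx = perm_all[r, ])
        }
      }
    }
  }
  best[order(best[, 1]), , drop = FALSE]
}

perms_of <- function(v) {
  if (length(v) == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], perms_of(v[-i])))
  out
}

# Forward-scan reading of the death-call rule, as literally as possible:
# find the first quiescent run of >= quiescent_h with no movement; death is
# the last moving time point before it; movement after the run only resets
# the scan when confirmed by >= confirm_m consecutive moving frames.
oracle_call_death <- function(counts, times, quiescent_h = 4, confirm_m = 2) {
  n <- length(counts)
  q <- ceiling(quiescent_h / stats::median(diff(times)))
  pos <- 1L
  repeat {
    run_start <- NA; run_end <- NA
    i <- pos
    while (i <= n) {
      if (counts[i] == 0) {
        j <- i
        while (j < n && counts[j + 1] == 0) j <- j + 1
        if (j - i + 1 >= q) { run_start <- i; run_end <- j; break }
        i <- j + 1
      } else i <- i + 1
    }
    if (is.na(run_start)) return(list(status = "censored", time = times[n]))
    before <- which(counts[seq_len(run_start - 1)] > 0)
    anchor <- if (length(before)) times[max(before)] else times[1]
    k <- run_end + 1; conf_start <- NA
    while (k <= n) {
      if (counts[k] > 0) {
        m <- k
        while (m < n && counts[m + 1] > 0) m <- m + 1
        if (m - k + 1 >= confirm_m) { conf_start <- k; break }
        k <- m + 1
      } else k <- k + 1
    }
    if (is.na(conf_start)) return(list(status = "dead", time = anchor))
    pos <- conf_start
  }
}

# Kaplan-Meier product-limit by direct accumulation.
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event == 1]))
  s <- 1; out <- data.frame(time = ts, survival = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s
  }
  out
}
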