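# Independent brute-force oracles for region morphology and features.
# Everything here is written with explicit per-pixel loops and naive
# formulas, deliberately sharing no code with the package implementation.

# BFS labeling of 8-connected foreground components, explicit queue.
oracle_label8 <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (cc in seq_len(W)) for (rr in seq_len(H)) {
    if (!fg[rr, cc] || lab[rr, cc] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(rr, cc)); lab[rr, cc] <- nxt
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 >= 1L && r2 <= H && c2 >= 1L && c2 <= W &&
            fg[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# Hull area of the pixel squares: fan triangulation from the centroid of
# the hull vertices (a different decomposition than the shoelace form).
oracle_hull_area <- function(r, c) {
  pr <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  pc <- c(c - 0.5, c + 0.5, c - 0.5, c + 0.5)
  h <- grDevices::chull(pc, pr)
  x <- pc[h]; y <- pr[h]
  cx <- mean(x); cy <- mean(y)
  n <- length(x); a <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- a + abs((x[i] - cx) * (y[j] - cy) - (x[j] - cx) * (y[i] - cy)) / 2
  }
  a
}

oracle_regions <- function(fg, vals = NULL) {
  lab <- oracle_label8(fg)
  k <- max(lab)
  out <- vector("list", k)
  H <- nrow(fg); W <- ncol(fg)
  for (i in seq_len(k)) {
    px <- which(lab == i, arr.ind = TRUE)
    n <- nrow(px)
    perim <- 0L
    for (j in seq_len(n)) {
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- px[j, 1] + d[1]; c2 <- px[j, 2] + d[2]
        if (r2 < 1L || r2 > H || c2 < 1L || c2 > W || lab[r2, c2] != i)
          perim <- perim + 1L
      }
    }
    mr <- sum(px[, 1]) / n; mc <- sum(px[, 2]) / n
    mrr <- sum((px[, 1] - mr)^2) / n
    mcc <- sum((px[, 2] - mc)^2) / n
    mrc <- sum((px[, 1] - mr) * (px[, 2] - mc)) / n
    disc <- sqrt(((mrr - mcc) / 2)^2 + mrc^2)
    l1 <- (mrr + mcc) / 2 + disc
    l2 <- max((mrr + mcc) / 2 - disc, 0)
    out[[i]] <- list(
      area = n,
      perimeter = perim,
      major_axis_length = 4 * sqrt(max(l1, 0)),
      eccentricity = if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0,
      solidity = min(n / oracle_hull_area(px[, 1], px[, 2]), 1),
      mean_probability = if (is.null(vals)) NA_real_
                         else mean(vals[px]))
  }
  out
}

oracle_stat5 <- function(x) {
  n <- length(x)
  if (n == 0L) return(c(0, 0, 0, 0, 0))
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  c(max(x), m,
    if (n < 2L) 0 else m2,
    if (n < 3L || m2 == 0) 0 else (sum((x - m)^3) / n) / m2^(3 / 2),
    if (n < 4L || m2 == 0) 0 else (sum((x - m)^4) / n) / m2^2 - 3)
}

oracle_features <- function(vals, threshold = 0.5, tissue = NULL, dsf = 1) {
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(vals), ncol(vals))
  fg <- vals >= threshold
  out <- numeric(31L)
  if (!any(fg)) return(out)
  regs <- oracle_regions(fg, vals)
  areas <- sapply(regs, `[[`, "area") * dsf^2
  perims <- sapply(regs, `[[`, "perimeter") * dsf
  big <- which.max(sapply(regs, `[[`, "area"))
  out[1] <- length(regs)
  out[2] <- sum(fg) / sum(tissue)
  out[3] <- areas[big]
  out[4] <- regs[[big]]$major_axis_length * dsf
  out[5] <- regs[[big]]$mean_probability
  out[6] <- sum(fg) * dsf^2
  out[7:11] <- oracle_stat5(vals[fg])
  out[12:16] <- oracle_stat5(areas)
  out[17:21] <- oracle_stat5(perims)
  out[22:26] <- oracle_stat5(sapply(regs, `[[`, "eccentricity"))
  out[27:31] <- oracle_stat5(sapply(regs, `[[`, "solidity"))
  out
}

# Random blobby probability map for property tests.
random_blob_map <- function(H, W, n_blobs, seed) {
  with_seed(seed, {
    v <- matrix(0, H, W)
    for (i in seq_len(n_blobs)) {
      r0 <- runif(1, 1, H); c0 <- runif(1, 1, W)
      a <- runif(1, 1.5, max(H, W) / 4); b <- runif(1, 1.5, max(H, W) / 4)
      d <- outer((seq_len(H) - r0) / a, rep(1, W))^2 +
           outer(rep(1, H), (seq_len(W) - c0) / b)^2
      v[d <= 1] <- runif(1, 0.5, 1)
    }
    v
  })
}
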