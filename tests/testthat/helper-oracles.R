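# Independent oracles, written against the definitions only -- none of them
# share code paths with the package implementation.

# connected components by explicit stack-based flood fill
oracle_flood_fill <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (t in seq_len(nrow(nb))) {
        ii <- p[1] + nb[t, 1]; jj <- p[2] + nb[t, 2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# canonical partition of a label matrix: list of sorted pixel-index sets,
# ordered by smallest member, so two labelings compare structurally
canonical_partition <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0) return(list())
  comps <- unname(split(idx, lab[idx]))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, 0))]
}

# triangle bin by brute-force point-to-line distance maximization
oracle_triangle_bin <- function(counts) {
  n <- length(counts)
  nz <- which(counts > 0)
  if (length(nz) == 0) return(0L)
  peak <- which.max(counts)
  lo <- min(nz); hi <- max(nz)
  end <- if ((hi - peak) >= (peak - lo)) hi else lo
  if (end == peak) return(peak - 1L)
  p1 <- c(peak, counts[peak]); p2 <- c(end, counts[end])
  L <- sqrt(sum((p2 - p1)^2))
  rng <- if (end > peak) peak:end else end:peak
  best <- rng[1]; bestd <- -1
  for (i in rng) {
    # distance from point (i, counts[i]) to the segment's supporting line
    d <- abs((p2[1] - p1[1]) * (p1[2] - counts[i]) -
               (p1[1] - i) * (p2[2] - p1[2])) / L
    if (d > bestd + 1e-12) { bestd <- d; best <- i }
  }
  best - 1L
}

# grayscale opening-based background subtraction by shift-accumulate
# pmin/pmax over the structuring-function offsets
oracle_rolling_ball <- function(pixels, radius) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  off <- expand.grid(dr = -ceiling(radius):ceiling(radius),
                     dc = -ceiling(radius):ceiling(radius))
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  hh <- sqrt(radius^2 - (off$dr^2 + off$dc^2))
  shift_pad <- function(m, dr, dc, fill) {
    out <- matrix(fill, nr, nc)
    sr <- max(1, 1 - dr):min(nr, nr - dr)
    sc <- max(1, 1 - dc):min(nc, nc - dc)
    out[sr, sc] <- m[sr + dr, sc + dc]
    out
  }
  ero <- matrix(Inf, nr, nc)
  for (t in seq_len(nrow(off)))
    ero <- pmin(ero, shift_pad(pixels, off$dr[t], off$dc[t], Inf) - hh[t])
  dil <- matrix(-Inf, nr, nc)
  for (t in seq_len(nrow(off)))
    dil <- pmax(dil, shift_pad(ero, off$dr[t], off$dc[t], -Inf) + hh[t])
  out <- pixels - dil
  out[out < 0] <- 0
  out
}

# studentized range CDF by direct double quadrature of its defining
# integral (range of k standard normals divided by an independent
# sqrt(chi^2_df / df))
oracle_ptukey <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z)
      k * stats::dnorm(z) *
        (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  dens_s <- function(s)
    2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) *
      exp(-df * s^2 / 2)
  stats::integrate(function(s) vapply(s, function(si)
    dens_s(si) * inner(si), 0), 0, Inf, rel.tol = 1e-8)$value
}

# balanced two-way ANOVA sums of squares from the textbook closed forms
oracle_balanced_twoway <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B); n <- length(y) / (a * b)
  gm <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_a <- b * n * sum((mA - gm)^2)
  ss_b <- a * n * sum((mB - gm)^2)
  ss_ab <- n * sum((mAB - outer(mA - gm, mB - gm, "+") - gm)^2)
  ss_res <- sum((y - mAB[cbind(A, B)])^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_res = ss_res,
       df_a = a - 1, df_b = b - 1, df_ab = (a - 1) * (b - 1),
       df_res = a * b * (n - 1))
}
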