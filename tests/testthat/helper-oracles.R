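# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from its definition (explicit per-threshold sums,
# per-offset morphology, BFS flood fill) rather than reusing any of the
# package's incremental formulations.

# --- threshold oracles -------------------------------------------------

# score every candidate t with the two-class Renyi objective, explicit sums
oracle_renyi_t <- function(counts, alpha) {
  p <- counts / sum(counts)
  scores <- vapply(0:254, function(t) {
    # both classes must hold at least one actual pixel (integer-exact)
    if (sum(counts[seq_len(t + 1)]) == 0 || sum(counts[(t + 2):256]) == 0) {
      return(-Inf)
    }
    pa <- sum(p[seq_len(t + 1)])
    pb <- 1 - pa
    ia <- p[seq_len(t + 1)]; ia <- ia[ia > 0]
    ib <- p[(t + 2):256]; ib <- ib[ib > 0]
    if (alpha == 1) {
      -sum((ia / pa) * log(ia / pa)) - sum((ib / pb) * log(ib / pb))
    } else {
      (log(sum((ia / pa)^alpha)) + log(sum((ib / pb)^alpha))) / (1 - alpha)
    }
  }, numeric(1))
  if (all(!is.finite(scores))) return(NA_integer_)
  best <- max(scores)
  # smallest t within numerical tolerance of the maximum (tie rule)
  which(scores >= best - 1e-9 * max(1, abs(best)))[1L] - 1L
}

# Sahoo combination recomputed from scratch from the three oracle candidates
oracle_renyi_combined <- function(counts) {
  ts <- sort(vapply(c(0.5, 1, 2), function(a) oracle_renyi_t(counts, a),
                    integer(1)))
  p <- counts / sum(counts)
  P1 <- function(t) sum(p[seq_len(t + 1)])
  if (abs(ts[1] - ts[2]) <= 5) {
    beta <- if (abs(ts[2] - ts[3]) <= 5) c(1, 2, 1) else c(0, 1, 3)
  } else {
    beta <- if (abs(ts[2] - ts[3]) <= 5) c(3, 1, 0) else c(1, 2, 1)
  }
  om <- P1(ts[3]) - P1(ts[1])
  as.integer(floor(ts[1] * (P1(ts[1]) + 0.25 * om * beta[1]) +
                   0.25 * ts[2] * om * beta[2] +
                   ts[3] * ((1 - P1(ts[3])) + 0.25 * om * beta[3])))
}

# the Intermodes smoothing loop written independently
oracle_intermodes <- function(counts, max_iter = 10000L) {
  h <- as.numeric(counts)
  n_modes <- function(h) {
    sum(h[2:255] > h[1:254] & h[2:255] > h[3:256])
  }
  iter <- 0L
  while (n_modes(h) != 2L) {
    if (iter >= max_iter) return(NA_integer_)
    hp <- c(0, h, 0)
    h <- (hp[1:256] + hp[2:257] + hp[3:258]) / 3
    iter <- iter + 1L
  }
  m <- which(h[2:255] > h[1:254] & h[2:255] > h[3:256]) # gray level = index
  as.integer(sum(m) %/% 2L)
}

# seeded random histogram: mixture of 1-3 roughly Gaussian lobes
random_lobe_histogram <- function(seed) {
  set.seed(seed)
  n_lobes <- sample(1:3, 1)
  counts <- integer(256)
  for (k in seq_len(n_lobes)) {
    center <- sample(10:245, 1)
    spread <- sample(2:12, 1)
    mass <- sample(50:5000, 1)
    levels <- pmin(255, pmax(0, round(rnorm(mass, center, spread))))
    counts <- counts + tabulate(levels + 1L, 256L)
  }
  structure(list(counts = counts, total = sum(counts)),
            class = "intensity_histogram")
}

# --- morphology oracles ------------------------------------------------

# BFS flood-fill labeling, raster order, written without the package's code
oracle_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  cur <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        ni <- p[1] + nb[k, 1]; nj <- p[2] + nb[k, 2]
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue <- c(queue, list(c(ni, nj)))
        }
      }
    }
  }
  lab
}

# explicit per-offset grayscale opening with a spherical-cap element
# (clipped windows at the border, as the package defines)
oracle_ball_opening <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2, ]
  offs$h <- sqrt(r^2 - offs$di^2 - offs$dj^2)
  pass <- function(src, combine, sign) {
    out <- matrix(if (sign > 0) -Inf else Inf, H, W)
    for (k in seq_len(nrow(offs))) {
      di <- offs$di[k]; dj <- offs$dj[k]; h <- offs$h[k]
      r0 <- max(1, 1 - di):min(H, H - di)
      c0 <- max(1, 1 - dj):min(W, W - dj)
      out[r0, c0] <- combine(out[r0, c0], src[r0 + di, c0 + dj] + sign * h)
    }
    out
  }
  ero <- pass(img, pmin, -1)
  pass(ero, pmax, +1)
}

random_mask <- function(seed, H = 32L, W = 32L, p = 0.35) {
  set.seed(seed)
  matrix(runif(H * W) < p, H, W)
}
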