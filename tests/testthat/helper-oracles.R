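# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (brute force) and share no code with the
# package internals they check.

# rasterize a filled ellipse into a logical mask (TRUE = black/pore)
raster_ellipse <- function(h, w, cx, cy, a, b, angle_deg = 0) {
  xs <- 0:(w - 1)
  dx <- outer(rep(1, h), xs - cx)
  dy <- outer(0:(h - 1) - cy, rep(1, w))
  ct <- cos(angle_deg * pi / 180); st <- sin(angle_deg * pi / 180)
  ((dx * ct + dy * st) / a)^2 + ((-dx * st + dy * ct) / b)^2 <= 1
}

raster_rect <- function(h, w, r0, r1, c0, c1) {
  m <- matrix(FALSE, h, w)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# naive 4/8-connected labeling oracle by repeated flood fill (queue in R)
flood_label_oracle <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1,-1,-1,0,0,1,1,1), c(-1,0,1,-1,1,-1,0,1))
  } else cbind(c(-1,1,0,0), c(0,0,-1,1))
  cur <- 0L
  for (i in 1:h) for (j in 1:w) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in 1:nrow(nb)) {
        ni <- p[1] + nb[k, 1]; nj <- p[2] + nb[k, 2]
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0) {
          lab[ni, nj] <- cur
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# even-odd point-in-polygon (independent of the package's internal helper)
pip_oracle <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (k in 1:n) {
    cross <- (vy[k] > py) != (vy[j] > py)
    if (any(cross)) {
      xint <- vx[k] + (py[cross] - vy[k]) / (vy[j] - vy[k]) * (vx[j] - vx[k])
      inside[cross] <- xor(inside[cross], px[cross] < xint)
    }
    j <- k
  }
  inside
}

# pixel-counting area oracle: number of integer grid points inside the polygon
pixel_count_area_oracle <- function(vx, vy) {
  gx <- seq(floor(min(vx)), ceiling(max(vx)))
  gy <- seq(floor(min(vy)), ceiling(max(vy)))
  g <- expand.grid(x = gx, y = gy)
  sum(pip_oracle(g$x, g$y, vx, vy))
}

# random star-shaped simple polygon around a center
random_simple_polygon <- function(n = 12, rmin = 5, rmax = 25) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(x = 40 + r * cos(ang), y = 40 + r * sin(ang))
}

# direct (non-fast) evaluation of the non-local-means formula at one pixel,
# patches taken fully inside the image
nlm_pixel_oracle <- function(img, y, x, h, patch, search) {
  pr <- patch %/% 2; sr <- search %/% 2
  patch_at <- function(cy, cx) img[(cy - pr):(cy + pr), (cx - pr):(cx + pr)]
  ref <- patch_at(y, x)
  num <- img[y, x]; den <- 1 # self weight 1
  for (dy in -sr:sr) for (dx in -sr:sr) {
    if (dy == 0 && dx == 0) next
    d2 <- mean((ref - patch_at(y + dy, x + dx))^2)
    w <- exp(-d2 / h^2)
    num <- num + w * img[y + dy, x + dx]
    den <- den + w
  }
  num / den
}

# classic histogram equalization closed form (CDF scaled to [0, 255])
hist_eq_oracle <- function(img) {
  counts <- tabulate(as.integer(img) + 1L, 256)
  cdf <- cumsum(counts) / length(img)
  map <- as.integer(round(255 * cdf))
  matrix(map[as.integer(img) + 1L], nrow(img), ncol(img))
}

# variance of the 256-bin histogram: lower = flatter
hist_flatness <- function(img) stats::var(tabulate(as.integer(img) + 1L, 256))

# small clean phantom shared by several suites (cheap to analyze)
small_phantom <- function(seed = 3, ...) {
  poremorph::generate_phantom(poremorph::phantom_spec(
    width = 400, height = 400, n_pores = 6, seed = seed, ...))
}
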