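## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: ray casting instead of sp, interp instead of
## deldir, explicit order-statistic interpolation instead of quantile().

## even-odd ray casting; returns TRUE for strictly interior points
ray_cast_inside <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((vy[i] > y) != (vy[j] > y)) {
        xint <- vx[i] + (y - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
        if (x < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

## linear interpolation between order statistics, written out explicitly
sort_percentile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  if (n == 1L) return(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

## alpha-shape area from an independent Delaunay engine (interp) with
## circumradii from an explicit circumcenter solve
alpha_area_oracle <- function(points, alpha) {
  tm <- interp::tri.mesh(points[, 1], points[, 2])
  tr <- interp::triangles(tm)
  px <- tm$x; py <- tm$y
  total <- 0
  for (r in seq_len(nrow(tr))) {
    a <- c(px[tr[r, 1]], py[tr[r, 1]])
    b <- c(px[tr[r, 2]], py[tr[r, 2]])
    cc <- c(px[tr[r, 3]], py[tr[r, 3]])
    M <- 2 * rbind(b - a, cc - a)
    rhs <- c(sum(b^2) - sum(a^2), sum(cc^2) - sum(a^2))
    ctr <- solve(M, rhs)
    r2 <- sum((ctr - a)^2)
    if (r2 <= alpha) {
      total <- total +
        abs((b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])) / 2
    }
  }
  total
}

convex_hull_area <- function(points) {
  h <- grDevices::chull(points)
  v <- points[h, , drop = FALSE]
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  abs(sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2])) / 2
}

## uniform points in a disk
disk_points <- function(n, center = c(0, 0), r = 200) {
  rad <- r * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(center[1] + rad * cos(th), center[2] + rad * sin(th))
}

## a localization table of two dense, well-separated disks (100 points each)
two_disk_table <- function(seed = 11, sep = 2000, r = 150, n = 100) {
  set.seed(seed)
  a <- disk_points(n, c(500, 500), r)
  b <- disk_points(n, c(500 + sep, 500), r)
  localizationTable(c(a[, 1], b[, 1]), c(a[, 2], b[, 2]),
                    adcount = rep(2e4, 2 * n))
}
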