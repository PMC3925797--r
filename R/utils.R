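## Internal helpers: seeding, polygons, intervals.

## Deterministic sub-seed from a master seed and integer indices, kept
## below 2^31 so it is a valid set.seed() argument.
.subSeed <- function(seed, ...) {
  v <- c(seed, ...)
  h <- 0
  for (x in v) h <- (h * 69069 + (as.double(x) %% 2147483647) + 1) %% 2147483629
  as.integer(h)
}

.strategyCores <- function(strategy) {
  if (strategy == "TRUS12") return(12L)
  m <- regmatches(strategy, regexec("^TARGETED_([1-9][0-9]*)$", strategy))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else NA_integer_
}

.normalize <- function(v) v / sqrt(sum(v^2))

## Shoelace signed area (positive for counter-clockwise vertex order).
.polygonArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

.polygonCentroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

## O(n^2) proper-crossing test; fine at contour sizes (<= ~128 vertices).
.polygonSelfIntersects <- function(p) {
  n <- nrow(p)
  if (n > 256L) return(FALSE)  # validity check skipped for very large contours
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip shared-vertex neighbours
    if (!length(js)) next
    p1 <- a[i, ]; p2 <- b[i, ]
    d1 <- p2 - p1
    q1 <- a[js, , drop = FALSE]; q2 <- b[js, , drop = FALSE]
    d2 <- q2 - q1
    denom <- d1[1] * d2[, 2] - d1[2] * d2[, 1]
    dq <- cbind(q1[, 1] - p1[1], q1[, 2] - p1[2])
    t1 <- (dq[, 1] * d2[, 2] - dq[, 2] * d2[, 1]) / denom
    t2 <- (dq[, 1] * d1[2] - dq[, 2] * d1[1]) / denom
    hit <- is.finite(t1) & is.finite(t2) &
      t1 > 1e-12 & t1 < 1 - 1e-12 & t2 > 1e-12 & t2 < 1 - 1e-12
    if (any(hit)) return(TRUE)
  }
  FALSE
}

## Signed distance from points (n x 2) to a closed polygon boundary,
## positive inside. Vectorised over points, loop over edges.
.polygonSdf <- function(points, poly) {
  n <- nrow(poly)
  px <- points[, 1]; py <- points[, 2]
  d2min <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]
    ex <- poly[j, 1] - ax; ey <- poly[j, 2] - ay
    len2 <- ex * ex + ey * ey
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - ax) * ex + (py - ay) * ey) / len2)) else 0
    dx <- px - (ax + t * ex); dy <- py - (ay + t * ey)
    d2 <- dx * dx + dy * dy
    d2min <- pmin(d2min, d2)
  }
  inside <- pracma::inpolygon(px, py, poly[, 1], poly[, 2], boundary = TRUE)
  ifelse(inside, 1, -1) * sqrt(d2min)
}

## Total length of the union of intervals given as a k x 2 matrix.
.unionLength <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(0)
  if (nrow(iv) == 1L) return(iv[1, 2] - iv[1, 1])
  o <- order(iv[, 1])
  a <- iv[o, 1]; b <- iv[o, 2]
  total <- 0
  curA <- a[1]; curB <- b[1]
  for (i in 2:length(a)) {
    if (a[i] > curB) {
      total <- total + (curB - curA)
      curA <- a[i]; curB <- b[i]
    } else if (b[i] > curB) curB <- b[i]
  }
  total + (curB - curA)
}

## Regular N-gon approximation of an ellipse, counter-clockwise.
## Vertices lie ON the ellipse; area deficit is O(N^-2).
.ellipsePolygon <- function(centre, rx, ry, theta = 0, n = 64L) {
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x0 <- rx * cos(ang); y0 <- ry * sin(ang)
  ct <- cos(theta); st <- sin(theta)
  cbind(centre[1] + ct * x0 - st * y0, centre[2] + st * x0 + ct * y0)
}

## Truncated lognormal sampler (inverse-CDF; deterministic given RNG state).
.rlnormTrunc <- function(n, meanlog, sdlog, min, max) {
  if (sdlog <= 0 || min >= max)
    return(pmin(max, pmax(min, rep(exp(meanlog), n))))
  plo <- stats::plnorm(min, meanlog, sdlog)
  phi <- stats::plnorm(max, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}
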