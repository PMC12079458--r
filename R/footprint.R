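# Footprint geometry.
#
# The occupied region of a growing aggregate is represented as a convex
# polygon plus an exact Minkowski dilation by a disc of radius d.  For a
# convex polygon with area A0 and perimeter P, the dilated area is the Steiner
# formula A0 + P*d + pi*d^2, so the dilation radius reproducing any target
# area has a closed form.  Uniform sampling on the dilated region decomposes
# exactly into the polygon (fan triangulation), one rectangle per edge and
# the vertex wedges, which jointly tile a full disc.

poly_area <- function(v) {
  # shoelace; v is an n x 2 matrix, CCW positive
  x <- v[, 1L]; y <- v[, 2L]
  i2 <- c(seq_len(nrow(v))[-1L], 1L)
  0.5 * sum(x * y[i2] - x[i2] * y)
}

poly_perimeter <- function(v) {
  i2 <- c(seq_len(nrow(v))[-1L], 1L)
  sum(sqrt((v[i2, 1L] - v[, 1L])^2 + (v[i2, 2L] - v[, 2L])^2))
}

#' Elliptical footprint polygon
#'
#' Regular angular discretization of an ellipse, rescaled so the polygon area
#' equals `area` exactly (the inscribed polygon is otherwise slightly small).
#'
#' @param area target polygon area in nm^2.
#' @param aspect major/minor axis ratio (>= 1); 1 gives a disc-like polygon.
#' @param origin centre, nm.
#' @param n number of vertices.
#' @return an `n` x 2 matrix of vertices, counter-clockwise.
#' @keywords internal
footprint_polygon <- function(area, aspect = 1, origin = c(0, 0), n = 64L) {
  stopifnot(area > 0, aspect >= 1)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  b <- sqrt(area / (pi * aspect))
  v <- cbind(aspect * b * cos(th), b * sin(th))
  v <- v * sqrt(area / poly_area(v))
  v[, 1L] <- v[, 1L] + origin[1L]
  v[, 2L] <- v[, 2L] + origin[2L]
  v
}

# Dilation radius d >= 0 such that area(poly (+) disc(d)) == target.
dilation_for_area <- function(poly, target) {
  a0 <- poly_area(poly)
  if (target <= a0) return(0)
  p <- poly_perimeter(poly)
  (-p + sqrt(p^2 + 4 * pi * (target - a0))) / (2 * pi)
}

footprint_area <- function(poly, d = 0) {
  poly_area(poly) + poly_perimeter(poly) * d + pi * d^2
}

# Uniform sample of n points on the dilated polygon.  Exact decomposition:
# interior polygon / edge rectangles / vertex wedges (the wedges tile a disc,
# each wedge spanning the gap between adjacent outward edge normals).
# Distance from points to the dilated footprint: 0 inside the polygon,
# distance minus d clipped at 0 within the band, positive outside.
dist_to_footprint <- function(poly, d, pts) {
  if (!nrow(pts)) return(numeric(0))
  m <- nrow(poly)
  i2 <- c(seq_len(m)[-1L], 1L)
  inside <- rep(TRUE, nrow(pts))
  dmin <- rep(Inf, nrow(pts))
  for (e in seq_len(m)) {
    ax <- poly[e, 1L]; ay <- poly[e, 2L]
    ex <- poly[i2[e], 1L] - ax; ey <- poly[i2[e], 2L] - ay
    cross <- ex * (pts[, 2L] - ay) - ey * (pts[, 1L] - ax)
    inside <- inside & cross >= 0
    l2 <- ex^2 + ey^2
    tt <- pmin(pmax(((pts[, 1L] - ax) * ex + (pts[, 2L] - ay) * ey) / l2, 0), 1)
    dmin <- pmin(dmin, sqrt((pts[, 1L] - (ax + tt * ex))^2 +
                              (pts[, 2L] - (ay + tt * ey))^2))
  }
  out <- pmax(dmin - d, 0)
  out[inside] <- 0
  out
}

sample_footprint <- function(poly, d, n) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  m <- nrow(poly)
  i2 <- c(seq_len(m)[-1L], 1L)
  ex <- poly[i2, 1L] - poly[, 1L]
  ey <- poly[i2, 2L] - poly[, 2L]
  len <- sqrt(ex^2 + ey^2)
  a_poly <- poly_area(poly)

  if (d <= 0) {
    comp <- rep.int(1L, n)
  } else {
    w <- c(a_poly, sum(len) * d, pi * d^2)
    comp <- sample.int(3L, n, replace = TRUE, prob = w)
  }
  out <- matrix(0, n, 2L)

  ip <- which(comp == 1L)
  if (length(ip)) {
    # fan triangulation from the vertex centroid (interior: polygon convex)
    c0 <- colMeans(poly)
    ta <- 0.5 * abs((poly[, 1L] - c0[1L]) * (poly[i2, 2L] - c0[2L]) -
                      (poly[i2, 1L] - c0[1L]) * (poly[, 2L] - c0[2L]))
    tri <- sample.int(m, length(ip), replace = TRUE, prob = ta)
    r1 <- sqrt(stats::runif(length(ip)))
    r2 <- stats::runif(length(ip))
    out[ip, 1L] <- (1 - r1) * c0[1L] + r1 * ((1 - r2) * poly[tri, 1L] + r2 * poly[i2, 1L][tri])
    out[ip, 2L] <- (1 - r1) * c0[2L] + r1 * ((1 - r2) * poly[tri, 2L] + r2 * poly[i2, 2L][tri])
  }

  ir <- which(comp == 2L)
  if (length(ir)) {
    ed <- sample.int(m, length(ir), replace = TRUE, prob = len)
    u <- stats::runif(length(ir))
    w <- stats::runif(length(ir)) * d
    # outward normal of a CCW edge is (ey, -ex)/len
    nx <- ey[ed] / len[ed]; ny <- -ex[ed] / len[ed]
    out[ir, 1L] <- poly[ed, 1L] + u * ex[ed] + w * nx
    out[ir, 2L] <- poly[ed, 2L] + u * ey[ed] + w * ny
  }

  iw <- which(comp == 3L)
  if (length(iw)) {
    phi <- atan2(-ex, ey)                     # outward normal angles, (-pi, pi]
    th <- stats::runif(length(iw), -pi, pi)
    rr <- d * sqrt(stats::runif(length(iw)))
    # wedge between normals of edges (i-1, i) belongs to vertex i
    ord <- order(phi)
    pos <- findInterval(th, phi[ord])
    vtx <- i2[ord][ifelse(pos == 0L, m, pos)]  # edge -> shared end vertex
    out[iw, 1L] <- poly[vtx, 1L] + rr * cos(th)
    out[iw, 2L] <- poly[vtx, 2L] + rr * sin(th)
  }
  out
}
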