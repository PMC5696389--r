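#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going up (half-up), the convention
#' used by printed survey summary tables, rather than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Close a lon/lat ring (first vertex repeated last) if it is not already.
close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) == 0) return(ring)
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

## TRUE where segments (p1,p2) and (p3,p4) properly intersect (interior crossing).
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

## Error if a closed ring self-intersects (non-adjacent edges crossing).
check_simple_ring <- function(ring) {
  ring <- close_ring(ring)
  k <- nrow(ring) - 1L
  if (k < 3) return(invisible(TRUE))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (j == i + 1L || (i == 1L && j == k)) next
      if (segments_cross(ring[i, ], ring[i + 1L, ], ring[j, ], ring[j + 1L, ]))
        stop("polygon ring is self-intersecting (edges ", i, " and ", j, ")")
    }
  }
  invisible(TRUE)
}

## Distance from points (q x 2) to a segment a-b.
point_segment_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

## TRUE for points lying on the ring boundary (within tol).
on_ring <- function(pts, ring, tol = 1e-9) {
  ring <- close_ring(ring)
  out <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(ring) - 1L)) {
    out <- out | (point_segment_dist(pts, ring[i, ], ring[i + 1L, ]) <= tol)
  }
  out
}

## Strict interior test: inside by ray casting and not on the boundary.
points_inside_ring <- function(pts, ring, strict = TRUE, tol = 1e-9) {
  pts <- as.matrix(pts)
  ring <- close_ring(ring)
  if (nrow(ring) < 4) return(rep(FALSE, nrow(pts)))
  inside <- mgcv::in.out(ring, pts)
  if (strict) {
    bnd <- on_ring(pts, ring, tol)
    inside <- inside & !bnd
  } else {
    inside <- inside | on_ring(pts, ring, tol)
  }
  inside
}

## Area of a simple polygon (shoelace), absolute value.
ring_area <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[-nrow(ring), 1]; y <- ring[-nrow(ring), 2]
  xn <- ring[-1, 1]; yn <- ring[-1, 2]
  abs(sum(x * yn - xn * y)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
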