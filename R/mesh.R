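## Triangulated mesh over the survey domain and the finite-element operators
## of the SPDE/Matern discretization.
##
## The triangulation is an incremental (Bowyer-Watson) Delaunay of the
## boundary ring plus (cutoff-thinned) data points, refined by inserting
## circumcenters/edge midpoints of oversized triangles until no inside
## triangle has an edge longer than max_edge. Coordinates are treated as
## planar lon/lat degrees (no sphere correction); at 40-52 N this stretches
## east-west distances by up to ~1/cos(lat), a caveat carried through to the
## reported spatial range, which is read in degrees latitude.

## ---- Bowyer-Watson Delaunay ------------------------------------------------

circumcircle <- function(p1, p2, p3) {
  ## returns c(cx, cy, r2); degenerate triangles get infinite radius
  ax <- p1[, 1]; ay <- p1[, 2]
  bx <- p2[, 1]; by <- p2[, 2]
  cx <- p3[, 1]; cy <- p3[, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  small <- abs(d) < 1e-14
  d[small] <- NA
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  ux[small] <- 0; uy[small] <- 0; r2[small] <- Inf
  cbind(ux, uy, r2)
}

## Delaunay triangulation of a point set (no duplicates). Returns an m x 3
## index matrix with counter-clockwise orientation.
delaunay_triangulate <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points to triangulate")
  ctr <- colMeans(pts)
  spread <- svd(sweep(pts, 2, ctr))$d
  if (spread[2] < 1e-12 * max(spread[1], 1))
    stop("all points are collinear; cannot build a triangulation")
  span <- max(apply(pts, 2, function(v) diff(range(v))))
  big <- 50 * span
  super <- rbind(ctr + c(-big, -big), ctr + c(big, -big), ctr + c(0, big))
  allp <- rbind(pts, super)
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  cc <- circumcircle(allp[tri[, 1], , drop = FALSE],
                     allp[tri[, 2], , drop = FALSE],
                     allp[tri[, 3], , drop = FALSE])
  eps <- 1e-10 * span^2
  for (ip in seq_len(n)) {
    p <- allp[ip, ]
    bad <- (p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 <= cc[, 3] + eps
    if (!any(bad)) { # numerical fallback: nearest circumcircle
      d2 <- (p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 - cc[, 3]
      bad <- seq_len(nrow(tri)) == which.min(d2)
    }
    bt <- tri[bad, , drop = FALSE]
    ## cavity boundary = edges of bad triangles appearing exactly once
    e <- rbind(bt[, c(1, 2), drop = FALSE],
               bt[, c(2, 3), drop = FALSE],
               bt[, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- !(key %in% key[duplicated(key)])
    eb <- e[once, , drop = FALSE]
    newt <- cbind(ip, eb)
    ## orient counter-clockwise
    a <- allp[newt[, 1], , drop = FALSE]
    b <- allp[newt[, 2], , drop = FALSE]
    c2 <- allp[newt[, 3], , drop = FALSE]
    det <- (b[, 1] - a[, 1]) * (c2[, 2] - a[, 2]) -
      (c2[, 1] - a[, 1]) * (b[, 2] - a[, 2])
    flip <- det < 0
    newt[flip, ] <- newt[flip, c(1, 3, 2), drop = FALSE]
    tri <- rbind(tri[!bad, , drop = FALSE], newt)
    cc <- rbind(cc[!bad, , drop = FALSE],
                circumcircle(allp[newt[, 1], , drop = FALSE],
                             allp[newt[, 2], , drop = FALSE],
                             allp[newt[, 3], , drop = FALSE]))
  }
  keep <- rowSums(matrix(tri %in% ((n + 1L):(n + 3L)), nrow(tri), 3)) == 0
  tri[keep, , drop = FALSE]
}

## Greedy thinning: keep points at least `cutoff` apart, in input order.
thin_points <- function(pts, cutoff) {
  pts <- as.matrix(pts)
  if (nrow(pts) == 0 || cutoff <= 0) return(pts)
  keep <- 1L
  for (i in seq_len(nrow(pts))[-1]) {
    d2 <- (pts[keep, 1] - pts[i, 1])^2 + (pts[keep, 2] - pts[i, 2])^2
    if (min(d2) >= cutoff^2) keep <- c(keep, i)
  }
  pts[keep, , drop = FALSE]
}

## Evenly subdivide ring edges so no boundary segment exceeds max_len.
densify_ring <- function(ring, max_len) {
  ring <- close_ring(ring)
  out <- NULL
  for (i in seq_len(nrow(ring) - 1L)) {
    a <- ring[i, ]; b <- ring[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / max_len))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out <- rbind(out, cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
  }
  out
}

#' Build a refined Delaunay triangulation over the survey domain
#'
#' Nodes are the domain boundary (densified to `max_edge`), the data points
#' thinned so that no two nodes are closer than `cutoff`, and refinement
#' points inserted until no triangle inside the domain has an edge longer
#' than `max_edge` — so triangles are smaller where data points are denser.
#' When no boundary ring is supplied, the domain is the convex hull of the
#' data inflated outward by `extension` of its diameter, the standard guard
#' against precision-boundary effects of the SPDE discretization.
#'
#' @param points k x 2 matrix of lon/lat data locations (k >= 3).
#' @param boundary optional simple closed lon/lat ring; may be concave (e.g.
#'   an estuary notch carved out of the domain).
#' @param max_edge target maximum triangle edge length, in degrees.
#' @param cutoff minimum node spacing; nearby data points collapse to one
#'   node. Must satisfy `max_edge > cutoff > 0`.
#' @param extension outward inflation of the domain, as a fraction of the
#'   domain diameter.
#' @param max_nodes safety cap on refinement.
#' @return an object of class `trawl_mesh` with `nodes` (n x 2),
#'   `triangles` (m x 3, counter-clockwise), `boundary_flag`, `n_nodes`,
#'   and the domain `boundary` ring used.
#' @export
build_mesh <- function(points, boundary = NULL, max_edge = 1, cutoff = 0.1,
                       extension = 0.15, max_nodes = 8000) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 data points")
  if (!(max_edge > cutoff && cutoff > 0))
    stop("require max_edge > cutoff > 0")
  ctr <- colMeans(points)
  if (is.null(boundary)) {
    hull <- points[grDevices::chull(points), , drop = FALSE]
    boundary <- hull
  } else {
    boundary <- as.matrix(boundary)
    check_simple_ring(boundary)
    boundary <- boundary[!duplicated(boundary[, 1] + 1i * boundary[, 2]), ,
                         drop = FALSE]
  }
  diam <- max(stats::dist(rbind(boundary, points)))
  if (extension > 0) {
    ctr_b <- colMeans(boundary)
    v <- sweep(boundary, 2, ctr_b)
    len <- sqrt(rowSums(v^2)); len[len == 0] <- 1
    boundary <- boundary + extension * diam * v / len
  }
  bring <- close_ring(boundary)
  bnodes <- densify_ring(bring, max_edge)
  inner <- points[points_inside_ring(points, bring, strict = TRUE), ,
                  drop = FALSE]
  nodes <- thin_points(rbind(bnodes, inner), cutoff)
  tol_area <- 1e-12 * diam^2

  for (pass in seq_len(40L)) {
    tri <- delaunay_triangulate(nodes)
    cen <- (nodes[tri[, 1], , drop = FALSE] + nodes[tri[, 2], , drop = FALSE] +
              nodes[tri[, 3], , drop = FALSE]) / 3
    inside <- points_inside_ring(cen, bring, strict = FALSE, tol = 1e-7)
    tri <- tri[inside, , drop = FALSE]
    if (nrow(tri) == 0) stop("no triangles inside the domain boundary")
    e1 <- sqrt(rowSums((nodes[tri[, 1], , drop = FALSE] -
                          nodes[tri[, 2], , drop = FALSE])^2))
    e2 <- sqrt(rowSums((nodes[tri[, 2], , drop = FALSE] -
                          nodes[tri[, 3], , drop = FALSE])^2))
    e3 <- sqrt(rowSums((nodes[tri[, 3], , drop = FALSE] -
                          nodes[tri[, 1], , drop = FALSE])^2))
    longest <- pmax(e1, e2, e3)
    big <- which(longest > max_edge)
    if (length(big) == 0 || nrow(nodes) >= max_nodes) break
    big <- big[order(longest[big], decreasing = TRUE)]
    cc <- circumcircle(nodes[tri[big, 1], , drop = FALSE],
                       nodes[tri[big, 2], , drop = FALSE],
                       nodes[tri[big, 3], , drop = FALSE])
    use_cc <- is.finite(cc[, 3]) &
      points_inside_ring(cc[, 1:2, drop = FALSE], bring, strict = TRUE)
    ## fallback: midpoint of the longest edge
    mids <- matrix(0, length(big), 2)
    for (j in seq_along(big)) {
      t3 <- tri[big[j], ]
      ee <- c(e1[big[j]], e2[big[j]], e3[big[j]])
      k <- which.max(ee)
      pr <- rbind(c(1, 2), c(2, 3), c(3, 1))[k, ]
      mids[j, ] <- (nodes[t3[pr[1]], ] + nodes[t3[pr[2]], ]) / 2
    }
    cand <- mids
    cand[use_cc, ] <- cc[use_cc, 1:2]
    cand <- cand[points_inside_ring(cand, bring, strict = FALSE, tol = 1e-9), ,
                 drop = FALSE]
    ## keep candidates well separated from existing nodes and each other
    sep <- max(cutoff, 0.4 * max_edge)
    acc <- NULL
    for (j in seq_len(nrow(cand))) {
      d2 <- (nodes[, 1] - cand[j, 1])^2 + (nodes[, 2] - cand[j, 2])^2
      if (min(d2) < sep^2) next
      if (!is.null(acc)) {
        d2a <- (acc[, 1] - cand[j, 1])^2 + (acc[, 2] - cand[j, 2])^2
        if (min(d2a) < sep^2) next
      }
      acc <- rbind(acc, cand[j, ])
      if (nrow(nodes) + nrow(acc) >= max_nodes) break
    }
    if (is.null(acc)) break
    nodes <- rbind(nodes, acc)
  }

  ## final triangulation bookkeeping
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)
  ## boundary nodes: on edges used by exactly one triangle
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- !(key %in% key[duplicated(key)])
  bflag <- rep(FALSE, nrow(nodes))
  bflag[unique(as.vector(e[once, ]))] <- TRUE
  colnames(nodes) <- c("lon", "lat")
  structure(list(nodes = nodes, triangles = tri, boundary_flag = bflag,
                 n_nodes = nrow(nodes), boundary = bring,
                 max_edge = max_edge, cutoff = cutoff,
                 extension = extension),
            class = "trawl_mesh")
}

#' @export
print.trawl_mesh <- function(x, ...) {
  cat("trawl_mesh:", x$n_nodes, "nodes,", nrow(x$triangles), "triangles,",
      sum(x$boundary_flag), "boundary nodes\n")
  invisible(x)
}

## ---- finite-element operators ---------------------------------------------

#' Finite-element mass and stiffness matrices of a mesh
#'
#' Linear (P1) basis assembly: `C` is the lumped (diagonal) mass matrix whose
#' trace equals the total mesh area, and `G` the sparse symmetric stiffness
#' matrix with zero row sums (constant functions are in its null space).
#' These are the building blocks of the Matern SPDE precision.
#'
#' @param mesh a `trawl_mesh`.
#' @return list with sparse matrices `C` (diagonal) and `G`.
#' @export
fem_matrices <- function(mesh) {
  nd <- mesh$nodes; tri <- mesh$triangles
  n <- nrow(nd)
  p1 <- nd[tri[, 1], , drop = FALSE]
  p2 <- nd[tri[, 2], , drop = FALSE]
  p3 <- nd[tri[, 3], , drop = FALSE]
  area <- 0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
                   (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
  bad <- which(area <= 1e-12 * max(abs(area)))
  if (length(bad) > 0)
    stop("degenerate (zero-area or mis-oriented) triangle(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  ## lumped mass: a third of each incident triangle's area
  agg <- rowsum(rep(area / 3, 3), as.vector(tri))
  Cd <- numeric(n)
  Cd[as.integer(rownames(agg))] <- agg[, 1]
  ## stiffness: Ke[i,j] = (b_i b_j + c_i c_j) / (4 A)
  b <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2])
  cc <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1])
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (bb in 1:3) {
    k <- k + 1
    ii[[k]] <- tri[, a]; jj[[k]] <- tri[, bb]
    xx[[k]] <- (b[, a] * b[, bb] + cc[, a] * cc[, bb]) / (4 * area)
  }
  G <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  G <- Matrix::forceSymmetric((G + Matrix::t(G)) / 2)
  list(C = Matrix::Diagonal(n, Cd), G = G)
}

## ---- observation projector -------------------------------------------------

#' Barycentric projector from mesh basis to point locations
#'
#' Each point is located in its containing triangle and given the barycentric
#' coordinates of that triangle's vertices as weights, so each row has at
#' most three non-zeros summing to one and linear functions are reproduced
#' exactly.
#'
#' @param mesh a `trawl_mesh`.
#' @param points q x 2 lon/lat matrix.
#' @param allow_outside if `TRUE`, points outside the mesh get an all-zero
#'   row (and are reported in the `outside` attribute) instead of an error.
#' @return a sparse q x n weight matrix.
#' @export
projector <- function(mesh, points, allow_outside = FALSE) {
  points <- as.matrix(points)
  q <- nrow(points)
  nd <- mesh$nodes; tri <- mesh$triangles
  m <- nrow(tri)
  assigned <- integer(q)          # triangle index per point, 0 = none
  w <- matrix(0, q, 3)
  tol <- -1e-9
  ## grid bin points for bbox candidate lookup
  rng <- apply(nd, 2, range)
  ng <- max(1L, floor(sqrt(m)))
  gx <- function(x) pmin(ng, pmax(1L, 1L + floor((x - rng[1, 1]) /
                                                   (diff(rng[, 1]) + 1e-12) * ng)))
  gy <- function(y) pmin(ng, pmax(1L, 1L + floor((y - rng[1, 2]) /
                                                   (diff(rng[, 2]) + 1e-12) * ng)))
  pcell <- (gx(points[, 1]) - 1L) * ng + gy(points[, 2])
  cell_pts <- split(seq_len(q), pcell)
  for (t in seq_len(m)) {
    a <- nd[tri[t, 1], ]; b <- nd[tri[t, 2], ]; c2 <- nd[tri[t, 3], ]
    xr <- range(a[1], b[1], c2[1]); yr <- range(a[2], b[2], c2[2])
    cells <- as.vector(outer((gx(xr[1]):gx(xr[2]) - 1L) * ng,
                             gy(yr[1]):gy(yr[2]), "+"))
    cand <- unlist(cell_pts[as.character(cells)], use.names = FALSE)
    cand <- cand[assigned[cand] == 0L]
    if (length(cand) == 0) next
    px <- points[cand, 1]; py <- points[cand, 2]
    det <- (b[1] - a[1]) * (c2[2] - a[2]) - (c2[1] - a[1]) * (b[2] - a[2])
    l1 <- ((b[2] - c2[2]) * (px - c2[1]) + (c2[1] - b[1]) * (py - c2[2])) / det
    l2 <- ((c2[2] - a[2]) * (px - c2[1]) + (a[1] - c2[1]) * (py - c2[2])) / det
    l3 <- 1 - l1 - l2
    hit <- l1 >= tol & l2 >= tol & l3 >= tol
    if (any(hit)) {
      idx <- cand[hit]
      assigned[idx] <- t
      w[idx, ] <- cbind(pmax(l1[hit], 0), pmax(l2[hit], 0), pmax(l3[hit], 0))
    }
  }
  out <- which(assigned == 0L)
  if (length(out) > 0 && !allow_outside)
    stop("point(s) outside the mesh hull: ",
         paste(utils::head(out, 10), collapse = ", "))
  ok <- assigned > 0L
  wn <- w[ok, , drop = FALSE] / rowSums(w[ok, , drop = FALSE])
  A <- Matrix::sparseMatrix(i = rep(which(ok), 3),
                            j = as.vector(tri[assigned[ok], ]),
                            x = as.vector(wn),
                            dims = c(q, nrow(nd)))
  attr(A, "outside") <- out
  A
}

## ---- serialization ----------------------------------------------------------

#' Write / read a mesh as two delimited text files
#'
#' `<stem>_nodes.csv` holds lon, lat and the boundary flag;
#' `<stem>_triangles.csv` the three node indices per triangle.
#'
#' @param mesh a `trawl_mesh`.
#' @param stem file path stem.
#' @return the stem, invisibly (`write_mesh`); a `trawl_mesh` (`read_mesh`).
#' @export
write_mesh <- function(mesh, stem) {
  utils::write.csv(data.frame(lon = mesh$nodes[, 1], lat = mesh$nodes[, 2],
                              boundary = as.integer(mesh$boundary_flag)),
                   paste0(stem, "_nodes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(v1 = mesh$triangles[, 1],
                              v2 = mesh$triangles[, 2],
                              v3 = mesh$triangles[, 3]),
                   paste0(stem, "_triangles.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(stem) {
  nd <- utils::read.csv(paste0(stem, "_nodes.csv"))
  tr <- utils::read.csv(paste0(stem, "_triangles.csv"))
  nodes <- as.matrix(nd[, c("lon", "lat")])
  colnames(nodes) <- c("lon", "lat")
  structure(list(nodes = nodes, triangles = as.matrix(tr),
                 boundary_flag = nd$boundary == 1L, n_nodes = nrow(nodes),
                 boundary = NULL), class = "trawl_mesh")
}
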