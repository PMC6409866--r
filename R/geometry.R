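# Internal planar-geometry helpers shared across segmentation, meshing and
# warping. All coordinates follow the package convention: pixel (0,0) at the
# top-left of the raster, x rightward, y downward, pixel centres at integer
# coordinates. Polygons are n x 2 matrices (columns x, y), implicitly closed.

#' Signed polygon area (shoelace). Positive when vertices are ordered
#' counter-clockwise in mathematical axes.
#' @noRd
poly_signed_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

#' @noRd
poly_area <- function(xy) abs(poly_signed_area(xy))

#' Polygon centroid (area-weighted, shoelace form). Falls back to vertex mean
#' for degenerate (near zero area) inputs.
#' @noRd
poly_centroid <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(xy))
  c(sum((xy[, 1] + xy[j, 1]) * cr), sum((xy[, 2] + xy[j, 2]) * cr)) / (6 * a)
}

#' Cyclic edge lengths and cumulative arc length of a closed polygon.
#' @noRd
poly_arclength <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  seg <- sqrt(rowSums((xy[j, , drop = FALSE] - xy)^2))
  list(seg = seg, cum = cumsum(c(0, seg[-n])), perimeter = sum(seg))
}

#' Resample an open polyline to n points equidistant in arc length,
#' keeping both endpoints.
#' @noRd
resample_polyline <- function(pts, n) {
  stopifnot(nrow(pts) >= 2, n >= 2)
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(matrix(rep(pts[1, ], n), ncol = 2, byrow = TRUE))
  target <- seq(0, total, length.out = n)
  x <- stats::approx(cum, pts[, 1], xout = target, ties = "ordered")$y
  y <- stats::approx(cum, pts[, 2], xout = target, ties = "ordered")$y
  cbind(x, y)
}

#' Scanline even-odd polygon fill. Returns a logical matrix of dims
#' c(height, width); element [y+1, x+1] is TRUE when pixel centre (x, y)
#' lies inside the polygon.
#' @noRd
rasterize_polygon <- function(xy, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  n <- nrow(xy)
  j <- c(2:n, 1)
  x1 <- xy[, 1]; y1 <- xy[, 2]; x2 <- xy[j, 1]; y2 <- xy[j, 2]
  ymin <- max(0L, floor(min(y1)))
  ymax <- min(height - 1L, ceiling(max(y1)))
  if (ymax < ymin) return(mask)
  for (y in ymin:ymax) {
    crosses <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(crosses)) next
    xs <- sort(x1[crosses] + (y - y1[crosses]) / (y2[crosses] - y1[crosses]) *
                 (x2[crosses] - x1[crosses]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      xa <- ceiling(xs[k] - 1e-9)
      xb <- floor(xs[k + 1] + 1e-9)
      xa <- max(xa, 0L); xb <- min(xb, width - 1L)
      if (xa <= xb) mask[y + 1L, (xa + 1L):(xb + 1L)] <- TRUE
    }
  }
  mask
}

#' Even-odd point-in-polygon test for a matrix of query points.
#' @noRd
points_in_polygon <- function(pts, xy) {
  pracma::inpolygon(pts[, 1], pts[, 2], xy[, 1], xy[, 2], boundary = TRUE)
}

#' Barycentric point-in-triangle test; eps widens the triangle slightly so
#' edge pixels are claimed.
#' @noRd
points_in_triangle <- function(pts, tri, eps = 1e-9) {
  d <- (tri[2, 2] - tri[3, 2]) * (tri[1, 1] - tri[3, 1]) +
       (tri[3, 1] - tri[2, 1]) * (tri[1, 2] - tri[3, 2])
  if (abs(d) < 1e-12) return(rep(FALSE, nrow(pts)))
  l1 <- ((tri[2, 2] - tri[3, 2]) * (pts[, 1] - tri[3, 1]) +
         (tri[3, 1] - tri[2, 1]) * (pts[, 2] - tri[3, 2])) / d
  l2 <- ((tri[3, 2] - tri[1, 2]) * (pts[, 1] - tri[3, 1]) +
         (tri[1, 1] - tri[3, 1]) * (pts[, 2] - tri[3, 2])) / d
  l3 <- 1 - l1 - l2
  l1 >= -eps & l2 >= -eps & l3 >= -eps
}

#' The unique affine map sending triangle src onto triangle dst.
#' Returns list(A = 2x2, b = length-2): p -> A p + b.
#' @noRd
affine_from_triangles <- function(src, dst) {
  M <- cbind(src, 1)
  sol <- solve(M, dst)            # 3x2; columns are (a d; b e; c f)
  list(A = t(sol[1:2, ]), b = sol[3, ])
}

#' Sutherland-Hodgman clip of a convex polygon against the half-plane to the
#' left of directed edge a -> b.
#' @noRd
clip_halfplane <- function(poly, a, b) {
  if (is.null(poly) || nrow(poly) == 0) return(poly)
  ex <- b[1] - a[1]; ey <- b[2] - a[2]
  side <- ex * (poly[, 2] - a[2]) - ey * (poly[, 1] - a[1])
  n <- nrow(poly)
  out <- matrix(0, nrow = 2 * n, ncol = 2)
  m <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ci <- side[i] <= 1e-12; cj <- side[j] <= 1e-12
    if (ci) { m <- m + 1; out[m, ] <- poly[i, ] }
    if (xor(ci, cj)) {
      t <- side[i] / (side[i] - side[j])
      m <- m + 1
      out[m, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

#' Area of intersection of two triangles (each 3x2, any orientation).
#' @noRd
triangle_intersection_area <- function(t1, t2) {
  if (poly_signed_area(t2) < 0) t2 <- t2[3:1, ]
  poly <- t1
  for (i in 1:3) {
    j <- if (i == 3) 1L else i + 1L
    poly <- clip_halfplane(poly, t2[i, ], t2[j, ])
    if (is.null(poly) || nrow(poly) < 3) return(0)
  }
  poly_area(poly)
}

#' Label connected components of a logical mask. EBImage's labeller is
#' 4-connected, whereas signal components here are defined 8-connected, so
#' the adjacency graph is built explicitly and passed to igraph.
#' Returns an integer matrix; 0 is background, components numbered from 1.
#' @noRd
label_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  id <- matrix(0L, h, w)
  id[fg] <- seq_along(fg)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  rows <- (fg - 1L) %% h + 1L
  cols <- (fg - 1L) %/% h + 1L
  edges <- integer(0)
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- id[cbind(r2[ok], c2[ok])]
    keep <- nb > 0L
    if (any(keep)) {
      edges <- c(edges, rbind(id[cbind(rows[ok][keep], cols[ok][keep])], nb[keep]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[fg] <- as.integer(memb)
  lab
}

#' Rotation matrix for angle theta (radians) in the pixel frame.
#' @noRd
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Apply an affine transform list(A, b) to an n x 2 point matrix.
#' @noRd
apply_affine <- function(tf, pts) {
  sweep(pts %*% t(tf$A), 2, tf$b, "+")
}

#' Compose affines: returns the transform equivalent to applying first
#' `inner`, then `outer`.
#' @noRd
compose_affine <- function(outer, inner) {
  list(A = outer$A %*% inner$A, b = as.numeric(outer$A %*% inner$b) + outer$b)
}
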