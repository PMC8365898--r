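#' Construct a plane from a normal vector and offset
#'
#' Planes are stored in Hessian normal form: a unit normal `n` and a scalar
#' offset `d` such that points `p` on the plane satisfy `n . p = d`.
#'
#' @param normal Length-3 numeric, need not be unit length (it is normalized).
#' @param offset Scalar; rescaled together with the normal.
#' @return A `vm_plane` object.
#' @export
plane <- function(normal, offset) {
  normal <- as.numeric(normal)
  if (length(normal) != 3L || !all(is.finite(normal)) || !is.finite(offset))
    .vm_stop("vm_invalid_plane", "plane needs a finite 3-vector normal and scalar offset")
  n <- .vm_norm(normal)
  if (n == 0) .vm_stop("vm_invalid_plane", "plane normal must be nonzero")
  structure(list(normal = normal / n, offset = as.numeric(offset) / n),
            class = "vm_plane")
}

#' @export
print.vm_plane <- function(x, ...) {
  cat(sprintf("Plane: normal (% .6f, % .6f, % .6f), offset % .6f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Signed distance from a point to a plane
#'
#' @param p Length-3 point, or an n x 3 matrix of points (mm).
#' @param plane A `vm_plane`.
#' @return Signed distance(s) in mm: `normal . p - offset`; zero iff on-plane.
#' @export
point_plane_distance <- function(p, plane) {
  stopifnot(inherits(plane, "vm_plane"))
  if (is.matrix(p)) drop(p %*% plane$normal) - plane$offset
  else sum(p * plane$normal) - plane$offset
}

# Orthogonal projection of point(s) onto a plane.
.vm_project_on_plane <- function(p, plane) {
  d <- point_plane_distance(p, plane)
  if (is.matrix(p)) p - outer(d, plane$normal) else p - d * plane$normal
}

#' Fit a plane to points
#'
#' With exactly three points the unique plane through them is returned (zero
#' residual). With more points the total-least-squares plane is fitted by
#' eigen-decomposition of the centered scatter matrix (orthogonal regression).
#'
#' @param points An n x 3 matrix (n >= 3) of coordinates in mm.
#' @return A `vm_plane`. The residual (sum of squared orthogonal distances)
#'   is attached as attribute `"residual"`.
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 3L)
    .vm_stop("vm_invalid_plane", "need an n x 3 matrix with n >= 3")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  scale <- max(sqrt(rowSums(X^2)), 1e-12)
  if (nrow(points) == 3L) {
    n <- .vm_cross(X[2, ] - X[1, ], X[3, ] - X[1, ])
    if (.vm_norm(n) <= 1e-12 * scale^2)
      .vm_stop("vm_degenerate_landmarks", "points are collinear or coincident")
    pl <- plane(n, sum(n * ctr))
    attr(pl, "residual") <- 0
    return(pl)
  }
  S <- crossprod(X)
  ev <- eigen(S, symmetric = TRUE)
  n <- ev$vectors[, 3]
  if (ev$values[2] <= 1e-18 * max(ev$values[1], 1))
    .vm_stop("vm_degenerate_landmarks", "points are collinear or coincident")
  pl <- plane(n, sum(n * ctr))
  attr(pl, "residual") <- ev$values[3]
  pl
}

#' Fit the mid-sagittal plane from landmarks
#'
#' The mid-sagittal plane (MSP) passes through the three midline landmarks:
#' the posterior endplate valley, the laminae intersection, and the midpoint
#' of the posterior rim of the inferior endplate. If extra (near-)midline
#' points are supplied, an orthogonal-regression plane through all points is
#' fitted instead. The normal is signed to point toward the left uncinate
#' tip, which makes the left/right labeling of the para-sagittal planes
#' deterministic.
#'
#' @param lm A `vm_landmarks` object.
#' @param extra_midline Optional k x 3 matrix of additional midline points.
#' @return A `vm_plane` with attribute `"residual"`.
#' @export
fit_midsagittal_plane <- function(lm, extra_midline = NULL) {
  stopifnot(inherits(lm, "vm_landmarks"))
  pts <- rbind(lm$pev, lm$laminae_intersection, lm$posterior_rim_midpoint)
  if (!is.null(extra_midline)) pts <- rbind(pts, as.matrix(extra_midline))
  pl <- fit_plane(pts)
  if (point_plane_distance(lm$up_tip_left, pl) < 0) {
    res <- attr(pl, "residual")
    pl <- plane(-pl$normal, -pl$offset)
    attr(pl, "residual") <- res
  }
  pl
}

#' Lateral para-sagittal plane through an uncinate tip
#'
#' Defined as the plane parallel to the mid-sagittal plane passing through
#' the uncinate-process tip, so the mid-sagittal, lateral, and quarter
#' para-sagittal planes form a parallel family.
#'
#' @param msp The mid-sagittal `vm_plane`.
#' @param up_tip Length-3 point (mm), the uncinate process tip.
#' @return A `vm_plane` parallel to `msp` through `up_tip`.
#' @export
lateral_plane <- function(msp, up_tip) {
  stopifnot(inherits(msp, "vm_plane"))
  up_tip <- as.numeric(up_tip)
  plane(msp$normal, sum(msp$normal * up_tip))
}

#' Average (bisector) plane of two planes
#'
#' For parallel planes this is the unique mid-plane; the quarter
#' para-sagittal planes are the averages of the mid-sagittal plane with each
#' lateral plane. For non-parallel input the normals are sign-aligned, the
#' returned normal is the normalized normal sum, and the plane is anchored at
#' the midpoint of the orthogonal projections of a shared anchor point (the
#' midpoint of the two planes' closest-to-origin points) onto each plane.
#'
#' @param a,b `vm_plane` objects.
#' @return A `vm_plane`.
#' @export
average_plane <- function(a, b) {
  stopifnot(inherits(a, "vm_plane"), inherits(b, "vm_plane"))
  nb <- b$normal; ob <- b$offset
  if (sum(a$normal * nb) < 0) { nb <- -nb; ob <- -ob }
  n <- a$normal + nb
  if (.vm_norm(n) <= 1e-12)
    .vm_stop("vm_undefined_bisector", "sign-aligned normals sum to zero")
  n <- n / .vm_norm(n)
  anchor <- (a$normal * a$offset + nb * ob) / 2
  m <- (.vm_project_on_plane(anchor, a) + .vm_project_on_plane(anchor, plane(nb, ob))) / 2
  plane(n, sum(n * m))
}

#' Build the anatomical local frame
#'
#' Axes: `lr` is the MSP normal signed toward the left uncinate tip;
#' `ap` is the unit vector from the laminae intersection toward the posterior
#' rim midpoint projected into the MSP (the posterior elements lie behind the
#' body, so it points anteriorly); `si = lr x ap`, sign-corrected so the
#' posterior endplate valley (on the superior endplate) has a larger
#' superior coordinate than the posterior rim midpoint. The origin is the
#' posterior rim midpoint. For anatomically consistent landmarks the triple
#' `(ap, si, lr)` is right-handed.
#'
#' @param lm A `vm_landmarks` object.
#' @param msp The mid-sagittal `vm_plane`; fitted from `lm` if missing.
#' @return A `vm_frame`: list with `origin`, `ap`, `si`, `lr`.
#' @export
build_frame <- function(lm, msp = fit_midsagittal_plane(lm)) {
  stopifnot(inherits(lm, "vm_landmarks"), inherits(msp, "vm_plane"))
  lr <- msp$normal
  if (point_plane_distance(lm$up_tip_left, msp) < 0) lr <- -lr
  v <- lm$posterior_rim_midpoint - lm$laminae_intersection
  v <- v - sum(v * msp$normal) * msp$normal
  if (.vm_norm(v) <= 1e-9 * max(.vm_norm(lm$posterior_rim_midpoint - lm$laminae_intersection), 1))
    .vm_stop("vm_degenerate_frame",
             "laminae intersection and posterior rim midpoint coincide in the MSP")
  ap <- v / .vm_norm(v)
  si <- .vm_unit(.vm_cross(lr, ap))
  if (sum((lm$pev - lm$posterior_rim_midpoint) * si) <= 0) si <- -si
  structure(list(origin = lm$posterior_rim_midpoint, ap = ap, si = si, lr = lr),
            class = "vm_frame")
}

#' @export
print.vm_frame <- function(x, ...) {
  cat("Anatomical frame (mm):\n")
  cat(sprintf("  origin % .4f % .4f % .4f\n", x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("ap", "si", "lr"))
    cat(sprintf("  %-6s % .6f % .6f % .6f\n", ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  invisible(x)
}
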