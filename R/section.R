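#' Intersect a triangle mesh with a plane
#'
#' Every triangle crossing the plane contributes one segment; segments are
#' chained into closed loops. Vertices lying exactly on the plane are handled
#' by symbolic perturbation (treated as lying an epsilon on the positive
#' side), which guarantees closed loops on watertight meshes. Open chains
#' (from non-watertight input) are excluded with a warning.
#'
#' @param mesh A `vm_mesh`.
#' @param plane A `vm_plane`.
#' @return List of `vm_section` objects (possibly empty if the plane misses
#'   the mesh). Each has `points`, a closed polyline (first row repeated as
#'   the last row), and `plane`.
#' @export
slice_mesh <- function(mesh, plane) {
  stopifnot(inherits(mesh, "vm_mesh"), inherits(plane, "vm_plane"))
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(F) == 0) return(list())
  d <- drop(V %*% plane$normal) - plane$offset
  scale <- max(abs(d), 1)
  d[d == 0] <- 1e-300 * scale  # symbolic perturbation: on-plane counts positive
  pos <- d > 0
  np <- pos[F[, 1]] + pos[F[, 2]] + pos[F[, 3]]
  keep <- np == 1L | np == 2L
  if (!any(keep)) return(list())
  Fk <- F[keep, , drop = FALSE]
  nf <- nrow(Fk)
  # candidate edges, 3 per face; a crossing face has exactly 2 crossed edges
  ia <- c(Fk[, 1], Fk[, 2], Fk[, 3])
  ib <- c(Fk[, 2], Fk[, 3], Fk[, 1])
  crossed <- pos[ia] != pos[ib]
  ekey <- paste0(pmin(ia, ib), "_", pmax(ia, ib))
  # per-face pair of crossed edge slots (column-major: slots nf apart)
  slot <- matrix(crossed, nf, 3L)
  keys <- matrix(ekey, nf, 3L)
  seg <- t(vapply(seq_len(nf), function(i) keys[i, slot[i, ]], character(2)))
  ukey <- unique(as.vector(seg))
  # intersection point per unique crossed edge
  first <- match(ukey, ekey)
  pa <- ia[first]; pb <- ib[first]
  t <- d[pa] / (d[pa] - d[pb])
  pts <- V[pa, , drop = FALSE] + t * (V[pb, , drop = FALSE] - V[pa, , drop = FALSE])
  segm <- cbind(match(seg[, 1], ukey), match(seg[, 2], ukey))
  # chain segments into loops: incidence of segments on edge-points
  inc <- vector("list", length(ukey))
  for (s in seq_len(nf)) {
    inc[[segm[s, 1]]] <- c(inc[[segm[s, 1]]], s)
    inc[[segm[s, 2]]] <- c(inc[[segm[s, 2]]], s)
  }
  used <- logical(nf)
  loops <- list()
  n_open <- 0L
  for (s0 in seq_len(nf)) {
    if (used[s0]) next
    used[s0] <- TRUE
    start <- segm[s0, 1]
    cur <- segm[s0, 2]
    path <- integer(length(ukey) + 1L)
    path[1:2] <- c(start, cur)
    len <- 2L
    closed <- FALSE
    repeat {
      if (cur == start) { closed <- TRUE; break }
      cand <- inc[[cur]]
      nxt <- cand[!used[cand]]
      if (!length(nxt)) break
      s <- nxt[1L]
      used[s] <- TRUE
      cur <- if (segm[s, 1] == cur) segm[s, 2] else segm[s, 1]
      len <- len + 1L
      path[len] <- cur
    }
    if (closed && len >= 4L) {
      loops[[length(loops) + 1L]] <-
        structure(list(points = pts[path[1:len], , drop = FALSE], plane = plane),
                  class = "vm_section")
    } else n_open <- n_open + 1L
  }
  if (n_open > 0L)
    warning(sprintf("excluded %d open chain(s); mesh is likely not watertight", n_open))
  loops
}

#' @export
print.vm_section <- function(x, ...) {
  cat(sprintf("Section curve: %d points (closed)\n", nrow(x$points) - 1L))
  invisible(x)
}

# Polygon area of a 3D planar loop (closed representation) via its plane basis.
.vm_section_area <- function(section) {
  n <- section$plane$normal
  u <- .vm_unit(if (abs(n[1]) < 0.9) .vm_cross(n, c(1, 0, 0)) else .vm_cross(n, c(0, 1, 0)))
  w <- .vm_cross(n, u)
  p <- section$points
  x <- drop(p %*% u); y <- drop(p %*% w)
  k <- nrow(p) - 1L
  abs(sum(x[1:k] * y[2:(k + 1L)] - x[2:(k + 1L)] * y[1:k]) / 2)
}

#' Select the vertebral-body loop among section curves
#'
#' Mesh-plane sections of a whole vertebra contain the body loop and loops
#' through the posterior elements. The body loop is the one whose centroid is
#' nearest to the centroid of the body-associated landmarks (PEV, posterior
#' rim midpoint, and both uncinate tips); ties are broken in favour of the
#' larger enclosed area, then by input order (stable).
#'
#' @param curves List of `vm_section` objects.
#' @param lm A `vm_landmarks`.
#' @return A single `vm_section`.
#' @export
select_body_curve <- function(curves, lm) {
  if (!length(curves)) .vm_stop("vm_no_section", "no section curves to select from")
  stopifnot(inherits(lm, "vm_landmarks"))
  target <- colMeans(rbind(lm$pev, lm$posterior_rim_midpoint,
                           lm$up_tip_left, lm$up_tip_right))
  cent <- t(vapply(curves, function(cv) {
    p <- cv$points
    colMeans(p[-nrow(p), , drop = FALSE])
  }, numeric(3)))
  dist <- sqrt(rowSums(sweep(cent, 2, target)^2))
  area <- vapply(curves, .vm_section_area, numeric(1))
  ord <- order(round(dist / 1e-9), -area)
  curves[[ord[1]]]
}

#' Project a section curve into the anatomical sagittal frame
#'
#' Maps a section curve (which must lie in a plane parallel to the frame's
#' sagittal (ap, si) plane) to 2D (anterior-positive, superior-positive)
#' coordinates relative to the frame origin, and normalizes the orientation
#' to counter-clockwise.
#'
#' @param curve A `vm_section`.
#' @param frame A `vm_frame`.
#' @param label Optional plane label, one of `"L"`, `"M"`, `"R"`.
#' @param angle_tol Maximum allowed angle (rad) between the curve plane
#'   normal and the frame's left-right axis.
#' @return A `vm_planar_curve`: list with `points` (n x 2 matrix, open
#'   representation, counter-clockwise) and `label`.
#' @export
to_planar <- function(curve, frame, label = NA_character_, angle_tol = 1e-3) {
  stopifnot(inherits(curve, "vm_section"), inherits(frame, "vm_frame"))
  cosang <- abs(sum(curve$plane$normal * frame$lr))
  if (acos(min(cosang, 1)) > angle_tol)
    .vm_stop("vm_misaligned_curve",
             "section plane is not parallel to the sagittal frame plane (angle %.2e rad)",
             acos(min(cosang, 1)))
  p <- curve$points
  p <- p[-nrow(p), , drop = FALSE]  # drop closing duplicate
  rel <- sweep(p, 2, frame$origin)
  xy <- cbind(drop(rel %*% frame$ap), drop(rel %*% frame$si))
  if (nrow(unique(xy)) < 3L)
    .vm_stop("vm_degenerate_section", "planar curve has fewer than 3 distinct points")
  n <- nrow(xy)
  j <- c(2:n, 1L)
  area2 <- sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])
  if (area2 < 0) xy <- xy[rev(seq_len(n)), , drop = FALSE]
  structure(list(points = xy, label = label), class = "vm_planar_curve")
}

#' @export
print.vm_planar_curve <- function(x, ...) {
  r <- apply(x$points, 2, range)
  cat(sprintf("Planar curve [%s]: %d points, ap [%.2f, %.2f] mm, si [%.2f, %.2f] mm\n",
              ifelse(is.na(x$label), "?", x$label), nrow(x$points),
              r[1, 1], r[2, 1], r[1, 2], r[2, 2]))
  invisible(x)
}

#' Partition a planar body curve into endplate and wall arcs
#'
#' The four rim corners are the vertices maximizing the four diagonal support
#' directions (+ap+si), (-ap+si), (+ap-si), (-ap-si) (anterosuperior,
#' posterosuperior, anteroinferior, posteroinferior). The superior arc runs
#' from the anterosuperior to the posterosuperior corner along the
#' superior side; the four arcs partition the closed curve.
#'
#' @param pc A `vm_planar_curve` (counter-clockwise).
#' @return A `vm_segments`: corner indices and arc index vectors
#'   (`superior`, `posterior`, `inferior`, `anterior`) into `pc$points`.
#' @export
segment_rims <- function(pc) {
  stopifnot(inherits(pc, "vm_planar_curve"))
  P <- pc$points
  n <- nrow(P)
  i_as <- which.max(P[, 1] + P[, 2])
  i_ps <- which.max(-P[, 1] + P[, 2])
  i_ai <- which.max(P[, 1] - P[, 2])
  i_pi <- which.max(-P[, 1] - P[, 2])
  corners <- c(anterosuperior = i_as, posterosuperior = i_ps,
               posteroinferior = i_pi, anteroinferior = i_ai)
  if (anyDuplicated(corners))
    .vm_stop("vm_degenerate_section", "two rim corners coincide")
  # counter-clockwise cyclic order must be AS -> PS -> PI -> AI
  rel <- (corners - i_as) %% n
  if (is.unsorted(rel))
    .vm_stop("vm_degenerate_section", "rim corners are not in cyclic order")
  arc <- function(from, to) {
    if (from <= to) from:to else c(from:n, 1:to)
  }
  structure(list(corners = corners,
                 superior = arc(i_as, i_ps),
                 posterior = arc(i_ps, i_pi),
                 inferior = arc(i_pi, i_ai),
                 anterior = arc(i_ai, i_as)),
            class = "vm_segments")
}

#' Extract the 2D points of one arc
#'
#' @param pc A `vm_planar_curve`.
#' @param segs A `vm_segments` from [segment_rims()].
#' @param which One of `"superior"`, `"posterior"`, `"inferior"`, `"anterior"`.
#' @return Matrix of arc points (k x 2).
#' @export
arc_points <- function(pc, segs, which = c("superior", "posterior", "inferior", "anterior")) {
  which <- match.arg(which)
  pc$points[segs[[which]], , drop = FALSE]
}

#' Endplate depth: anteroposterior rim-to-rim chord of an arc
#'
#' @param arc Matrix (k x 2, k >= 2) of arc points; the first and last rows
#'   are the rim corners.
#' @return Chord length in mm.
#' @export
endplate_depth <- function(arc) {
  arc <- as.matrix(arc)
  if (nrow(arc) < 2L) .vm_stop("vm_degenerate_section", "arc needs at least 2 points")
  .vm_norm(arc[nrow(arc), ] - arc[1L, ])
}

#' Concavity depth of an arc
#'
#' Maximum perpendicular distance from the endpoint chord to any arc vertex,
#' measured on the concave side (the side carrying the dominant deviation);
#' zero for a straight arc.
#'
#' @param arc Matrix (k x 2, k >= 2) of arc points.
#' @return Depth in mm (>= 0).
#' @export
concave_depth <- function(arc) {
  arc <- as.matrix(arc)
  if (nrow(arc) < 2L) .vm_stop("vm_degenerate_section", "arc needs at least 2 points")
  a <- arc[1L, ]; b <- arc[nrow(arc), ]
  u <- b - a
  L <- .vm_norm(u)
  if (L == 0) return(max(sqrt(rowSums(sweep(arc, 2, a)^2))))
  nvec <- c(-u[2], u[1]) / L
  s <- drop(sweep(arc, 2, a) %*% nvec)
  if (max(s) < -min(s)) s <- -s
  max(0, max(s))
}

#' Measure one vertebra in the three sagittal planes
#'
#' Runs the full pipeline: mid-sagittal plane from the midline landmarks,
#' lateral planes through the uncinate tips, quarter para-sagittal planes as
#' the average planes, anatomical frame, mesh slicing in each of the left
#' (L), mid-sagittal (M), and right (R) planes, body-loop selection,
#' re-alignment to 2D, rim segmentation, and the three dimensions per curve:
#' SED (superior endplate anteroposterior depth), IED (inferior endplate
#' depth, the chord between the anterior and posterior rims of the inferior
#' endplate concave), and IECD (inferior endplate concavity depth).
#'
#' @param mesh A `vm_mesh` (mm).
#' @param lm A `vm_landmarks`.
#' @return A `vm_measurements` data frame with one row per plane label
#'   (L, M, R) and columns `label`, `sed_mm`, `iecd_mm`, `ied_mm`.
#' @examples
#' fix <- generate_vertebra(vertebra_params())
#' measure_vertebra(fix$mesh, fix$truth$landmarks)
#' @export
measure_vertebra <- function(mesh, lm) {
  stopifnot(inherits(mesh, "vm_mesh"), inherits(lm, "vm_landmarks"))
  msp <- fit_midsagittal_plane(lm)
  frame <- build_frame(lm, msp)
  planes <- list(
    L = average_plane(msp, lateral_plane(msp, lm$up_tip_left)),
    M = msp,
    R = average_plane(msp, lateral_plane(msp, lm$up_tip_right)))
  rows <- lapply(names(planes), function(lab) {
    rec <- tryCatch({
      curves <- slice_mesh(mesh, planes[[lab]])
      body <- select_body_curve(curves, lm)
      pc <- to_planar(body, frame, label = lab)
      segs <- segment_rims(pc)
      sup <- arc_points(pc, segs, "superior")
      inf <- arc_points(pc, segs, "inferior")
      data.frame(label = lab,
                 sed_mm = endplate_depth(sup),
                 iecd_mm = concave_depth(inf),
                 ied_mm = endplate_depth(inf),
                 stringsAsFactors = FALSE)
    }, vm_error = function(e) {
      .vm_stop(class(e)[1], "plane %s: %s", lab, conditionMessage(e))
    })
    rec
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$label, c("L", "M", "R"))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vm_measurements", "data.frame")
  out
}

#' Fig-style alias names for measurement values
#'
#' Combines the plane label (L, M, R) with the dimension (SED, IECD, IED)
#' into the conventional nine names LSED ... RIED.
#'
#' @param label Plane label(s).
#' @param dimension Dimension name(s): `"SED"`, `"IECD"`, or `"IED"`.
#' @return Character vector of alias names.
#' @export
measurement_alias <- function(label, dimension) {
  if (length(label) == 0) return(character(0))
  paste0(label, dimension)
}
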