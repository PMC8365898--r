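#' Canonical landmark names
#'
#' The five named anatomical points that drive all reference-plane
#' construction: the posterior endplate valley (PEV) on the superior endplate,
#' the intersection point of the bilateral laminae, the midpoint of the
#' posterior rim of the inferior endplate, and the lateral tips of the left
#' and right uncinate processes.
#'
#' @return Character vector of the five canonical landmark names.
#' @export
landmark_names <- function() {
  c("pev", "laminae_intersection", "posterior_rim_midpoint",
    "up_tip_left", "up_tip_right")
}

#' Construct a validated landmark set
#'
#' @param pev,laminae_intersection,posterior_rim_midpoint,up_tip_left,up_tip_right
#'   Numeric length-3 vectors, coordinates in mm.
#' @return A `vm_landmarks` object (named list of length-3 numeric vectors).
#' @details Validity requires finite coordinates, the three midline points
#'   (PEV, laminae intersection, posterior rim midpoint) to be non-collinear,
#'   distinct uncinate tips, and the two tips to lie on opposite sides of the
#'   plane through the midline points.
#' @examples
#' lm <- landmark_set(pev = c(0, -4.8, 6),
#'                    laminae_intersection = c(0, -14, -6),
#'                    posterior_rim_midpoint = c(0, -8, -6),
#'                    up_tip_left = c(12, 0, 8), up_tip_right = c(-12, 0, 8))
#' @export
landmark_set <- function(pev, laminae_intersection, posterior_rim_midpoint,
                         up_tip_left, up_tip_right) {
  lm <- list(pev = as.numeric(pev),
             laminae_intersection = as.numeric(laminae_intersection),
             posterior_rim_midpoint = as.numeric(posterior_rim_midpoint),
             up_tip_left = as.numeric(up_tip_left),
             up_tip_right = as.numeric(up_tip_right))
  for (nm in names(lm)) {
    if (length(lm[[nm]]) != 3L || !all(is.finite(lm[[nm]])))
      .vm_stop("vm_invalid_landmarks", "landmark '%s' must be 3 finite coordinates", nm)
  }
  mid <- rbind(lm$pev, lm$laminae_intersection, lm$posterior_rim_midpoint)
  n <- .vm_cross(mid[2, ] - mid[1, ], mid[3, ] - mid[1, ])
  scale <- max(.vm_norm(mid[2, ] - mid[1, ]), .vm_norm(mid[3, ] - mid[1, ]), 1)
  if (.vm_norm(n) <= 1e-12 * scale^2)
    .vm_stop("vm_degenerate_landmarks", "midline landmarks are collinear or coincident")
  if (.vm_norm(lm$up_tip_left - lm$up_tip_right) <= 1e-12)
    .vm_stop("vm_invalid_landmarks", "uncinate tips coincide")
  n <- n / .vm_norm(n)
  dl <- sum(n * (lm$up_tip_left - mid[1, ]))
  dr <- sum(n * (lm$up_tip_right - mid[1, ]))
  if (dl * dr >= 0)
    .vm_stop("vm_invalid_landmarks",
             "uncinate tips must lie on opposite sides of the midline plane")
  structure(lm, class = "vm_landmarks")
}

#' @export
print.vm_landmarks <- function(x, ...) {
  cat("Vertebral landmark set (mm):\n")
  for (nm in names(x))
    cat(sprintf("  %-24s % .3f % .3f % .3f\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' Apply a rigid (or general affine) transform to a landmark set
#'
#' @param lm A `vm_landmarks` object.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (mm).
#' @return Transformed `vm_landmarks`.
#' @export
transform_landmarks <- function(lm, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(lm, "vm_landmarks"))
  out <- lapply(unclass(lm), function(p) drop(rotation %*% p) + translation)
  do.call(landmark_set, out)
}
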