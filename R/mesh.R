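#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A `vm_mesh` object.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    .vm_stop("vm_invalid_mesh", "vertices and faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    .vm_stop("vm_invalid_mesh", "face indices out of range")
  if (!all(is.finite(vertices)))
    .vm_stop("vm_invalid_mesh", "non-finite vertex coordinates")
  structure(list(vertices = vertices, faces = faces), class = "vm_mesh")
}

#' @export
print.vm_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("Triangle mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Undirected edge keys "i_j" (i < j) for all face edges, 3 per face.
.vm_mesh_edges <- function(mesh) {
  f <- mesh$faces
  ia <- c(f[, 1], f[, 2], f[, 3])
  ib <- c(f[, 2], f[, 3], f[, 1])
  paste0(pmin(ia, ib), "_", pmax(ia, ib))
}

#' Test whether a mesh is watertight
#'
#' A mesh is watertight (closed 2-manifold) when every undirected edge is
#' shared by exactly two faces.
#'
#' @param mesh A `vm_mesh`.
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "vm_mesh"))
  if (nrow(mesh$faces) == 0) return(FALSE)
  all(table(.vm_mesh_edges(mesh)) == 2L)
}

#' Apply a rigid (or general affine) transform to a mesh
#'
#' @param mesh A `vm_mesh`.
#' @param rotation 3x3 matrix.
#' @param translation Length-3 vector (mm).
#' @return Transformed `vm_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "vm_mesh"))
  triangle_mesh(sweep(mesh$vertices %*% t(rotation), 2, -translation), mesh$faces)
}

# ---- simple analytic meshes (fixtures for slicing checks and examples) ----

#' Axis-aligned box mesh
#'
#' @param min_corner,max_corner Length-3 corners (mm).
#' @return Watertight `vm_mesh` with 12 triangles.
#' @export
mesh_box <- function(min_corner = c(0, 0, 0), max_corner = c(1, 1, 1)) {
  a <- min_corner; b <- max_corner
  v <- rbind(c(a[1], a[2], a[3]), c(b[1], a[2], a[3]), c(b[1], b[2], a[3]), c(a[1], b[2], a[3]),
             c(a[1], a[2], b[3]), c(b[1], a[2], b[3]), c(b[1], b[2], b[3]), c(a[1], b[2], b[3]))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),  # bottom
             c(5, 6, 7), c(5, 7, 8),  # top
             c(1, 2, 6), c(1, 6, 5),
             c(2, 3, 7), c(2, 7, 6),
             c(3, 4, 8), c(3, 8, 7),
             c(4, 1, 5), c(4, 5, 8))
  triangle_mesh(v, f)
}

#' Icosphere mesh
#'
#' Unit-radius sphere by repeated subdivision of an icosahedron, vertices
#' projected onto the sphere.
#'
#' @param subdivisions Number of 4-to-1 subdivisions (0 = icosahedron).
#' @param radius Sphere radius (mm).
#' @param center Length-3 center.
#' @return Watertight `vm_mesh`.
#' @export
mesh_icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste0(min(i, j), "_", max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / .vm_norm(m)
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      mid_cache[[key]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      t1 <- f[k, 1]; t2 <- f[k, 2]; t3 <- f[k, 3]
      a <- midpoint(t1, t2); b <- midpoint(t2, t3); cc <- midpoint(t3, t1)
      nf[(k - 1L) * 4L + 1:4, ] <- rbind(c(t1, a, cc), c(t2, b, a), c(t3, cc, b), c(a, b, cc))
    }
    extra <- do.call(rbind, vlist[-1])
    v <- rbind(v, matrix(extra, ncol = 3))
    f <- nf
  }
  triangle_mesh(sweep(v * radius, 2, -center), f)
}

#' Torus mesh
#'
#' Torus with its symmetry axis along z (the tube circles lie in planes
#' containing the z axis).
#'
#' @param major_radius Distance from axis to tube center (mm).
#' @param minor_radius Tube radius (mm).
#' @param n_major,n_minor Grid resolution.
#' @return Watertight `vm_mesh`.
#' @export
mesh_torus <- function(major_radius = 2, minor_radius = 0.5,
                       n_major = 48, n_minor = 24) {
  th <- seq(0, 2 * pi, length.out = n_major + 1)[-(n_major + 1)]
  ph <- seq(0, 2 * pi, length.out = n_minor + 1)[-(n_minor + 1)]
  g <- expand.grid(ph = ph, th = th)
  r <- major_radius + minor_radius * cos(g$ph)
  v <- cbind(r * cos(g$th), r * sin(g$th), minor_radius * sin(g$ph))
  idx <- function(i, j) ((i - 1L) %% n_major) * n_minor + ((j - 1L) %% n_minor) + 1L
  f <- matrix(0L, 2L * n_major * n_minor, 3L)
  k <- 0L
  for (i in seq_len(n_major)) for (j in seq_len(n_minor)) {
    a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    f[k + 1L, ] <- c(a, b, cc); f[k + 2L, ] <- c(a, cc, d)
    k <- k + 2L
  }
  triangle_mesh(v, f)
}
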