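#' Read a triangle mesh from STL, PLY, or OBJ
#'
#' Format is inferred from the file extension (`.stl`, `.ply`, `.obj`,
#' case-insensitive). STL may be ASCII or binary; PLY must be ASCII; OBJ
#' triangular faces only. Coordinates are taken as millimetres.
#'
#' @param path Path to the mesh file.
#' @return A `vm_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) .vm_stop("vm_io", "mesh file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = .vm_read_stl(path),
         ply = .vm_read_ply(path),
         obj = .vm_read_obj(path),
         .vm_stop("vm_io", "unsupported mesh format '.%s'", ext))
}

#' Write a triangle mesh to STL (ASCII), PLY (ASCII), or OBJ
#'
#' @param mesh A `vm_mesh`.
#' @param path Output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "vm_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = .vm_write_stl(mesh, path),
         ply = .vm_write_ply(mesh, path),
         obj = .vm_write_obj(mesh, path),
         .vm_stop("vm_io", "unsupported mesh format '.%s'", ext))
  invisible(path)
}

.vm_read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 5L)
  close(con)
  if (identical(rawToChar(head), "solid") && .vm_stl_is_ascii(path))
    .vm_read_stl_ascii(path) else .vm_read_stl_binary(path)
}

# A binary STL may also start with "solid"; require the 'facet' keyword.
.vm_stl_is_ascii <- function(path) {
  txt <- readChar(path, nchars = min(file.size(path), 4096L), useBytes = TRUE)
  grepl("facet", txt, fixed = TRUE)
}

.vm_read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  .vm_weld(do.call(rbind, nums))
}

.vm_read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- matrix(readBin(con, "raw", nf * 50L), nrow = 50L)
  coords <- matrix(0, nf * 3L, 3L)
  for (v in 0:2) for (cc in 0:2) {
    off <- 12L + v * 12L + cc * 4L  # skip 12-byte facet normal
    bytes <- as.vector(rec[(off + 1L):(off + 4L), , drop = FALSE])
    coords[seq_len(nf) * 3L - 2L + v, cc + 1L] <-
      readBin(bytes, "numeric", n = nf, size = 4L, endian = "little")
  }
  .vm_weld(coords)
}

# Merge exactly-coincident vertices of a triangle soup into an indexed mesh.
.vm_weld <- function(tri_coords) {
  if (is.null(tri_coords) || nrow(tri_coords) %% 3L != 0L)
    .vm_stop("vm_io", "malformed STL triangle data")
  key <- paste(tri_coords[, 1], tri_coords[, 2], tri_coords[, 3], sep = "|")
  ids <- match(key, unique(key))
  verts <- tri_coords[!duplicated(key), , drop = FALSE]
  triangle_mesh(verts, matrix(ids, ncol = 3L, byrow = TRUE))
}

.vm_write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vertamorph", con)
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]; cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  block <- paste0("facet normal ", fmt(n), "\nouter loop\nvertex ", fmt(a),
                  "\nvertex ", fmt(b), "\nvertex ", fmt(cc), "\nendloop\nendfacet")
  writeLines(block, con)
  writeLines("endsolid vertamorph", con)
}

.vm_read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- strsplit(trimws(grep("^v\\s", lines, value = TRUE)), "\\s+")
  v <- do.call(rbind, lapply(vl, function(x) as.numeric(x[2:4])))
  fl <- strsplit(trimws(grep("^f\\s", lines, value = TRUE)), "\\s+")
  f <- do.call(rbind, lapply(fl, function(x) {
    ix <- as.integer(sub("/.*", "", x[-1]))
    if (length(ix) != 3L) .vm_stop("vm_io", "OBJ reader supports triangular faces only")
    ix
  }))
  triangle_mesh(v, f)
}

.vm_write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

.vm_read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(trimws(lines[1]), "ply")) .vm_stop("vm_io", "not a PLY file")
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) .vm_stop("vm_io", "PLY header not terminated")
  hdr <- lines[seq_len(endh)]
  if (any(grepl("^format\\s+binary", trimws(hdr))))
    .vm_stop("vm_io", "only ASCII PLY is supported")
  nvert <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                          grep("element\\s+vertex", hdr, value = TRUE)[1]))
  nface <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                          grep("element\\s+face", hdr, value = TRUE)[1]))
  body <- lines[(endh + 1L):length(lines)]
  vl <- strsplit(trimws(body[seq_len(nvert)]), "\\s+")
  v <- do.call(rbind, lapply(vl, function(x) as.numeric(x[1:3])))
  fl <- strsplit(trimws(body[nvert + seq_len(nface)]), "\\s+")
  f <- do.call(rbind, lapply(fl, function(x) {
    if (as.integer(x[1]) != 3L) .vm_stop("vm_io", "PLY reader supports triangular faces only")
    as.integer(x[2:4]) + 1L
  }))
  triangle_mesh(v, f)
}

.vm_write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}
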