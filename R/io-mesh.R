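# ASCII mesh I/O: PLY and legacy-VTK POLYDATA subsets sufficient for
# triangulated surfaces. Both are written and parsed here directly (no mesh-IO
# dependency); round-trips are exact to the printed precision.

#' Write a surface as ASCII PLY
#' @param surface a [tri_surface()].
#' @param path output file path.
#' @export
write_ply <- function(surface, path) {
  stopifnot(inherits(surface, "tri_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(surface$vertices); nf <- nrow(surface$triangles)
  writeLines(c("ply", "format ascii 1.0",
               "comment pmjsim endocardial surrogate (mm)",
               sprintf("element vertex %d", nv),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(surface$vertices, 1, function(r)
    sprintf("%.17g %.17g %.17g", r[1], r[2], r[3])), con)
  writeLines(apply(surface$triangles - 1L, 1, function(r)
    sprintf("3 %d %d %d", r[1], r[2], r[3])), con)
  invisible(path)
}

#' Read an ASCII PLY surface
#' @param path file path.
#' @return A [tri_surface()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file")
  hdr_end <- which(lines == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY header not terminated")
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)[1]))
  vlines <- lines[hdr_end + seq_len(nv)]
  flines <- lines[hdr_end + nv + seq_len(nf)]
  V <- matrix(as.numeric(unlist(strsplit(vlines, " ", fixed = TRUE))), nv, 3, byrow = TRUE)
  Fm <- matrix(as.integer(unlist(strsplit(flines, " ", fixed = TRUE))), nf, 4, byrow = TRUE)
  if (any(Fm[, 1] != 3L)) stop("only triangle faces are supported")
  tri_surface(V, Fm[, 2:4] + 1L)
}

#' Write a surface as legacy ASCII VTK POLYDATA
#' @param surface a [tri_surface()].
#' @param path output file path.
#' @export
write_vtk <- function(surface, path) {
  stopifnot(inherits(surface, "tri_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(surface$vertices); nf <- nrow(surface$triangles)
  writeLines(c("# vtk DataFile Version 3.0",
               "pmjsim endocardial surrogate (mm)", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nv)), con)
  writeLines(apply(surface$vertices, 1, function(r)
    sprintf("%.17g %.17g %.17g", r[1], r[2], r[3])), con)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(apply(surface$triangles - 1L, 1, function(r)
    sprintf("3 %d %d %d", r[1], r[2], r[3])), con)
  invisible(path)
}

#' Read a legacy ASCII VTK POLYDATA surface
#' @param path file path.
#' @return A [tri_surface()].
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS ", lines)[1]
  if (is.na(ip)) stop("no POINTS section")
  nv <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  # points may span several lines; collect numbers until 3*nv read
  vals <- numeric(0)
  i <- ip
  while (length(vals) < 3L * nv) {
    i <- i + 1L
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), " +")[[1]]))
  }
  V <- matrix(vals[seq_len(3L * nv)], nv, 3, byrow = TRUE)
  ig <- grep("^POLYGONS ", lines)[1]
  nf <- as.integer(strsplit(lines[ig], " +")[[1]][2])
  fvals <- integer(0)
  i <- ig
  while (length(fvals) < 4L * nf) {
    i <- i + 1L
    fvals <- c(fvals, as.integer(strsplit(trimws(lines[i]), " +")[[1]]))
  }
  Fm <- matrix(fvals[seq_len(4L * nf)], nf, 4, byrow = TRUE)
  if (any(Fm[, 1] != 3L)) stop("only triangle polygons are supported")
  tri_surface(V, Fm[, 2:4] + 1L)
}
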