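#' Triangulated surface
#'
#' Container for a triangulated surface used as an endocardial surrogate on
#' which Purkinje trees are grown. Vertex positions are in mm; the total area
#' is reported in cm^2 to match PMJ-density units (PMJs/cm^2).
#'
#' @param vertices numeric matrix (n x 3) of vertex positions in mm.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices with
#'   consistent outward winding.
#' @return An object of class `tri_surface` with fields `vertices`,
#'   `triangles`, `triangle_areas_mm2` and `area_cm2` (sum of triangle areas).
#' @export
tri_surface <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (nrow(triangles) < 1L) stop("surface has no triangles")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  if (!all(seq_len(nrow(vertices)) %in% as.vector(triangles)))
    stop("every vertex must be referenced by at least one triangle")
  areas <- triangle_areas(vertices, triangles)
  if (any(areas <= 0)) stop("degenerate triangle with non-positive area")
  structure(
    list(vertices = vertices, triangles = triangles,
         triangle_areas_mm2 = areas, area_cm2 = sum(areas) / 100,
         centroids = tri_centroids(vertices, triangles),
         circumradius = tri_circumradius(vertices, triangles)),
    class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("tri_surface: %d vertices, %d triangles, area %.3f cm^2\n",
              nrow(x$vertices), nrow(x$triangles), x$area_cm2))
  invisible(x)
}

triangle_areas <- function(V, Tm) {
  a <- V[Tm[, 1], , drop = FALSE]
  ab <- V[Tm[, 2], , drop = FALSE] - a
  ac <- V[Tm[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

tri_centroids <- function(V, Tm) {
  (V[Tm[, 1], , drop = FALSE] + V[Tm[, 2], , drop = FALSE] +
     V[Tm[, 3], , drop = FALSE]) / 3
}

tri_circumradius <- function(V, Tm) {
  cen <- tri_centroids(V, Tm)
  d1 <- sqrt(rowSums((V[Tm[, 1], , drop = FALSE] - cen)^2))
  d2 <- sqrt(rowSums((V[Tm[, 2], , drop = FALSE] - cen)^2))
  d3 <- sqrt(rowSums((V[Tm[, 3], , drop = FALSE] - cen)^2))
  pmax(d1, d2, d3)
}

# Ramanujan approximation to an ellipse perimeter.
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Hemi-ellipsoid endocardial surrogate surface
#'
#' Builds a triangulated hemi-ellipsoid dome (apex at +z, rim on the z = 0
#' equator) by latitude rings spaced at approximately equal meridian arc
#' length, with ring resolution chosen so that edge lengths track
#' `target_edge`. Every vertex lies exactly on the ellipsoid
#' (x/a)^2 + (y/b)^2 + (z/c)^2 = 1; triangle winding is outward.
#'
#' @param semi_axes numeric length-3, the (a, b, c) semi-axes in mm; all > 0.
#' @param target_edge target mean edge length in mm; must be smaller than
#'   `min(semi_axes) / 4`.
#' @param seed integer seed controlling the (deterministic) azimuthal phase of
#'   each ring, so repeated calls with the same seed are bit-identical.
#' @return A [tri_surface()].
#' @export
make_hemiellipsoid_surface <- function(semi_axes, target_edge, seed = 1L) {
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("semi_axes must be three positive lengths (mm)")
  if (!is.finite(target_edge) || target_edge <= 0)
    stop("target_edge must be positive")
  if (target_edge >= min(semi_axes) / 4)
    stop("target_edge must be smaller than min(semi_axes)/4")
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]

  # Meridian arc length from apex (theta = 0) to equator, using the mean
  # horizontal semi-axis; equal-arc theta spacing via numeric inversion.
  m <- (a + b) / 2
  th_fine <- seq(0, pi / 2, length.out = 4001)
  ds <- sqrt((m * cos(th_fine))^2 + (cc * sin(th_fine))^2)
  s_cum <- c(0, cumsum((ds[-1] + ds[-length(ds)]) / 2 * diff(th_fine)))
  L <- s_cum[length(s_cum)]
  n_rings <- max(3L, as.integer(round(L / target_edge)))
  s_targets <- seq_len(n_rings) / n_rings * L
  thetas <- approx(s_cum, th_fine, xout = s_targets, ties = "ordered")$y

  with_seed(seed, {
    verts <- list(c(0, 0, cc))   # apex
    ring_idx <- vector("list", n_rings)
    ring_ang <- vector("list", n_rings)
    n_v <- 1L
    for (i in seq_len(n_rings)) {
      th <- thetas[i]
      per <- ellipse_perimeter(a * sin(th), b * sin(th))
      mi <- max(6L, as.integer(round(per / target_edge)))
      phi0 <- runif(1, 0, 2 * pi / mi)
      phi <- phi0 + 2 * pi * (seq_len(mi) - 1L) / mi
      verts[[i + 1L]] <- cbind(a * sin(th) * cos(phi),
                               b * sin(th) * sin(phi),
                               cc * cos(th))
      ring_idx[[i]] <- n_v + seq_len(mi)
      ring_ang[[i]] <- phi %% (2 * pi)
      n_v <- n_v + mi
    }
    V <- do.call(rbind, c(list(matrix(verts[[1]], 1, 3)), verts[-1]))

    tris <- list()
    # apex fan to ring 1
    r1 <- ring_idx[[1]]
    m1 <- length(r1)
    tris[[1]] <- cbind(1L, r1, r1[c(2:m1, 1L)])
    for (i in seq_len(n_rings - 1L)) {
      tris[[i + 1L]] <- stitch_rings(ring_idx[[i]], ring_ang[[i]],
                                     ring_idx[[i + 1L]], ring_ang[[i + 1L]])
    }
    Tm <- do.call(rbind, tris)
    storage.mode(Tm) <- "integer"

    # Orient all triangles outward: the outward normal at a point p on the
    # ellipsoid is parallel to (x/a^2, y/b^2, z/c^2), whose dot product with a
    # correctly wound face normal is positive.
    A <- V[Tm[, 1], , drop = FALSE]
    e1 <- V[Tm[, 2], , drop = FALSE] - A
    e2 <- V[Tm[, 3], , drop = FALSE] - A
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    cen <- (A + V[Tm[, 2], , drop = FALSE] + V[Tm[, 3], , drop = FALSE]) / 3
    grad <- cbind(cen[, 1] / a^2, cen[, 2] / b^2, cen[, 3] / cc^2)
    flip <- rowSums(nrm * grad) < 0
    if (any(flip)) Tm[flip, 2:3] <- Tm[flip, 3:2]

    tri_surface(V, Tm)
  })
}

# Stitch two adjacent latitude rings (given vertex ids and azimuthal angles)
# into a triangle strip, advancing around whichever ring has the smaller next
# unwrapped angle. Produces length(u) + length(w) triangles.
stitch_rings <- function(idx_u, ang_u, idx_w, ang_w) {
  mu <- length(idx_u); mw <- length(idx_w)
  # rotate each ring to start at its smallest angle, then unwrap
  ou <- order(ang_u); idx_u <- idx_u[ou]; ang_u <- ang_u[ou]
  ow <- order(ang_w); idx_w <- idx_w[ow]; ang_w <- ang_w[ow]
  # align ring w start to the first vertex counter-clockwise of u's start
  d0 <- (ang_w - ang_u[1]) %% (2 * pi)
  k0 <- which.min(d0)
  rot <- function(x, k) if (k == 1L) x else c(x[k:length(x)], x[seq_len(k - 1L)])
  idx_w <- rot(idx_w, k0); ang_w <- rot(ang_w, k0)
  # unwrapped angle sequences, closed by first + 2*pi
  au <- ang_u - ang_u[1]; au <- au %% (2 * pi); au <- cummax_unwrap(au)
  aw <- ang_w - ang_u[1]; aw <- aw %% (2 * pi); aw <- cummax_unwrap(aw)
  au_next <- c(au[-1], au[1] + 2 * pi)
  aw_next <- c(aw[-1], aw[1] + 2 * pi)

  tris <- matrix(0L, mu + mw, 3)
  iu <- 1L; iw <- 1L; cu <- 0L; cw <- 0L; k <- 0L
  while (cu < mu || cw < mw) {
    k <- k + 1L
    adv_u <- if (cu >= mu) FALSE
    else if (cw >= mw) TRUE
    else au_next[iu] <= aw_next[iw]
    if (adv_u) {
      ju <- iu %% mu + 1L
      tris[k, ] <- c(idx_u[iu], idx_w[iw], idx_u[ju])
      iu <- ju; cu <- cu + 1L
    } else {
      jw <- iw %% mw + 1L
      tris[k, ] <- c(idx_u[iu], idx_w[iw], idx_w[jw])
      iw <- jw; cw <- cw + 1L
    }
  }
  tris[seq_len(k), , drop = FALSE]
}

# Monotone unwrap of angles in [0, 2*pi) that may wrap once.
cummax_unwrap <- function(a) {
  out <- a
  add <- 0
  for (i in seq_along(a)[-1]) {
    if (a[i] + add < out[i - 1]) add <- add + 2 * pi
    out[i] <- a[i] + add
  }
  out
}

#' Excitable tissue sheet specification
#'
#' @param nx,ny grid dimensions (>= 16).
#' @param dx grid spacing in mm.
#' @param diffusivity scalar diffusion coefficient in mm^2/ms.
#' @return Object of class `tissue_sheet` with derived `area_cm2 =
#'   nx * ny * dx^2 / 100`.
#' @export
tissue_sheet <- function(nx = 256L, ny = 256L, dx = 0.25, diffusivity = 0.05) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 16L || ny < 16L) stop("nx and ny must both be >= 16")
  if (!is.finite(dx) || dx <= 0) stop("dx must be positive")
  if (!is.finite(diffusivity) || diffusivity <= 0) stop("diffusivity must be positive")
  structure(list(nx = nx, ny = ny, dx = dx, diffusivity = diffusivity,
                 area_cm2 = nx * ny * dx^2 / 100),
            class = "tissue_sheet")
}

#' @export
print.tissue_sheet <- function(x, ...) {
  cat(sprintf("tissue_sheet: %d x %d, dx = %g mm (%.2f cm^2), D = %g mm^2/ms\n",
              x$nx, x$ny, x$dx, x$area_cm2, x$diffusivity))
  invisible(x)
}
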