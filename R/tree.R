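# Fractal Purkinje network growth on a triangulated surface, and PMJ
# placement at a controllable density.

# Vectorized closest point on a set of triangles (Eberly's region
# decomposition of the quadratic distance over the (s, t) parameter domain).
# p: length-3 point; V0, V1, V2: m x 3 matrices of triangle corners.
# Returns list(points = m x 3 closest points, dist2 = squared distances).
closest_on_triangles <- function(p, V0, V1, V2) {
  E0 <- V1 - V0
  E1 <- V2 - V0
  D <- sweep(V0, 2, p)          # V0 - p
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); cc <- rowSums(E1 * E1)
  d <- rowSums(E0 * D);  e <- rowSums(E1 * D)
  det <- pmax(a * cc - b * b, 1e-300)
  s <- b * e - cc * d
  t <- b * d - a * e
  clamp01 <- function(x) pmin(1, pmax(0, x))
  m <- length(a)
  S <- numeric(m); Tt <- numeric(m)

  inside <- s + t <= det
  r0 <- inside & s >= 0 & t >= 0
  r3 <- inside & s < 0 & t >= 0
  r4 <- inside & s < 0 & t < 0
  r5 <- inside & s >= 0 & t < 0
  r1 <- !inside & s >= 0 & t >= 0
  r2 <- !inside & s < 0
  r6 <- !inside & s >= 0 & t < 0

  if (any(r0)) { S[r0] <- s[r0] / det[r0]; Tt[r0] <- t[r0] / det[r0] }
  if (any(r3)) { S[r3] <- 0; Tt[r3] <- clamp01(-e[r3] / cc[r3]) }
  if (any(r5)) { Tt[r5] <- 0; S[r5] <- clamp01(-d[r5] / a[r5]) }
  if (any(r4)) {
    use_s <- d[r4] < 0
    S4 <- ifelse(use_s, clamp01(-d[r4] / a[r4]), 0)
    T4 <- ifelse(use_s, 0, clamp01(-e[r4] / cc[r4]))
    S[r4] <- S4; Tt[r4] <- T4
  }
  if (any(r1)) {
    numer <- cc[r1] + e[r1] - b[r1] - d[r1]
    denom <- a[r1] - 2 * b[r1] + cc[r1]
    S1 <- ifelse(numer <= 0, 0, clamp01(numer / pmax(denom, 1e-300)))
    S[r1] <- S1; Tt[r1] <- 1 - S1
  }
  if (any(r2)) {
    tmp0 <- b[r2] + d[r2]; tmp1 <- cc[r2] + e[r2]
    edge <- tmp1 > tmp0
    numer <- tmp1 - tmp0
    denom <- a[r2] - 2 * b[r2] + cc[r2]
    S2 <- ifelse(edge, clamp01(numer / pmax(denom, 1e-300)), 0)
    T2 <- ifelse(edge, 1 - S2, clamp01(-e[r2] / cc[r2]))
    S[r2] <- S2; Tt[r2] <- T2
  }
  if (any(r6)) {
    tmp0 <- b[r6] + e[r6]; tmp1 <- a[r6] + d[r6]
    edge <- tmp1 > tmp0
    numer <- tmp1 - tmp0
    denom <- a[r6] - 2 * b[r6] + cc[r6]
    T6 <- ifelse(edge, clamp01(numer / pmax(denom, 1e-300)), 0)
    S6 <- ifelse(edge, 1 - T6, clamp01(-d[r6] / a[r6]))
    S[r6] <- S6; Tt[r6] <- T6
  }
  pts <- V0 + E0 * S + E1 * Tt
  dif <- sweep(pts, 2, p)
  list(points = pts, dist2 = rowSums(dif * dif))
}

#' Project a point onto the closest triangle of a surface
#'
#' Exact closest-point projection over the union of all triangles, with a
#' centroid-radius prefilter for speed (the filter is conservative, so the
#' result equals the brute-force minimum). Ties at exact equidistance go to
#' the lowest triangle index.
#'
#' @param surface a [tri_surface()].
#' @param p length-3 numeric point (mm).
#' @return List with `point` (closest point, mm), `triangle` (1-based index)
#'   and `distance` (mm).
#' @export
project_point_to_surface <- function(surface, p) {
  stopifnot(inherits(surface, "tri_surface"), length(p) == 3L)
  cen <- surface$centroids
  rad <- surface$circumradius
  dc <- sqrt(rowSums(sweep(cen, 2, p)^2))
  ub <- min(dc + rad)                    # attainable upper bound on min dist
  cand <- which(dc - rad <= ub)          # cannot exclude the true minimizer
  V <- surface$vertices; Tm <- surface$triangles
  res <- closest_on_triangles(p,
                              V[Tm[cand, 1], , drop = FALSE],
                              V[Tm[cand, 2], , drop = FALSE],
                              V[Tm[cand, 3], , drop = FALSE])
  i <- which.min(res$dist2)              # candidates ascend, so first = lowest id
  list(point = as.numeric(res$points[i, ]), triangle = cand[i],
       distance = sqrt(res$dist2[i]))
}

tri_normal <- function(surface, tri_id) {
  Tm <- surface$triangles[tri_id, ]
  V <- surface$vertices
  unit(cross3(V[Tm[2], ] - V[Tm[1], ], V[Tm[3], ] - V[Tm[1], ]))
}

#' Growth rule for the fractal Purkinje tree
#'
#' Parallel rewriting rule: at each iteration every open tip sprouts
#' `daughters_per_tip` branches at `+/- branch_half_angle` (plus Gaussian
#' jitter) in the local tangent plane; each branch is `segments_per_branch`
#' straight segments of total length `branch_length`, re-projected onto the
#' surface segment by segment so branches follow the curvature.
#'
#' @param branch_length total branch length in mm (default 2).
#' @param segments_per_branch segments per branch (default 5).
#' @param daughters_per_tip branches sprouted per tip (default 2).
#' @param branch_half_angle degrees, in (0, 90) (default 40).
#' @param jitter_sd Gaussian angular jitter s.d. in degrees (default 8).
#' @param iterations number of rewriting iterations.
#' @param rng_seed integer seed; identical seed + rule gives a bit-identical
#'   network.
#' @param foldback_reject drop a branch whose tip ends within
#'   `0.5 * branch_length` of its grandparent node (projection fold-back).
#' @return Object of class `growth_rule`.
#' @export
growth_rule <- function(branch_length = 2, segments_per_branch = 5L,
                        daughters_per_tip = 2L, branch_half_angle = 40,
                        jitter_sd = 8, iterations = 5L, rng_seed = 1L,
                        foldback_reject = TRUE) {
  if (branch_length <= 0) stop("branch_length must be positive")
  if (segments_per_branch < 1L) stop("segments_per_branch must be >= 1")
  if (branch_half_angle <= 0 || branch_half_angle >= 90)
    stop("branch_half_angle must be in (0, 90) degrees")
  if (daughters_per_tip < 1L) stop("daughters_per_tip must be >= 1")
  structure(list(branch_length = branch_length,
                 segments_per_branch = as.integer(segments_per_branch),
                 daughters_per_tip = as.integer(daughters_per_tip),
                 branch_half_angle = branch_half_angle,
                 jitter_sd = jitter_sd,
                 iterations = as.integer(iterations),
                 rng_seed = as.integer(rng_seed),
                 foldback_reject = isTRUE(foldback_reject)),
            class = "growth_rule")
}

#' Grow a fractal Purkinje network on a surface
#'
#' @param surface a [tri_surface()].
#' @param seed_points numeric matrix (k x 3) of starting positions (mm);
#'   projected onto the surface before growth. Must be non-empty.
#' @param rule a [growth_rule()].
#' @return Object of class `purkinje_network` with `nodes` (n x 3, mm),
#'   `on_surface`, `grown` (logical: created by rewriting, not a seed),
#'   `edges` (data.frame n1, n2, length_mm), `roots`, `terminals`.
#' @export
grow_network <- function(surface, seed_points, rule = growth_rule()) {
  stopifnot(inherits(surface, "tri_surface"), inherits(rule, "growth_rule"))
  seed_points <- matrix(as.numeric(seed_points), ncol = 3)
  if (nrow(seed_points) == 0L) stop("seed point set must be non-empty")

  seg_len <- rule$branch_length / rule$segments_per_branch
  nodes <- list(); n_nodes <- 0L
  edges_n1 <- integer(0); edges_n2 <- integer(0); edges_len <- numeric(0)
  grown <- logical(0)

  with_seed(rule$rng_seed, {
    tips <- list()
    for (si in seq_len(nrow(seed_points))) {
      pr <- project_point_to_surface(surface, seed_points[si, ])
      n_nodes <- n_nodes + 1L
      nodes[[n_nodes]] <- pr$point
      grown[n_nodes] <- FALSE
      nrm <- tri_normal(surface, pr$triangle)
      # random initial tangent direction
      ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      t1 <- unit(ref - sum(ref * nrm) * nrm)
      dir0 <- rotate_about(t1, nrm, runif(1, 0, 2 * pi))
      tips[[length(tips) + 1L]] <- list(node = n_nodes, pos = pr$point,
                                        dir = dir0, normal = nrm,
                                        grandparent = NULL)
    }
    roots <- seq_len(nrow(seed_points))

    if (rule$iterations > 0L) for (it in seq_len(rule$iterations)) {
      new_tips <- list()
      for (tip in tips) {
        base_angles <- rule$branch_half_angle *
          (if (rule$daughters_per_tip == 1L) 0
           else seq(-1, 1, length.out = rule$daughters_per_tip))
        for (dgt in seq_len(rule$daughters_per_tip)) {
          ang <- (base_angles[dgt] + rnorm(1, 0, rule$jitter_sd)) * pi / 180
          dirc <- rotate_about(tip$dir, tip$normal, ang)
          dirc <- unit(dirc - sum(dirc * tip$normal) * tip$normal)
          p <- tip$pos
          br_pos <- matrix(0, rule$segments_per_branch, 3)
          br_nrm <- tip$normal
          for (s in seq_len(rule$segments_per_branch)) {
            praw <- p + seg_len * dirc
            pr <- project_point_to_surface(surface, praw)
            step <- pr$point - p
            if (vnorm(step) > 1e-9) dirc <- step / vnorm(step)
            br_pos[s, ] <- pr$point
            br_nrm <- tri_normal(surface, pr$triangle)
            p <- pr$point
          }
          if (rule$foldback_reject && !is.null(tip$grandparent) &&
              vnorm(p - tip$grandparent) < 0.5 * rule$branch_length)
            next  # reject folded-back branch; tip stays closed
          prev <- tip$node
          for (s in seq_len(rule$segments_per_branch)) {
            n_nodes <- n_nodes + 1L
            nodes[[n_nodes]] <- br_pos[s, ]
            grown[n_nodes] <- TRUE
            edges_n1 <- c(edges_n1, prev)
            edges_n2 <- c(edges_n2, n_nodes)
            prev <- n_nodes
          }
          new_tips[[length(new_tips) + 1L]] <-
            list(node = n_nodes, pos = p, dir = dirc, normal = br_nrm,
                 grandparent = tip$pos)
        }
      }
      tips <- new_tips
    }
  })

  pos <- do.call(rbind, nodes)
  edges_len <- sqrt(rowSums((pos[edges_n2, , drop = FALSE] -
                               pos[edges_n1, , drop = FALSE])^2))
  deg <- tabulate(c(edges_n1, edges_n2), nbins = n_nodes)
  roots <- which(!grown)
  terminals <- setdiff(which(deg == 1L), roots)
  structure(list(nodes = pos,
                 on_surface = rep(TRUE, n_nodes),
                 grown = grown,
                 edges = data.frame(n1 = edges_n1, n2 = edges_n2,
                                    length_mm = edges_len),
                 roots = roots, terminals = terminals,
                 rule = rule),
            class = "purkinje_network")
}

#' @export
print.purkinje_network <- function(x, ...) {
  cat(sprintf("purkinje_network: %d nodes, %d edges, %d roots, %d terminals\n",
              nrow(x$nodes), nrow(x$edges), length(x$roots), length(x$terminals)))
  invisible(x)
}

#' Place PMJs on the grown branches of a network
#'
#' Seeded farthest-point (maximin) traversal over the grown-branch nodes: the
#' first site is drawn at random, each subsequent site is the candidate
#' farthest from all chosen sites, and selection stops when that farthest
#' distance drops below `min_distance`. All selected pairs are therefore
#' `>= min_distance` apart, and a smaller `min_distance` always yields a
#' superset of the sites chosen at a larger one under the same seed.
#'
#' @param network a [purkinje_network()].
#' @param min_distance minimum pairwise Euclidean distance between PMJ sites
#'   (mm, >= 0; 0 selects every candidate).
#' @param rng_seed integer seed for the starting site.
#' @param r_pmj,loading_factor junctional resistance (MOhm) and loading
#'   factor recorded on each PMJ.
#' @param insertion_depth_fraction carried as metadata (the 2D sheet has no
#'   wall-depth analog); in `[0, 1]`.
#' @return Object of class `pmj_set`: data.frame `pmjs` (terminal_id, r_pmj,
#'   loading_factor), `coupled` (list of myocardial node ids, filled when the
#'   network is coupled to a sheet), plus the placement metadata.
#' @export
place_pmjs <- function(network, min_distance, rng_seed = 1L,
                       r_pmj = 20, loading_factor = 20,
                       insertion_depth_fraction = 0.2) {
  stopifnot(inherits(network, "purkinje_network"))
  if (!is.finite(min_distance) || min_distance < 0)
    stop("min_distance must be >= 0")
  if (insertion_depth_fraction < 0 || insertion_depth_fraction > 1)
    stop("insertion_depth_fraction must be in [0, 1]")
  cand <- which(network$grown)
  if (length(cand) == 0L) stop("network has no grown-branch candidate nodes")
  P <- network$nodes[cand, , drop = FALSE]

  sel_local <- with_seed(rng_seed, {
    if (min_distance == 0) {
      seq_along(cand)
    } else {
      start <- sample.int(length(cand), 1L)
      chosen <- start
      dmin <- sqrt(rowSums(sweep(P, 2, P[start, ])^2))
      repeat {
        i <- which.max(dmin)
        if (dmin[i] < min_distance) break
        chosen <- c(chosen, i)
        dmin <- pmin(dmin, sqrt(rowSums(sweep(P, 2, P[i, ])^2)))
      }
      chosen
    }
  })
  ids <- cand[sel_local]
  structure(list(pmjs = data.frame(terminal_id = ids,
                                   r_pmj = rep(r_pmj, length(ids)),
                                   loading_factor = rep(loading_factor, length(ids))),
                 coupled = rep(list(integer(0)), length(ids)),
                 min_distance = min_distance,
                 rng_seed = as.integer(rng_seed),
                 insertion_depth_fraction = insertion_depth_fraction),
            class = "pmj_set")
}

#' @export
print.pmj_set <- function(x, ...) {
  cat(sprintf("pmj_set: %d PMJs (min_distance = %g mm)\n",
              nrow(x$pmjs), x$min_distance))
  invisible(x)
}

#' PMJ density
#'
#' @param n_pmjs PMJ count.
#' @param area surface area in cm^2 (> 0).
#' @return Density in PMJs/cm^2.
#' @export
pmj_density <- function(n_pmjs, area) {
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  n_pmjs / area
}
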