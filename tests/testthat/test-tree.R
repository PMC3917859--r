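# Purkinje tree growth, projection and PMJ placement.

test_that("projection returns a vertex when queried at that vertex", {
  s <- fix_sphere()
  v <- s$vertices[17, ]
  pr <- project_point_to_surface(s, v)
  expect_equal(pr$point, unname(v), tolerance = 1e-12)
  expect_lt(pr$distance, 1e-12)
})

test_that("projection above a triangle interior drops the perpendicular", {
  # a single triangle in the z = 0 plane
  s <- tri_surface(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)),
                   rbind(c(1L, 2L, 3L)))
  pr <- project_point_to_surface(s, c(1, 1, 2.5))
  expect_equal(pr$point, c(1, 1, 0), tolerance = 1e-12)
  expect_equal(pr$distance, 2.5, tolerance = 1e-12)
})

test_that("projection equals the exhaustive per-triangle minimum", {
  s <- fix_sphere()
  V <- s$vertices; Tm <- s$triangles
  brute <- function(p) {
    res <- pmjsim:::closest_on_triangles(p, V[Tm[, 1], ], V[Tm[, 2], ],
                                         V[Tm[, 3], ])
    sqrt(min(res$dist2))
  }
  withr::with_seed(4, {
    for (i in 1:200) {
      p <- runif(3, -14, 14)
      pr <- project_point_to_surface(s, p)
      expect_equal(pr$distance, brute(p), tolerance = 1e-9)
    }
  })
})

test_that("zero iterations yields only the seed nodes", {
  net <- grow_network(fix_sphere(), fix_seed_points(),
                      growth_rule(iterations = 0, rng_seed = 1))
  expect_identical(nrow(net$nodes), 4L)
  expect_identical(nrow(net$edges), 0L)
  expect_identical(net$roots, 1:4)
})

test_that("one binary iteration follows the rewriting rule counts", {
  net <- grow_network(fix_sphere(), fix_seed_points()[1, , drop = FALSE],
                      growth_rule(iterations = 1, rng_seed = 2))
  # 2 branches x 5 segments: 10 new edges, 10 new nodes, 2 terminals
  expect_identical(nrow(net$edges), 10L)
  expect_identical(nrow(net$nodes), 11L)
  expect_identical(length(net$terminals), 2L)
  # each branch path length within 10% of the 2 mm branch length
  for (term in net$terminals) {
    # walk back to the root summing edge lengths
    len <- 0; node <- term
    repeat {
      e <- which(net$edges$n2 == node)
      if (length(e) == 0L) break
      len <- len + net$edges$length_mm[e]
      node <- net$edges$n1[e]
    }
    expect_lt(abs(len - 2), 0.2)
  }
})

test_that("growth is deterministic and keeps nodes on the surface", {
  a <- grow_network(fix_sphere(), fix_seed_points(),
                    growth_rule(iterations = 3, rng_seed = 13))
  b <- grow_network(fix_sphere(), fix_seed_points(),
                    growth_rule(iterations = 3, rng_seed = 13))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  s <- fix_sphere()
  dmax <- max(vapply(seq_len(nrow(a$nodes)), function(i)
    project_point_to_surface(s, a$nodes[i, ])$distance, numeric(1)))
  expect_lt(dmax, 0.01)
  # segment lengths near branch_length / segments_per_branch
  expect_true(all(abs(a$edges$length_mm - 0.4) < 0.1))
})

test_that("empty seed set is rejected", {
  expect_error(grow_network(fix_sphere(), matrix(numeric(0), 0, 3)),
               "non-empty")
})

test_that("PMJ placement respects the minimum distance (brute force)", {
  net <- fix_network()
  for (md in c(1.5, 3, 6)) {
    pm <- place_pmjs(net, md, rng_seed = 21)
    P <- net$nodes[pm$pmjs$terminal_id, , drop = FALSE]
    if (nrow(P) > 1) {
      dmin <- min(dist(P))
      expect_gte(dmin, md)
    }
  }
})

test_that("PMJ count decreases monotonically with min_distance", {
  net <- fix_network()
  mds <- c(0.5, 1, 1.5, 2, 3, 4, 6)
  counts <- vapply(mds, function(md)
    nrow(place_pmjs(net, md, rng_seed = 8)$pmjs), numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("PMJ placement edge cases behave as specified", {
  net <- fix_network()
  # distance beyond the network diameter forces a single PMJ
  pm1 <- place_pmjs(net, 100, rng_seed = 3)
  expect_identical(nrow(pm1$pmjs), 1L)
  # zero distance selects every grown candidate
  pm0 <- place_pmjs(net, 0, rng_seed = 3)
  expect_identical(nrow(pm0$pmjs), sum(net$grown))
  expect_error(place_pmjs(net, -1), ">= 0")
  # determinism
  a <- place_pmjs(net, 2, rng_seed = 17)
  b <- place_pmjs(net, 2, rng_seed = 17)
  expect_identical(a$pmjs, b$pmjs)
})

test_that("PMJ density follows the count / area arithmetic", {
  expect_equal(pmj_density(74, 16.57), 4.46, tolerance = 0.01 / 4.46)
  expect_equal(pmj_density(516, 16.57), 31.14, tolerance = 0.01 / 31.14)
  expect_identical(pmj_density(0, 10), 0)
  expect_error(pmj_density(10, 0), "positive")
})
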