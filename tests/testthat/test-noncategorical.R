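test_that("discrete metric bridges RQE to the Gini-Simpson index", {
  expect_equal(discrete_metric(1), matrix(0, 1, 1, dimnames = list("1", "1")))
  d3 <- discrete_metric(3)
  expect_true(all(d3[upper.tri(d3)] == 1) && all(diag(d3) == 0))

  set.seed(71)
  for (i in 1:200) {
    p <- random_abundance(sample(2:50, 1))
    expect_lt(abs(rao_quadratic_entropy(discrete_metric(length(p)), p) -
                    gini_simpson(p)), 1e-12)
  }
})

test_that("set and binary distances match their definitions", {
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(1:3, 4:6), 1)
  expect_equal(jaccard_distance(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_error(jaccard_distance(integer(0), integer(0)),
               class = "renyihet_invalid_input")

  expect_equal(hamming_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(hamming_distance(c(1, 0, 1, 1), c(0, 1, 0, 0)), 4)
  expect_equal(hamming_distance(c(1, 0, 1), c(0, 1, 1)), 2)
  expect_error(hamming_distance(c(1, 0), c(1, 0, 1)),
               class = "renyihet_invalid_input")
})

test_that("profile distance matrices agree with pairwise evaluation", {
  pats <- c("110", "011", "000")
  dh <- profile_distances(pats, metric = "hamming")
  expect_equal(dh["110", "011"], 2)
  expect_equal(dh["110", "000"], 2)
  dj <- profile_distances(c("110", "011"), metric = "jaccard")
  expect_equal(dj["110", "011"], 1 - 1 / 3)
  # two all-zero profiles have no defined Jaccard distance
  expect_error(profile_distances(c("000", "000", "100")),
               class = "renyihet_invalid_input")
})

test_that("RQE is bilinear in the metric and permutation-invariant", {
  set.seed(73)
  p <- random_abundance(6)
  d <- as.matrix(stats::dist(matrix(rnorm(12), 6)))
  q0 <- rao_quadratic_entropy(d, p)
  expect_equal(rao_quadratic_entropy(3.5 * d, p), 3.5 * q0, tolerance = 1e-12)
  expect_equal(rao_quadratic_entropy(d, c(1, 0, 0, 0, 0, 0)), 0)

  perm <- sample(6)
  p_perm <- abundance_vector(as.numeric(p)[perm], labels = names(p)[perm])
  expect_equal(rao_quadratic_entropy(d[perm, perm], p_perm),
               q0, tolerance = 1e-12)
  expect_error(rao_quadratic_entropy(d[1:5, 1:5], p),
               class = "renyihet_invalid_input")
})

test_that("functional Hill numbers calibrate but ignore distances at uniformity", {
  # calibration: uniform abundance, constant distances
  expect_equal(functional_hill_number(discrete_metric(4), rep(0.25, 4), 2), 4,
               tolerance = 1e-9)
  expect_equal(functional_hill_number(discrete_metric(5), rep(0.2, 5), 0), 5,
               tolerance = 1e-9)
  # perfect conformity
  expect_equal(functional_hill_number(discrete_metric(3), c(1, 0, 0), 2), 1)

  # the insensitivity critique: any distance structure with uniform
  # abundance collapses to the category count
  set.seed(79)
  d_het <- as.matrix(stats::dist(matrix(rnorm(8), 4)))
  d_const <- discrete_metric(4) * mean(d_het[upper.tri(d_het)])
  for (q in c(0, 0.5, 2)) {
    expect_equal(functional_hill_number(d_het, rep(0.25, 4), q),
                 functional_hill_number(d_const, rep(0.25, 4), q),
                 tolerance = 1e-9)
  }
  # q = 1 limit is continuous
  p <- random_abundance(4)
  expect_lt(abs(functional_hill_number(d_het, p, 1) -
                  functional_hill_number(d_het, p, 1 + 1e-7)), 1e-3)
})

test_that("convex hulls measure extreme points, not density", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(as.numeric(convex_hull_volume(sq)), 1)

  # interior points leave the hull unchanged
  set.seed(83)
  interior <- cbind(runif(50, 0.1, 0.9), runif(50, 0.1, 0.9))
  expect_equal(as.numeric(convex_hull_volume(rbind(sq, interior))), 1)

  # an outlier inflates the hull although the data density is unchanged
  expect_gt(as.numeric(convex_hull_volume(rbind(sq, interior, c(10, 10)))), 1)

  # 1-D: range length
  expect_equal(as.numeric(convex_hull_volume(cbind(c(0, 0.2, 1)))), 1)

  # degenerate (collinear) clouds are flagged
  expect_warning(v <- convex_hull_volume(cbind(1:5, 2 * (1:5))), "degenerate")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "degenerate"))

  expect_error(convex_hull_volume(rbind(c(0, 0), c(1, 1))),
               class = "renyihet_invalid_input")
  expect_error(convex_hull_volume(matrix(rnorm(30), 10, 3)),
               class = "renyihet_invalid_parameter")
})

test_that("dendrogram functional diversity sums branch lengths", {
  # two leaves at distance 3: two branches of 1.5
  expect_equal(dendrogram_fd(rbind(c(0, 3), c(3, 0))), 3)

  # duplicated points merge at height zero and add no branch length
  # (under single linkage later merge heights are also unaffected)
  pts <- rbind(c(0, 0), c(1, 0), c(0.2, 0.8))
  d <- as.matrix(stats::dist(pts))
  d_dup <- as.matrix(stats::dist(rbind(pts, pts[1, ])))
  expect_equal(dendrogram_fd(d_dup, "single"), dendrogram_fd(d, "single"),
               tolerance = 1e-9)

  expect_warning(expect_equal(dendrogram_fd(matrix(0, 1, 1)), 0), "single")

  # linkage choices are honored
  set.seed(89)
  d <- as.matrix(stats::dist(matrix(rnorm(20), 10)))
  expect_gte(dendrogram_fd(d, "complete"), dendrogram_fd(d, "single"))
})

test_that("cluster separation lowers FD while the hull expands", {
  seps <- c(0.3, 1, 3, 8)
  fd <- vapply(seps, function(s) {
    pts <- five_cluster_cloud(s, seed = 42)
    dendrogram_fd(as.matrix(stats::dist(pts)))
  }, numeric(1))
  expect_true(all(diff(fd) < 0))
})

test_that("subset RQE can exceed pooled RQE while beta stays >= 1", {
  # a maximally heterogeneous system pooled with a degenerate one, under
  # the discrete metric: mirrors the published pooling anomaly
  a <- abundance_vector(c(x1 = 0.25, x2 = 0.25, x3 = 0.25, x4 = 0.25))
  b <- abundance_vector(c(x1 = 1))
  pooled <- pool_systems(list(a, b))

  d_sub <- discrete_metric(4, labels = names(a))
  d_pool <- discrete_metric(length(pooled), labels = names(pooled))
  expect_gt(rao_quadratic_entropy(d_sub, a),
            rao_quadratic_entropy(d_pool, pooled))

  # the numbers-equivalent decomposition never drops below its within part
  for (q in c(0, 1, 2)) {
    dec <- decompose_heterogeneity(list(a, b), q = q)
    expect_gte(dec$beta, 1 - 1e-12)
  }
})
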