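test_that("Renyi heterogeneity reproduces its special orders", {
  p <- c(0.9, 0.1)
  expect_equal(renyi_heterogeneity(p, 2), 1 / 0.82, tolerance = 1e-12)
  expect_equal(renyi_heterogeneity(c(0.5, 0.5), 2), 2)
  expect_equal(renyi_heterogeneity(p, 0), 2)
  expect_equal(renyi_heterogeneity(p, 1),
               exp(shannon_entropy(p)), tolerance = 1e-12)
  expect_error(renyi_heterogeneity(p, -0.5),
               class = "renyihet_invalid_parameter")
})

test_that("uniform distributions score their richness at every order", {
  for (n in c(2, 5, 37, 200)) {
    p <- rep(1 / n, n)
    expect_equal(renyi_heterogeneity(p, c(0, 0.5, 1, 2, 5, 20)),
                 rep(n, 6), tolerance = 1e-9)
  }
})

test_that("diversity profiles are monotone non-increasing and hand-checked", {
  prof <- diversity_profile(c(0.7, 0.2, 0.1), q_grid = c(0, 1, 2))
  expect_equal(prof$heterogeneity[1], 3)
  expect_equal(prof$heterogeneity[2], exp(0.801819), tolerance = 1e-5)
  expect_equal(prof$heterogeneity[3], 1 / 0.54, tolerance = 1e-12)

  expect_equal(diversity_profile(rep(0.2, 5), c(0, 1, 2))$heterogeneity,
               rep(5, 3))
  expect_error(diversity_profile(c(0.5, 0.5), numeric(0)),
               class = "renyihet_invalid_parameter")

  set.seed(31)
  for (i in 1:1000) {
    p <- random_abundance(sample(2:50, 1), concentrated = TRUE)
    v <- renyi_heterogeneity(p, c(0, 0.25, 0.5, 1, 2, 4, 8))
    expect_true(all(diff(v) <= 1e-9))
    expect_true(all(v >= 1 - 1e-12))
  }
})

test_that("the q = 1 analytic limit is continuous", {
  set.seed(43)
  for (i in 1:100) {
    p <- random_abundance(sample(2:40, 1))
    v1 <- renyi_heterogeneity(p, 1)
    expect_lt(abs(renyi_heterogeneity(p, 1 - 1e-6) - v1), 1e-4)
    expect_lt(abs(renyi_heterogeneity(p, 1 + 1e-6) - v1), 1e-4)
  }
})

test_that("log-space evaluation survives very large category sets", {
  n <- 2e5
  p <- normalize_counts(rep(1, n))
  expect_equal(renyi_heterogeneity(p, 2), n, tolerance = 1e-6)
  expect_equal(renyi_heterogeneity(p, 0.5), n, tolerance = 1e-6)
})

test_that("evenness and Pielou's J behave at their calibration points", {
  expect_equal(evenness(rep(1 / 8, 8), 1), 1)
  expect_equal(evenness(c(0.9, 0.1), 2), (1 / 0.82) / 2, tolerance = 1e-12)
  expect_equal(evenness(c(1, 0, 0), 5), 1) # single-category support
  expect_equal(pielou_j(rep(0.25, 4)), 1)
  expect_equal(pielou_j(c(0.9, 0.1)), 0.325083 / log(2), tolerance = 1e-5)
  expect_error(pielou_j(c(1, 0)), class = "renyihet_invalid_input")
})

test_that("pooling merges label spaces with the stated weights", {
  a <- abundance_vector(c(x1 = 0.5, x2 = 0.5))
  expect_equal(as.numeric(pool_systems(list(a, a))), c(0.5, 0.5))

  b <- abundance_vector(c(y1 = 0.25, y2 = 0.25, y3 = 0.25, y4 = 0.25))
  c4 <- abundance_vector(c(z1 = 0.25, z2 = 0.25, z3 = 0.25, z4 = 0.25))
  pooled <- pool_systems(list(b, c4))
  expect_equal(as.numeric(pooled), rep(1 / 8, 8))

  expect_error(pool_systems(list(a, b), weights = c(0.9, 0.3)),
               class = "renyihet_invalid_parameter")
})

test_that("replication principle holds for Pi_q but fails for H and GSI", {
  set.seed(59)
  for (rep_i in 1:10) {
    p <- random_abundance(sample(3:25, 1), concentrated = TRUE)
    for (k in c(2, 3, 5)) {
      systems <- disjoint_copies(p, k)
      pooled <- pool_systems(systems)
      for (q in c(0, 0.5, 1, 2, 5)) {
        expect_equal(renyi_heterogeneity(pooled, q),
                     k * renyi_heterogeneity(p, q), tolerance = 1e-9)
      }
      # entropy is additive (log-scale), not multiplicative
      expect_equal(shannon_entropy(pooled), shannon_entropy(p) + log(k),
                   tolerance = 1e-9)
      expect_false(isTRUE(all.equal(shannon_entropy(pooled),
                                    k * shannon_entropy(p))))
      # GSI does not multiply: pooled value is 1 - Simpson(p)/k, not k * GSI
      expect_equal(gini_simpson(pooled), 1 - simpson_concentration(p) / k,
                   tolerance = 1e-12)
      expect_false(isTRUE(all.equal(gini_simpson(pooled),
                                    k * gini_simpson(p), tolerance = 1e-6)))
    }
  }
})

test_that("transfers increase Pi_q for q > 0", {
  set.seed(61)
  for (i in 1:100) {
    p <- random_abundance(sample(3:30, 1), concentrated = TRUE)
    pv <- as.numeric(p)
    if (max(pv) - min(pv) < 1e-6) next
    p2 <- pigou_dalton(p, eps = (max(pv) - min(pv)) / 10)
    for (q in c(0.5, 1, 2)) {
      expect_gt(renyi_heterogeneity(p2, q), renyi_heterogeneity(p, q))
    }
  }
})

test_that("decomposition multiplies back to gamma and calibrates beta", {
  a <- abundance_vector(c(x1 = 0.25, x2 = 0.25, x3 = 0.25, x4 = 0.25))
  b <- abundance_vector(c(y1 = 0.25, y2 = 0.25, y3 = 0.25, y4 = 0.25))

  # identical systems: no between-group heterogeneity
  dec <- decompose_heterogeneity(list(a, a), q = 2)
  expect_equal(dec$beta, 1, tolerance = 1e-12)

  # disjoint replication: gamma 8, alpha 4, beta 2
  dec <- decompose_heterogeneity(list(a, b), q = 1)
  expect_equal(dec$gamma, 8, tolerance = 1e-9)
  expect_equal(dec$alpha, 4, tolerance = 1e-9)
  expect_equal(dec$beta, 2, tolerance = 1e-9)

  # partial overlap at q = 2 against the direct-evaluation oracle
  s1 <- abundance_vector(c(a = 0.6, b = 0.3, c = 0.1))
  s2 <- abundance_vector(c(b = 0.2, c = 0.5, d = 0.3))
  dec <- decompose_heterogeneity(list(s1, s2), q = 2)
  pooled <- pool_systems(list(s1, s2))
  gamma_oracle <- 1 / sum(as.numeric(pooled)^2)
  alpha_oracle <- (mean(c(sum(as.numeric(s1)^2), sum(as.numeric(s2)^2))))^(-1)
  expect_equal(dec$gamma, gamma_oracle, tolerance = 1e-12)
  expect_equal(dec$alpha, alpha_oracle, tolerance = 1e-12)
  expect_gt(dec$beta, 1)
  expect_lt(dec$beta, 2)

  expect_error(
    decompose_heterogeneity(list(s1, s2), weights = c(0.7, 0.3), q = 2),
    class = "renyihet_unsupported_configuration")
  # ... but q = 1 supports arbitrary weights
  dec <- decompose_heterogeneity(list(s1, s2), weights = c(0.7, 0.3), q = 1)
  expect_equal(dec$gamma, dec$alpha * dec$beta, tolerance = 1e-9)
})

test_that("gamma = alpha x beta and beta in [1, G] across random groupings", {
  set.seed(67)
  for (i in 1:200) {
    g <- sample(2:5, 1)
    systems <- lapply(seq_len(g), function(j) {
      n <- sample(3:12, 1)
      shared <- sample(1:6, 1)
      labs <- c(paste0("shared_", seq_len(shared)),
                paste0("g", j, "_", seq_len(n)))
      random_abundance(length(labs)) |> as.numeric() |>
        abundance_vector(labels = labs)
    })
    q <- sample(c(0, 0.5, 1, 2, 5), 1)
    dec <- decompose_heterogeneity(systems, q = q)
    expect_equal(dec$gamma, dec$alpha * dec$beta, tolerance = 1e-9)
    expect_gte(dec$beta, 1 - 1e-9)
    expect_lte(dec$beta, g + 1e-9)
  }
})

test_that("Hill numbers agree with an independent community-ecology oracle", {
  set.seed(113)
  for (i in 1:20) {
    counts <- drop(stats::rmultinom(1, 500, prob = rgamma(sample(3:25, 1), 0.5) + 1e-9))
    counts <- counts[counts > 0]
    p <- normalize_counts(counts)
    qs <- c(0, 0.5, 1, 2, 4)
    ref <- as.numeric(vegan::renyi(counts, scales = qs, hill = TRUE))
    expect_equal(renyi_heterogeneity(p, qs), ref, tolerance = 1e-8)
  }
})
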