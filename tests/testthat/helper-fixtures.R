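# Shared fixture builders; everything is generated in code under fixed
# seeds so the suite needs no data files.

# random probability vector with support size n (all entries positive)
random_abundance <- function(n, concentrated = FALSE) {
  x <- stats::rgamma(n, shape = if (concentrated) 0.3 else 1)
  x <- x + 1e-12
  abundance_vector(x / sum(x))
}

# random count vector of total n_samples over n categories
random_counts <- function(n, n_samples) {
  count_vector(drop(stats::rmultinom(1, n_samples, prob = rep(1, n))))
}

# K disjoint relabeled copies of an abundance vector
disjoint_copies <- function(p, k) {
  lapply(seq_len(k), function(g) {
    abundance_vector(as.numeric(p),
                     labels = paste0("g", g, "_", seq_along(p)))
  })
}

# apply a small Pigou-Dalton transfer (rich -> poor) to a distribution
pigou_dalton <- function(p, eps = NULL) {
  pv <- as.numeric(p)
  i <- which.max(pv)
  j <- which.min(pv)
  eps <- eps %||% ((pv[i] - pv[j]) / 4)
  pv[i] <- pv[i] - eps
  pv[j] <- pv[j] + eps
  abundance_vector(pv / sum(pv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# five 2-D Gaussian clusters at a given separation, rescaled so the cloud
# always spans the same bounding box
five_cluster_cloud <- function(sep, seed, per_cluster = 12, sd = 0.2,
                               half_width = 1.5) {
  set.seed(seed)
  centers <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1), c(0, 0)) * sep
  pts <- do.call(rbind, lapply(seq_len(5), function(i) {
    cbind(stats::rnorm(per_cluster, centers[i, 1], sd),
          stats::rnorm(per_cluster, centers[i, 2], sd))
  }))
  for (j in 1:2) {
    r <- range(pts[, j])
    pts[, j] <- (pts[, j] - mean(r)) / diff(r) * 2 * half_width
  }
  pts
}
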