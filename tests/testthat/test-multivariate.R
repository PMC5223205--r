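test_that("transforms obey their closed forms", {
  expect_equal(sqrt_transform(matrix(c(4, 0, 1, 0.01), 2)),
               matrix(c(2, 0, 1, 0.1), 2))
  expect_error(sqrt_transform(matrix(-1)), "negative")

  h <- hellinger_transform(rbind(c(1, 3), c(2, 2)))
  expect_equal(h[1, ], c(0.5, sqrt(3) / 2))
  expect_equal(h[2, ], c(sqrt(0.5), sqrt(0.5)))
  # unit sum of squares for nonzero rows (random matrices)
  set.seed(1)
  for (r in 1:5) {
    m <- matrix(rexp(24), 4)
    expect_equal(rowSums(hellinger_transform(m)^2), rep(1, 4),
                 ignore_attr = TRUE)
  }
  expect_warning(hz <- hellinger_transform(rbind(c(0, 0), c(1, 1))),
                 "all-zero")
  expect_equal(hz[1, ], c(0, 0))
})

test_that("bray-curtis matches the closed form and handles zero rows", {
  d <- bray_curtis(rbind(a = c(1, 2), b = c(2, 2)))
  expect_equal(d["a", "b"], 1 / 7)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_equal(bray_curtis(rbind(c(1, 0), c(0, 3)))[1, 2], 1) # disjoint
  expect_warning(dz <- bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")
  expect_equal(dz[1, 2], 0)
})

test_that("bray-curtis on binary data equals Sorensen dissimilarity", {
  set.seed(42)
  for (r in 1:10) {
    m <- matrix(rbinom(40, 1, 0.5), 5)
    m[1, ] <- pmax(m[1, ], 1)  # avoid all-zero rows
    m[, 1] <- pmax(m[, 1], 1)
    d <- bray_curtis(m)
    for (i in 1:4) for (j in (i + 1):5) {
      a <- sum(m[i, ] & m[j, ]); b <- sum(m[i, ]); c <- sum(m[j, ])
      expect_equal(d[i, j], 1 - 2 * a / (b + c))
    }
  }
})

test_that("pca matches a brute-force eigendecomposition oracle", {
  set.seed(7)
  x <- matrix(rnorm(40), 8, 5)
  p <- pca(x)
  ev_oracle <- sort(eigen(cov(x), symmetric = TRUE)$values,
                    decreasing = TRUE)
  expect_equal(p$eigenvalues, ev_oracle, tolerance = 1e-8)
  # score covariance is diagonal with entries = eigenvalues
  sc_cov <- cov(p$scores)
  expect_equal(diag(sc_cov), p$eigenvalues, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sc_cov - diag(diag(sc_cov)), matrix(0, 5, 5),
               tolerance = 1e-8, ignore_attr = TRUE)
  # perfectly correlated pair -> PC1 explains everything
  y <- cbind(1:6, 2 * (1:6))
  expect_equal(pca(y)$proportion_explained[1], 1)
})

test_that("pca is rotation invariant and sign deterministic", {
  set.seed(8)
  x <- matrix(rnorm(60), 12, 5)
  q <- qr.Q(qr(matrix(rnorm(25), 5)))
  expect_equal(pca(x)$eigenvalues, pca(x %*% q)$eigenvalues,
               tolerance = 1e-8)
  p1 <- pca(x); p2 <- pca(x[, 5:1])  # column permutation
  expect_equal(abs(p1$scores), abs(p2$scores), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: largest |loading| positive
  expect_true(all(apply(p1$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("pca drops constant columns when scaling", {
  x <- cbind(a = rnorm(10), b = rnorm(10), c = rep(2, 10))
  expect_warning(p <- pca(x, scale = TRUE), "constant")
  expect_equal(nrow(p$loadings), 2L)
})

test_that("pcoa round-trips Euclidean configurations", {
  set.seed(9)
  pts <- matrix(rnorm(8), 4, 2)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  d2 <- as.matrix(dist(ord$scores))
  expect_equal(d2, d, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("pcoa on collinear points gives one axis with 1:2 spacing", {
  d <- as.matrix(dist(c(0, 1, 3)))
  ord <- pcoa(d)
  expect_equal(length(ord$eigenvalues), 1L)
  gaps <- diff(sort(ord$scores[, 1]))
  expect_equal(unname(gaps[2] / gaps[1]), 2, tolerance = 1e-8)
  # identical objects coincide
  ord2 <- pcoa(as.matrix(dist(c(0, 0, 5))))
  expect_equal(ord2$scores[1, ], ord2$scores[2, ], tolerance = 1e-8)
})

test_that("pcoa/pca duality: classical scaling of score distances", {
  set.seed(10)
  x <- matrix(rnorm(36), 9, 4)
  p <- pca(x)
  ord <- pcoa(as.matrix(dist(p$scores)))
  # cmdscale eigenvalues are sums of squares: (n-1) * pca variances
  expect_equal(ord$eigenvalues[1:4], (nrow(x) - 1) * p$eigenvalues,
               tolerance = 1e-8)
})

test_that("broken-stick retention matches the closed form and vegan", {
  # p = 2 thresholds are 0.75 / 0.25
  expect_equal(broken_stick(c(0.8, 0.2)), 1L)
  expect_equal(broken_stick(c(0.74, 0.26)), 0L)
  # equal eigenvalues never beat the first stick
  expect_equal(broken_stick(rep(1, 4)), 0L)
  expect_equal(broken_stick(c(0, 0, 0)), 0L)
  set.seed(11)
  for (r in 1:10) {
    ev <- sort(rexp(6), decreasing = TRUE)
    ours <- broken_stick(ev)
    stick <- vegan::bstick(length(ev), tot.var = sum(ev))
    oracle <- 0L
    for (k in seq_along(ev)) {
      if (ev[k] > stick[k]) oracle <- k else break
    }
    expect_equal(ours, oracle)
  }
})

test_that("scree elbow finds the largest successive drop", {
  expect_equal(scree_elbow(c(5, 4.5, 1, 0.9)), 2L)
  expect_equal(scree_elbow(c(5, 1, 0.9, 0.8)), 1L)
})
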