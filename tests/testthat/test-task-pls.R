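test_that("datamat stacking is condition-blocked and round-trips", {
  im <- noise_images(n_subjects = 14, n_voxels = 25, seed = 1)
  dm <- build_datamat(im)
  expect_equal(dim(dm$X), c(28, 25))
  expect_equal(dm$row_condition, rep(1:2, each = 14))
  # row -> (condition, subject) -> row is the identity
  for (row in c(1, 14, 15, 28)) {
    c <- dm$row_condition[row]; s <- dm$row_subject[row]
    expect_equal(dm$X[row, ], im$values[s, c, ])
    expect_equal((c - 1) * dm$n + s, row)
  }
  # consistent subject reordering leaves singular values unchanged
  im2 <- im
  ord <- sample.int(14)
  im2$values <- im$values[ord, , ]
  d1 <- svd(mean_center(build_datamat(im)))$d
  d2 <- svd(mean_center(build_datamat(im2)))$d
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("mean centering removes the grand mean exactly", {
  im <- noise_images(n_subjects = 6, n_voxels = 10, seed = 2)
  M <- mean_center(build_datamat(im))
  expect_lt(max(abs(colSums(M))), 1e-12)
  # identical condition means -> zero matrix
  im$values[, 2, ] <- im$values[, 1, ]
  expect_lt(max(abs(mean_center(build_datamat(im)))), 1e-14)
})

test_that("SVD of a hand-built two-condition matrix matches hand algebra", {
  # per-voxel condition means (1, 0) and (0, 1) -> centered rows +-(.5, -.5)
  im <- structure(list(values = array(0, c(3, 2, 2)),
                       conditions = c("A", "B"), subjects = 1:3,
                       grid = voxel_grid(c(2, 1, 1))),
                  class = "condition_images")
  im$values[, 1, 1] <- 1
  im$values[, 2, 2] <- 1
  M <- mean_center(build_datamat(im))
  expect_equal(unname(M), rbind(c(0.5, -0.5), c(-0.5, 0.5)))
  res <- pls_svd(M)
  expect_length(res$singular_values, 1)
  expect_equal(res$singular_values, 1, tolerance = 1e-12)
  expect_equal(res$voxel_saliences[, 1], c(1, -1) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(abs(res$task_saliences[, 1]), c(1, 1) / sqrt(2),
               tolerance = 1e-12)
  # zero matrix -> no nonzero LVs
  expect_length(pls_svd(matrix(0, 2, 5))$singular_values, 0)
})

test_that("SVD conserves energy and returns orthonormal saliences", {
  set.seed(3)
  M <- matrix(rnorm(6 * 50), 6, 50)
  M <- sweep(M, 2, colMeans(M))
  res <- pls_svd(M)
  expect_equal(sum(res$singular_values^2), sum(M^2), tolerance = 1e-10)
  r <- length(res$singular_values)
  expect_equal(crossprod(res$task_saliences), diag(r), tolerance = 1e-10)
  expect_equal(crossprod(res$voxel_saliences), diag(r), tolerance = 1e-10)
  expect_true(all(diff(res$singular_values) <= 0))
  expect_equal(sum(res$pct_covariance), 100, tolerance = 1e-10)
})

test_that("scaling the data scales singular values, not saliences", {
  im <- noise_images(n_subjects = 10, n_voxels = 30, seed = 4)
  dm <- build_datamat(im)
  r1 <- pls_svd(mean_center(dm))
  dm2 <- dm
  dm2$X <- dm$X * 3.7
  r2 <- pls_svd(mean_center(dm2))
  expect_equal(r2$singular_values, 3.7 * r1$singular_values,
               tolerance = 1e-10)
  expect_equal(abs(r2$voxel_saliences), abs(r1$voxel_saliences),
               tolerance = 1e-10)
})

test_that("two-condition voxel saliences equal the difference-map oracle", {
  im <- planted_images(n_subjects = 14, seed = 5)
  dm <- build_datamat(im)
  res <- pls_svd(mean_center(dm))
  # brute-force oracle: normalized difference of condition means
  mA <- colMeans(im$values[, 1, ]); mB <- colMeans(im$values[, 2, ])
  diff <- mA - mB
  oracle <- diff / sqrt(sum(diff^2))
  u <- res$voxel_saliences[, 1]
  if (sum(u * oracle) < 0) oracle <- -oracle
  expect_equal(u, oracle, tolerance = 1e-10)
})

test_that("brain scores are the voxel-salience projections", {
  im <- planted_images(n_subjects = 8, noise_sd = 0, subject_sd = 0, seed = 6)
  dm <- build_datamat(im)
  res <- pls_svd(mean_center(dm))
  sc <- compute_brain_scores(dm, res, 1)
  expect_equal(dim(sc), c(8, 2))
  # noise-free rank-1 data: scores proportional to the task profile and
  # identical across subjects
  expect_lt(max(apply(sc, 2, sd)), 1e-10)
  v <- attr(im, "v_true")
  ratio <- mean(sc[, 1]) / mean(sc[, 2])
  expect_equal(ratio, v[1] / v[2], tolerance = 1e-8)
  # condition means of brain scores align with task saliences x singular value
  centered <- sweep(sc, 1, rowMeans(sc))
  expected <- res$task_saliences[, 1] * res$singular_values[1]
  expect_equal(unname(colMeans(centered) / sqrt(sum(colMeans(centered)^2))),
               expected / sqrt(sum(expected^2)), tolerance = 1e-8)
  # degenerate zero salience vector gives zero scores
  res0 <- res
  res0$voxel_saliences[, 1] <- 0
  expect_true(all(compute_brain_scores(dm, res0, 1) == 0))
})

test_that("planted task patterns are recovered end to end", {
  hits <- 0
  for (seed in 1:10) {
    im <- planted_images(n_subjects = 14, amplitude = 6, noise_sd = 0.2,
                         grid = voxel_grid(c(8, 8, 8)), seed = seed)
    res <- pls_svd(mean_center(build_datamat(im)))
    u <- attr(im, "u_true")
    hits <- hits + (abs(cor(res$voxel_saliences[, 1], u)) > 0.9)
  }
  expect_gte(hits, 9)
})
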