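test_that("two points merge at half their squared distance", {
  mat <- rbind(c(0, 0), c(3, 4))
  wc <- ward_linkage(mat)
  expect_equal(nrow(wc$merge), 1)
  expect_equal(wc$height, 25 / 2)
})

test_that("ward linkage equals the brute-force minimal-variance agglomerator", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    p <- sample(1:4, 1)
    mat <- matrix(rnorm(n * p), n, p)
    wc <- ward_linkage(mat)
    bf <- brute_force_ward(mat)
    expect_equal(ward_merge_sets(wc), bf$merges)
    expect_equal(wc$height, bf$heights, tolerance = 1e-8)
  }
})

test_that("duplicated points merge first at height zero", {
  set.seed(3)
  base <- matrix(rnorm(8), 4, 2)
  mat <- rbind(base, base)
  wc <- ward_linkage(mat)
  expect_equal(wc$height[1:4], rep(0, 4))
  first_pairs <- lapply(1:4, function(s) sort(-wc$merge[s, ]))
  expect_setequal(lapply(first_pairs, function(x) abs(diff(x))), list(4))
})

test_that("merge order and heights agree with hclust ward.D2", {
  set.seed(17)
  mat <- matrix(rnorm(60), 15, 4)
  rownames(mat) <- sprintf("s%02d", 1:15)
  wc <- ward_linkage(mat)
  hc <- hclust(dist(mat), method = "ward.D2")
  expect_equal(sqrt(2 * wc$height), hc$height, tolerance = 1e-9)
  for (k in c(2, 3, 5, 8)) {
    ours <- cut_tree(wc, k)
    theirs <- cutree(hc, k)[ours$species]
    expect_equal(ari(ours$cluster, theirs), 1)
  }
})

test_that("ward heights are monotone non-decreasing", {
  set.seed(31)
  for (rep in 1:5) {
    mat <- matrix(rnorm(30 * 3), 30, 3)
    wc <- ward_linkage(mat)
    expect_true(all(diff(wc$height) >= -1e-12))
  }
})

test_that("two-way clustering mirrors a symmetric matrix and splits blocks", {
  set.seed(8)
  s <- matrix(rnorm(25), 5, 5)
  sym <- s + t(s)
  dimnames(sym) <- list(letters[1:5], letters[1:5])
  tw <- two_way_cluster(sym)
  expect_equal(tw$species_tree$merge, tw$trait_tree$merge)
  expect_equal(tw$species_tree$height, tw$trait_tree$height)

  blocks <- rbind(cbind(matrix(5, 3, 2), matrix(0, 3, 3)),
                  cbind(matrix(0, 4, 2), matrix(5, 4, 3)))
  blocks <- blocks + matrix(rnorm(35, 0, 0.01), 7, 5)
  rownames(blocks) <- sprintf("r%d", 1:7); colnames(blocks) <- sprintf("c%d", 1:5)
  tw2 <- two_way_cluster(blocks)
  top_rows <- cut_tree(tw2$species_tree, 2)
  expect_equal(ari(top_rows$cluster, c(1, 1, 1, 2, 2, 2, 2)), 1)
  top_cols <- cut_tree(tw2$trait_tree, 2)
  expect_equal(ari(top_cols$cluster, c(1, 1, 2, 2, 2)), 1)
  expect_equal(dim(tw2$matrix), dim(blocks))

  single <- matrix(rnorm(4), 4, 1, dimnames = list(letters[1:4], "only"))
  tw3 <- two_way_cluster(single)
  expect_null(tw3$trait_tree)
})

test_that("tree cutting spans k = 1 to n and produces nested partitions", {
  set.seed(12)
  mat <- matrix(rnorm(20), 10, 2)
  rownames(mat) <- sprintf("s%02d", 1:10)
  wc <- ward_linkage(mat)
  expect_equal(unique(cut_tree(wc, 1)$cluster), 1L)
  expect_equal(sort(cut_tree(wc, 10)$cluster), 1:10)
  expect_error(cut_tree(wc, 0), "out of range")
  for (k in 2:9) {
    fine <- cut_tree(wc, k + 1)$cluster
    coarse <- cut_tree(wc, k)$cluster
    # each fine cluster maps into exactly one coarse cluster
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
})

test_that("discriminant distances reduce to Euclidean under identity covariance", {
  set.seed(44)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  mat <- do.call(rbind, lapply(1:3, function(g) {
    sweep(matrix(rnorm(100 * 2), 100, 2), 2, centers[g, ], `+`)
  }))
  labels <- rep(c("A", "B", "C"), each = 100)
  model <- fit_discriminant(mat, labels, lambda = 0)
  maha <- mahalanobis_matrix(model)
  eucl <- as.matrix(dist(model$centroids))^2
  # pooled covariance is near identity, so distances are near squared Euclidean
  expect_equal(maha, eucl, tolerance = 0.1)
})

test_that("a two-group two-dimensional fixture matches hand-computed Mahalanobis", {
  g1 <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  g2 <- rbind(c(5, 5), c(7, 5), c(5, 7), c(7, 7))
  mat <- rbind(g1, g2)
  labels <- rep(c("A", "B"), each = 4)
  model <- fit_discriminant(mat, labels, lambda = 0)
  # hand computation: both groups have centroid scatter 4 per axis, pooled
  # covariance = (4 + 4)/(8 - 2) * I ... computed explicitly:
  S_hand <- (crossprod(sweep(g1, 2, colMeans(g1))) +
             crossprod(sweep(g2, 2, colMeans(g2)))) / (8 - 2)
  d <- colMeans(g1) - colMeans(g2)
  hand <- as.numeric(d %*% solve(S_hand) %*% d)
  expect_equal(mahalanobis_matrix(model)["A", "B"], hand, tolerance = 1e-9)
  # 1-D closed form: ((mu1 - mu2)/s)^2
  x <- c(1, 2, 3, 11, 12, 13)
  m1 <- fit_discriminant(matrix(x, ncol = 1), rep(c("a", "b"), each = 3),
                         lambda = 0)
  s2 <- (var(x[1:3]) * 2 + var(x[4:6]) * 2) / 4
  expect_equal(mahalanobis_matrix(m1)["a", "b"], (10)^2 / s2, tolerance = 1e-9)
})

test_that("identical centroids give zero Mahalanobis separation", {
  set.seed(2)
  mat <- matrix(rnorm(40), 20, 2)
  model <- fit_discriminant(rbind(mat, mat),
                            rep(c("A", "B"), each = 20), lambda = 0)
  expect_equal(unname(mahalanobis_matrix(model)["A", "B"]), 0, tolerance = 1e-12)
})

test_that("Mahalanobis matrix is affine invariant, symmetric and zero-diagonal", {
  set.seed(23)
  mat <- matrix(rnorm(90), 30, 3)
  mat[11:20, ] <- mat[11:20, ] + 3
  mat[21:30, 1] <- mat[21:30, 1] - 4
  labels <- rep(c("A", "B", "C"), each = 10)
  m0 <- mahalanobis_matrix(fit_discriminant(mat, labels, lambda = 0))
  A <- matrix(c(2, 1, 0, 0, 1, -1, 1, 0, 3), 3)
  m1 <- mahalanobis_matrix(fit_discriminant(mat %*% A + 5, labels, lambda = 0))
  expect_equal(m0, m1, tolerance = 1e-8)
  expect_equal(m0, t(m0))
  expect_equal(unname(diag(m0)), rep(0, 3))
})

test_that("discriminant classification agrees with the generator and with lda", {
  sim <- simulate_traits(synthetic_config(seed = 19))
  mat <- transform_traits(select_traits(sim$table))
  model <- fit_discriminant(mat, sim$labels$label)
  pred <- predict(model, mat)
  expect_gte(mean(pred$group == sim$labels$label), 0.95)

  # independent check on a non-degenerate subspace: MASS::lda with equal
  # priors should classify the training points near-identically
  cont <- setdiff(colnames(mat), "PB")
  sub <- mat[, cont[1:6]]
  m2 <- fit_discriminant(sub, sim$labels$label, lambda = 0)
  p2 <- predict(m2, sub)
  ld <- MASS::lda(sub, grouping = sim$labels$label,
                  prior = rep(1 / 5, 5))
  agree <- mean(p2$group == as.character(predict(ld)$class))
  expect_gte(agree, 0.95)
})

test_that("degenerate group sizes are rejected", {
  mat <- matrix(rnorm(10), 5, 2)
  expect_error(fit_discriminant(mat, c("A", "A", "A", "A", "B")), "< 2 members")
  expect_error(fit_discriminant(mat, rep("A", 5)), "at least 2 groups")
})
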