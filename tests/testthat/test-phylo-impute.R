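make_obs_table <- function(obs, traits = c("Height", "LL", "LW", "TC")) {
  # logical observed matrix -> trait table with NA at FALSE cells
  vals <- matrix(abs(rnorm(length(obs))) + 1, nrow(obs), ncol(obs))
  vals[!obs] <- NA
  df <- tibble::as_tibble(as.data.frame(vals))
  names(df) <- traits[seq_len(ncol(obs))]
  df$species <- sprintf("s%02d", seq_len(nrow(obs)))
  df$genus <- "g"
  trait_table(df)
}

test_that("coverage filter drops under-covered traits and is identity on complete data", {
  set.seed(1)
  obs <- matrix(TRUE, 10, 4)
  tt <- make_obs_table(obs)
  expect_equal(nrow(coverage_filter(tt)), 10)

  obs2 <- matrix(TRUE, 10, 4)
  obs2[1:4, 4] <- FALSE   # 60% coverage for trait 4
  tt2 <- make_obs_table(obs2)
  out <- coverage_filter(tt2, 0.70)
  expect_false("TC" %in% names(out))
  expect_equal(nrow(out), 10)
})

test_that("coverage-filter fixed point matches exhaustive subset search on a 6x4 instance", {
  set.seed(2)
  obs <- matrix(TRUE, 6, 4)
  obs[1, 2] <- FALSE          # trait B missing for row 1
  obs[1:3, 4] <- FALSE        # trait D at 50% coverage
  tt <- make_obs_table(obs)
  out <- coverage_filter(tt, 0.70)
  kept_rows <- match(out$species, tt$species)
  kept_cols <- match(intersect(c("Height", "LL", "LW", "TC"), names(out)),
                     c("Height", "LL", "LW", "TC"))
  bf <- brute_force_coverage(obs, 0.70)
  expect_equal(sum(obs[kept_rows, kept_cols]), bf$cells)
  expect_true(any(vapply(seq_along(bf$rows), function(i) {
    setequal(bf$rows[[i]], kept_rows) && setequal(bf$cols[[i]], kept_cols)
  }, logical(1))))
})

test_that("coverage filter errors when nothing survives", {
  obs <- matrix(FALSE, 3, 3)
  obs[1, 1] <- TRUE
  tt <- make_obs_table(obs, traits = c("Height", "LL", "LW"))
  expect_error(coverage_filter(tt, 0.9), "removed all rows")
})

test_that("newick reading validates and round-trips", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tr <- read_newick(path)
  expect_equal(ape::Ntip(tr), 3)
  expect_setequal(tr$tip.label, c("A", "B", "C"))

  writeLines("((A:1,A:1):1,C:2);", path)
  expect_error(read_newick(path), "duplicated tip")

  tr2 <- simulate_tree(12, 1, seed = 4)
  write_newick(tr2, path)
  back <- read_newick(path)
  expect_equal(sort(ape::cophenetic.phylo(back)[tr2$tip.label, tr2$tip.label]),
               sort(ape::cophenetic.phylo(tr2)), tolerance = 1e-9)
})

test_that("BM imputation on a star tree reduces to the observed mean", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  tt <- trait_table(tibble::tibble(
    species = c("A", "B", "C", "D"), genus = "g",
    Height = c(0.2, 0.4, 0.9, NA)
  ))
  out <- impute_bm(tt, tr)
  expect_equal(out$table$Height[4], mean(c(0.2, 0.4, 0.9)), tolerance = 1e-6)
  expect_equal(out$report$n_imputed_phylo, 1)
  expect_equal(attr(out$table, "provenance")$Height[4], "imputed_phylo")
})

test_that("BM imputation exploits a perfect trait correlation", {
  tr <- simulate_tree(12, 1, seed = 3)
  set.seed(5)
  y1 <- as.numeric(t(chol(ape::vcv(tr))) %*% rnorm(12))
  y2 <- 3 + 2 * y1
  tt <- trait_table(tibble::tibble(
    species = tr$tip.label, genus = "g",
    Height = y1 - min(y1) + 1, LL = y2 - min(y2) + 1
  ))
  expected <- tt$LL[5]
  tt$LL[5] <- NA
  attr(tt, "provenance")$LL[5] <- NA_character_
  out <- impute_bm(tt, tr)
  expect_equal(out$table$LL[5], expected, tolerance = 1e-6)
})

test_that("BM imputation without missing cells is the identity", {
  tr <- simulate_tree(6, 1, seed = 9)
  tt <- trait_table(tibble::tibble(
    species = tr$tip.label, genus = "g", Height = runif(6, 0.1, 1)
  ))
  out <- impute_bm(tt, tr)
  expect_identical(tibble::as_tibble(out$table), tibble::as_tibble(tt))
  expect_equal(out$report$n_imputed_phylo, 0)
})

test_that("BM rate-matrix recovery converges over replicates", {
  R_true <- matrix(c(1, 0.6, 0.6, 1), 2)
  set.seed(1)
  fits <- replicate(20, {
    tr <- simulate_tree(50, 1, seed = sample.int(1e6, 1))
    C <- ape::vcv(tr)
    L <- t(chol(C))
    X <- L %*% matrix(rnorm(100), 50, 2) %*% chol(R_true)
    tt <- trait_table(tibble::tibble(
      species = tr$tip.label, genus = "g",
      Height = X[, 1] + 10, LL = X[, 2] + 10
    ))
    # mask a few cells so the EM path is exercised
    idx <- sample.int(50, 4)
    tt$Height[idx[1:2]] <- NA; tt$LL[idx[3:4]] <- NA
    prov <- attr(tt, "provenance")
    prov$Height[idx[1:2]] <- NA; prov$LL[idx[3:4]] <- NA
    attr(tt, "provenance") <- prov
    impute_bm(tt, tr)$fit$R
  })
  R_bar <- apply(fits, c(1, 2), mean)
  expect_lt(norm(R_bar - R_true, "F") / norm(R_true, "F"), 0.20)
})

test_that("out-of-range phylogenetically imputed values are rejected", {
  tt <- trait_table(tibble::tibble(
    species = c("a", "b", "c", "d"), genus = "g",
    TC = c(0, 10, 4924, -0)
  ))
  # forge an imputed cell below the observed range
  tt$TC[4] <- -4
  prov <- attr(tt, "provenance")
  prov$TC[4] <- "imputed_phylo"
  attr(tt, "provenance") <- prov
  # bypass the >=0 invariant check by operating on the forged object directly
  rep0 <- structure(list(
    n_missing_before = 1, n_imputed_phylo = 1, n_rejected = 0,
    n_imputed_genus = 0, n_left_empty = 0,
    cells = tibble::tibble(species = "d", trait = "TC",
                           method = "imputed_phylo", value = -4)),
    class = "impute_report")
  out <- reject_out_of_range(tt, rep0)
  expect_true(is.na(out$table$TC[4]))
  expect_equal(out$report$n_rejected, 1)
  # an in-range imputed value is kept
  tt2 <- trait_table(tibble::tibble(
    species = c("a", "b", "c"), genus = "g", TC = c(0, 10, 5)))
  prov2 <- attr(tt2, "provenance"); prov2$TC[3] <- "imputed_phylo"
  attr(tt2, "provenance") <- prov2
  rep2 <- structure(list(n_missing_before = 1, n_imputed_phylo = 1,
                         n_rejected = 0, n_imputed_genus = 0, n_left_empty = 0,
                         cells = tibble::tibble(species = "c", trait = "TC",
                                                method = "imputed_phylo",
                                                value = 5)),
                    class = "impute_report")
  out2 <- reject_out_of_range(tt2, rep2)
  expect_equal(out2$table$TC[3], 5)
  expect_equal(out2$report$n_rejected, 0)
})

test_that("genus-mean fallback averages congeners and leaves orphans empty", {
  tt <- trait_table(tibble::tibble(
    species = c("a", "b", "c", "lonely"),
    genus = c("g1", "g1", "g1", "g2"),
    Height = c(2, 4, NA, NA)
  ))
  out <- impute_genus_mean(tt)
  expect_equal(out$table$Height[3], 3)
  expect_true(is.na(out$table$Height[4]))
  expect_equal(out$report$n_imputed_genus, 1)
  expect_equal(out$report$n_left_empty, 1)
  expect_equal(out$report$n_missing_before,
               out$report$n_imputed_phylo + out$report$n_imputed_genus +
                 out$report$n_left_empty)
  # identity on complete data
  complete <- trait_table(tibble::tibble(
    species = c("a", "b"), genus = "g", Height = c(1, 2)))
  expect_identical(tibble::as_tibble(impute_genus_mean(complete)$table),
                   tibble::as_tibble(complete))
})

test_that("the full gap-filling chain never alters an observed cell", {
  sim <- simulate_traits(synthetic_config(seed = 21))
  masked <- mask_missing(sim$table, 0.072, seed = 3)
  out <- impute_traits(masked, sim$tree)
  for (tr in intersect(clustering_traits(), names(out$table))) {
    obs <- !is.na(masked[[tr]])
    kept <- match(out$table$species, masked$species)
    expect_equal(out$table[[tr]][obs[kept]], masked[[tr]][kept][obs[kept]],
                 tolerance = 1e-12)
  }
  expect_equal(out$report$n_missing_before,
               out$report$n_imputed_phylo + out$report$n_imputed_genus +
                 out$report$n_left_empty)
})

test_that("phylogenetic imputation beats genus means under strong signal and ties on a star tree", {
  mse_pair <- function(tree, n = 40, seed = 13, r_cross = 0.7) {
    set.seed(seed)
    C <- ape::vcv(tree)
    L <- t(chol(C + diag(1e-10, nrow(C))))
    R <- matrix(c(1, r_cross, r_cross, 1), 2)
    X <- L %*% matrix(rnorm(2 * n), n, 2) %*% chol(R)
    genus <- sprintf("g%d", cutree(hclust(as.dist(ape::cophenetic.phylo(tree)),
                                          method = "average"), k = 6))
    tt <- trait_table(tibble::tibble(
      species = tree$tip.label, genus = genus,
      Height = X[, 1] + 20, LL = X[, 2] + 20))
    idx <- sample.int(n, 6)
    truth <- tt$Height[idx]
    tt$Height[idx] <- NA
    prov <- attr(tt, "provenance"); prov$Height[idx] <- NA
    attr(tt, "provenance") <- prov
    bm <- impute_bm(tt, tree)$table$Height[idx]
    gm <- impute_genus_mean(tt)$table$Height[idx]
    c(bm = mean((bm - truth)^2, na.rm = TRUE),
      gm = mean((gm - truth)^2, na.rm = TRUE))
  }
  # strong signal: a deep Yule tree
  res <- rowMeans(vapply(1:5, function(r) {
    mse_pair(simulate_tree(40, 1, seed = 100 + r), seed = 200 + r)
  }, numeric(2)))
  expect_lt(res["bm"], res["gm"])

  # zero signal: star tree, both are mean-like estimators
  star <- ape::read.tree(text = paste0("(", paste(sprintf("t%d:1", 1:40),
                                                  collapse = ","), ");"))
  star$tip.label <- sprintf("t%d", 1:40)
  res0 <- vapply(1:8, function(r) mse_pair(star, seed = 300 + r, r_cross = 0),
                 numeric(2))
  ratio <- mean(res0["bm", ]) / mean(res0["gm", ])
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.67)
})
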