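test_that("Spearman matrix handles monotone, reversed and tied data", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  up <- x^3
  down <- -x + 100
  df <- tibble::tibble(a = x, b = up, d = down)
  m <- spearman_matrix(df)
  expect_equal(m$rho["a", "b"], 1)
  expect_equal(m$rho["a", "d"], -1)
  expect_equal(m$rho, t(m$rho))
  expect_equal(unname(diag(m$rho)), rep(1, 3))

  # ties: rho must equal the midrank Pearson-on-ranks computation, and p the
  # two-sided t approximation, both assembled by hand
  set.seed(6)
  xt <- c(1, 1, 2, 3, 3, 3, 4, 5)
  yt <- c(2, 1, 1, 4, 4, 6, 5, 5)
  mt <- spearman_matrix(tibble::tibble(x = xt, y = yt))
  rho_hand <- cor(rank(xt), rank(yt))
  expect_equal(mt$rho["x", "y"], rho_hand, tolerance = 1e-12)
  tstat <- rho_hand * sqrt((8 - 2) / (1 - rho_hand^2))
  p_hand <- 2 * pt(abs(tstat), df = 6, lower.tail = FALSE)
  expect_equal(mt$p["x", "y"], p_hand, tolerance = 1e-9)
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(10)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  r0 <- spearman_matrix(tibble::tibble(a = x, b = y))$rho["a", "b"]
  r1 <- spearman_matrix(tibble::tibble(a = exp(x), b = y^3 + 5 * y))$rho["a", "b"]
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("Spearman uses pairwise-complete cells and flags tiny overlap as undefined", {
  df <- tibble::tibble(
    a = c(1, 2, 3, 4, NA, NA),
    b = c(2, 1, 4, 3, 5, 6),
    d = c(NA, NA, NA, NA, 1, 2)
  )
  m <- spearman_matrix(df)
  expect_equal(m$n["a", "b"], 4L)
  expect_true(is.na(m$rho["a", "d"]))   # only 0 complete pairs
})

test_that("KW comparison degenerates gracefully and separates clear groups", {
  flat <- suppressWarnings(kw_posthoc(rep(5, 12), rep(c("A", "B", "C"), 4)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_equal(unique(flat$summary$letters), "a")

  # three groups of four with no overlap: the exact two-sided rank-sum
  # minimum p at n = 4 is 2/choose(8,4) = 0.0286 < 0.05, so all letters differ
  v <- c(1, 2, 3, 4, 11, 12, 13, 14, 21, 22, 23, 24)
  g <- rep(c("A", "B", "C"), each = 4)
  res <- kw_posthoc(v, g)
  expect_equal(unname(res$pairwise["A", "B"]), 2 / choose(8, 4), tolerance = 1e-12)
  expect_equal(length(unique(res$summary$letters)), 3)
  expect_true(check_cld_consistency(
    setNames(res$summary$letters, res$summary$group), res$pairwise, res$alpha))
})

test_that("tie-free KW statistic equals the rank-sum identity", {
  set.seed(14)
  v <- rnorm(30)
  g <- rep(c("A", "B", "C"), each = 10)
  res <- kw_posthoc(v, g)
  N <- length(v)
  r <- rank(v)
  rbar_g <- tapply(r, g, mean)
  H_hand <- 12 / (N * (N + 1)) * sum(10 * (rbar_g - mean(r))^2)
  expect_equal(res$statistic, H_hand, tolerance = 1e-12)
  expect_equal(res$df, 2)
})

test_that("groups with fewer than two observations are excluded with a warning", {
  expect_warning(
    res <- kw_posthoc(c(1, 2, 3, 4, 9), c("A", "A", "B", "B", "C")),
    "excluding groups"
  )
  expect_setequal(res$summary$group, c("A", "B"))
})

test_that("ANOVA comparison matches hand-computed mean squares and letters behave", {
  same <- anova_tukey(c(rnorm(5, 0, 1e-9) + 1, rnorm(5, 0, 1e-9) + 1),
                      rep(c("A", "B"), each = 5))
  expect_lt(same$statistic, 1)
  expect_equal(unique(same$summary$letters), "a")

  far <- anova_tukey(c(rnorm(5, 0, 0.01), rnorm(5, 100, 0.01)),
                     rep(c("A", "B"), each = 5))
  expect_lt(far$p, 1e-6)
  expect_equal(length(unique(far$summary$letters)), 2)

  # balanced 3x5 fixture: F = MS_between / MS_within assembled by hand
  v <- c(3, 4, 5, 6, 7,  8, 9, 10, 11, 12,  2, 3, 4, 5, 6)
  g <- rep(c("A", "B", "C"), each = 5)
  res <- anova_tukey(v, g)
  means <- tapply(v, g, mean)
  ms_between <- 5 * sum((means - mean(v))^2) / 2
  ms_within <- sum((v - means[g])^2) / 12
  expect_equal(res$statistic, ms_between / ms_within, tolerance = 1e-9)
  expect_equal(res$df, c(2, 12))
})

test_that("compact letter display is consistent with any pairwise p matrix", {
  set.seed(77)
  for (rep in 1:40) {
    g <- sample(3:6, 1)
    pm <- matrix(NA_real_, g, g, dimnames = list(letters[1:g], letters[1:g]))
    for (i in 1:(g - 1)) for (j in (i + 1):g) {
      pm[i, j] <- pm[j, i] <- sample(c(runif(1, 0, 0.04), runif(1, 0.06, 1)), 1)
    }
    cl <- epibrom:::cld_letters(pm, 0.05)
    expect_true(check_cld_consistency(cl, pm, 0.05))
  }
})

test_that("ecozone presence counts species, not records", {
  rec <- tibble::tibble(
    species = c(rep("sp1", 100), "sp2", "sp2", "sp2"),
    ecozone = c(rep("Tropical rainforest", 100), "Tropical rainforest",
                "Tropical dry forest", "Tropical mountain system")
  )
  labels <- tibble::tibble(species = c("sp1", "sp2"), label = c("NEB", "C3_T"))
  m <- ecozone_presence(rec, labels)
  expect_equal(m["NEB", "Tropical rainforest"], 1L)
  expect_equal(sum(m["C3_T", ]), 3L)   # one per zone spanned
  # duplication invariance
  m2 <- ecozone_presence(dplyr::bind_rows(rec, rec), labels)
  expect_equal(m, m2)
  # unlabeled species are dropped with a warning
  rec2 <- dplyr::bind_rows(rec, tibble::tibble(species = "ghost",
                                               ecozone = "Tropical desert"))
  expect_warning(m3 <- ecozone_presence(rec2, labels), "ghost")
  expect_equal(m, m3[, colnames(m)])
})

test_that("environmental comparisons recover constructed niche contrasts", {
  cfg <- synthetic_config(seed = 31)
  sim <- simulate_traits(cfg)
  rec <- simulate_env_records(cfg, sim$labels, records_per_species = 10)
  expect_equal(nrow(rec), nrow(sim$labels) * 10)
  out <- env_group_compare(rec, sim$labels)
  expect_setequal(names(out), env_variables())
  ppt <- out$PPT$summary
  expect_false(any(strsplit(ppt$letters[ppt$group == "NEB"], "")[[1]] %in%
                     strsplit(ppt$letters[ppt$group == "C3_T"], "")[[1]]))
  # calibration: identical niches share letters
  cfg0 <- cfg
  cfg0$niches$mean[env_variables()] <- lapply(env_variables(), function(v) {
    rep(cfg$niches$mean[[v]][1], 5)
  })
  rec0 <- simulate_env_records(cfg0, sim$labels, records_per_species = 6, seed = 8)
  out0 <- env_group_compare(rec0, sim$labels)
  shared <- vapply(out0, function(x) {
    all(vapply(x$summary$letters, function(l) {
      any(strsplit(l, "")[[1]] %in% strsplit(x$summary$letters[1], "")[[1]])
    }, logical(1)))
  }, logical(1))
  # with a single climate, letters are mostly shared across groups
  expect_gte(mean(shared), 0.5)
  # single labelled group: skipped with a notice
  one <- sim$labels[sim$labels$label == "NEB", ]
  expect_message(out1 <- env_group_compare(rec, one), "skipping")
  expect_equal(length(out1), 0)
})

test_that("strong-correlation filter applies the published cutoffs", {
  set.seed(4)
  x <- rnorm(40)
  df <- tibble::tibble(a = x, b = x + rnorm(40, 0, 0.1),
                       d = x + rnorm(40, 0, 2), e = rnorm(40))
  m <- spearman_matrix(df)
  sc <- strong_correlations(m)
  expect_true(all(sc$rho^2 > 0.60))
  expect_true(all(sc$p < 0.05))
  expect_true(any(sc$trait_a == "b" & sc$trait_b == "a" |
                    sc$trait_a == "a" & sc$trait_b == "b"))
})
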