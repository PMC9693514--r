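# Independent oracles used across the suite. These deliberately recompute
# quantities from first definitions (explicit SSE sums, exhaustive subset
# search, rank arithmetic) rather than reusing package internals.

# Brute-force Ward agglomerator: evaluates every candidate pair merge at
# every step by recomputing within-cluster SSE from the raw points.
brute_force_ward <- function(mat) {
  mat <- as.matrix(mat)
  sse <- function(idx) {
    if (length(idx) == 1) return(0)
    sub <- mat[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- as.list(seq_len(nrow(mat)))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL; bestd <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        d <- sse(c(clusters[[i]], clusters[[j]])) - sse(clusters[[i]]) -
          sse(clusters[[j]])
        better <- d < bestd - 1e-12
        tie <- !better && d < bestd + 1e-12
        if (tie && !is.null(best)) {
          cand <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
          cur <- sort(c(min(clusters[[best[1]]]), min(clusters[[best[2]]])))
          better <- cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])
        }
        if (better) { bestd <- min(bestd, d); best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges <- c(merges, list(merged))
    heights <- c(heights, bestd)
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# Merged leaf sets per step of a ward_clust, for comparison with the oracle.
ward_merge_sets <- function(wc) {
  members <- function(node) {
    if (node < 0) return(-node)
    c(members(wc$merge[node, 1]), members(wc$merge[node, 2]))
  }
  lapply(seq_len(nrow(wc$merge)), function(s) {
    sort(c(members(wc$merge[s, 1]), members(wc$merge[s, 2])))
  })
}

# Exhaustive row/column-subset search for the coverage criterion: among all
# subsets where every kept column covers >= min_frac of kept rows and vice
# versa, return those maximizing the number of observed cells.
brute_force_coverage <- function(obs, min_frac) {
  nr <- nrow(obs); nc <- ncol(obs)
  best <- list(cells = -1, rows = list(), cols = list())
  for (rmask in 1:(2^nr - 1)) {
    rows <- which(bitwAnd(rmask, 2^(seq_len(nr) - 1)) > 0)
    for (cmask in 1:(2^nc - 1)) {
      cols <- which(bitwAnd(cmask, 2^(seq_len(nc) - 1)) > 0)
      sub <- obs[rows, cols, drop = FALSE]
      if (any(colMeans(sub) < min_frac) || any(rowMeans(sub) < min_frac)) next
      cells <- sum(sub)
      if (cells > best$cells) {
        best <- list(cells = cells, rows = list(rows), cols = list(cols))
      } else if (cells == best$cells) {
        best$rows <- c(best$rows, list(rows))
        best$cols <- c(best$cols, list(cols))
      }
    }
  }
  best
}

# Adjusted Rand index between two labelings (Hubert & Arabie form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small complete trait table on a handful of species.
tiny_trait_table <- function() {
  trait_table(tibble::tibble(
    species = c("s1", "s2", "s3", "s4"),
    genus = c("g1", "g1", "g2", "g2"),
    Height = c(0.2, 0.4, 0.6, 0.8),
    LL = c(20, 30, 40, 50),
    LW = c(2, 3, 4, 5),
    TC = c(0, 10, 100, 400),
    d13C = c(-14, -15, -28, -29),
    PB = c(0, 1, 0, 0)
  ))
}

# Verify a compact letter display against its pairwise p matrix: groups
# sharing a letter must have p >= alpha, groups sharing none must have
# p < alpha (NA pairs are unconstrained).
check_cld_consistency <- function(letters_vec, pmat, alpha) {
  groups <- names(letters_vec)
  for (i in seq_along(groups)[-length(groups)]) {
    for (j in (i + 1):length(groups)) {
      pij <- pmat[groups[i], groups[j]]
      if (is.na(pij)) next
      shared <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                                 strsplit(letters_vec[j], "")[[1]])) > 0
      if (shared && pij < alpha) return(FALSE)
      if (!shared && pij >= alpha) return(FALSE)
    }
  }
  TRUE
}
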