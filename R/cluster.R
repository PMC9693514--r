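#' Ward minimum-variance agglomerative clustering
#'
#' Agglomerates the rows of a numeric matrix by, at each step, merging the
#' pair of clusters whose fusion least increases the total within-cluster
#' sum of squared Euclidean distances (Ward's criterion). The increase for
#' clusters A, B with centroids \eqn{c_A, c_B} and sizes \eqn{n_A, n_B} is
#' \deqn{\Delta SSE = \frac{n_A n_B}{n_A + n_B} \lVert c_A - c_B \rVert^2,}
#' maintained incrementally from cluster centroids and sizes. Merge heights
#' are stored on this \eqn{\Delta SSE} scale, so two singletons merge at
#' half their squared distance; the merge sequence is identical to the
#' squared-Euclidean Ward criterion of `hclust(method = "ward.D2")`, whose
#' heights are `sqrt(2 * height)` on our scale. Ties are broken
#' deterministically in favour of the pair with lexicographically smallest
#' leaf indices.
#'
#' @param mat Numeric matrix (rows are items to cluster, e.g. species on the
#'   0-1 trait scale); at least 2 rows, no missing values.
#' @return A `ward_clust` object: list with `merge` (hclust-style merge
#'   matrix), `height` (\eqn{\Delta SSE} per merge, non-decreasing),
#'   `labels`, and `order` (leaf display order).
#' @export
ward_linkage <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) rlang::abort("ward_linkage: matrix contains missing values")
  n <- nrow(mat)
  if (n < 2) rlang::abort("ward_linkage: need at least 2 rows")
  labels <- rownames(mat)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  centroid <- mat
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  # cluster id in hclust convention: -leaf before first merge, merge step after
  node <- -seq_len(n)
  min_leaf <- seq_len(n)

  dmat <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    d2 <- colSums((t(centroid[(i + 1):n, , drop = FALSE]) - centroid[i, ])^2)
    dmat[i, (i + 1):n] <- d2 / 2
  }

  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    act <- which(active)
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      js <- act[act > i]
      ds <- dmat[i, js]
      k <- which.min(ds)
      if (ds[k] < best_d - 1e-12) {
        best_d <- ds[k]; best <- c(i, js[k])
      } else if (ds[k] < best_d + 1e-12) {
        # tie: prefer lexicographically smaller (min leaf of i, then of j)
        cand <- c(i, js[k])
        if (min_leaf[cand[1]] < min_leaf[best[1]] ||
            (min_leaf[cand[1]] == min_leaf[best[1]] &&
             min_leaf[cand[2]] < min_leaf[best[2]])) {
          best_d <- min(best_d, ds[k]); best <- cand
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort_pair(node[i], node[j])
    height[step] <- best_d

    ni <- size[i]; nj <- size[j]
    new_centroid <- (ni * centroid[i, ] + nj * centroid[j, ]) / (ni + nj)
    centroid[i, ] <- new_centroid
    size[i] <- ni + nj
    node[i] <- step
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
    active[j] <- FALSE

    for (k in which(active)) {
      if (k == i) next
      dk <- sum((centroid[k, ] - new_centroid)^2)
      d <- size[i] * size[k] / (size[i] + size[k]) * dk
      if (k < i) dmat[k, i] <- d else dmat[i, k] <- d
    }
  }
  structure(
    list(merge = merge, height = height, labels = labels,
         order = merge_order(merge, n)),
    class = "ward_clust"
  )
}

sort_pair <- function(a, b) {
  # hclust convention: singletons (negative) before clusters, else ascending
  if ((a < 0 && b < 0 && a > b) || (a > 0 && b < 0) || (a > 0 && b > 0 && a > b)) {
    c(b, a)
  } else {
    c(a, b)
  }
}

merge_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1)
}

#' @export
print.ward_clust <- function(x, ...) {
  cat(sprintf("Ward clustering of %d items (%d merges)\n",
              length(x$labels), nrow(x$merge)))
  cat(sprintf("  merge heights (within-SSE increase): %.4g .. %.4g\n",
              min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a Ward clustering to an hclust object
#'
#' @param x A `ward_clust`.
#' @param scale `"delta_sse"` keeps the package's height convention;
#'   `"ward.D2"` rescales heights to `sqrt(2 * h)`, matching
#'   `stats::hclust(method = "ward.D2")`.
#' @return An object of class `hclust` (usable with `plot()`, `cutree()`,
#'   `cophenetic()` and dendrogram tooling).
#' @export
as_hclust <- function(x, scale = c("delta_sse", "ward.D2")) {
  scale <- match.arg(scale)
  h <- if (scale == "ward.D2") sqrt(2 * x$height) else x$height
  structure(
    list(merge = x$merge, height = h, order = x$order, labels = x$labels,
         method = "ward", call = match.call(),
         dist.method = "euclidean"),
    class = "hclust"
  )
}

#' Serialize a Ward clustering
#'
#' Writes the merge list as CSV (`step`, `members_a`, `members_b`,
#' `height`) and, optionally, a newick string with node heights.
#'
#' @param x A `ward_clust`.
#' @param csv_path,newick_path Output paths (`NULL` to skip either).
#' @export
write_linkage <- function(x, csv_path = NULL, newick_path = NULL) {
  if (!is.null(csv_path)) {
    members <- function(node) {
      if (node < 0) return(x$labels[-node])
      c(members(x$merge[node, 1]), members(x$merge[node, 2]))
    }
    df <- purrr::map_dfr(seq_len(nrow(x$merge)), function(s) {
      tibble::tibble(
        step = s,
        members_a = paste(members(x$merge[s, 1]), collapse = ";"),
        members_b = paste(members(x$merge[s, 2]), collapse = ";"),
        height = x$height[s]
      )
    })
    readr::write_csv(df, csv_path)
  }
  if (!is.null(newick_path)) {
    phy <- ape::as.phylo(as_hclust(x))
    ape::write.tree(phy, file = newick_path)
  }
  invisible(x)
}

#' Two-way Ward clustering of a species-by-trait matrix
#'
#' Clusters species on their trait vectors and traits on their species
#' vectors (the transposed matrix), and reorders the matrix by both leaf
#' orders for heatmap display.
#'
#' @param mat Numeric matrix (species x traits, typically 0-1 scaled).
#' @return A list with `species_tree` and `trait_tree` (`ward_clust`
#'   objects; `trait_tree` is `NULL` for a single column) and `matrix`, the
#'   input reordered by both trees.
#' @export
two_way_cluster <- function(mat) {
  mat <- as.matrix(mat)
  sp_tree <- ward_linkage(mat)
  tr_tree <- if (ncol(mat) >= 2) ward_linkage(t(mat)) else NULL
  ord_rows <- sp_tree$order
  ord_cols <- if (is.null(tr_tree)) seq_len(ncol(mat)) else tr_tree$order
  list(species_tree = sp_tree, trait_tree = tr_tree,
       matrix = mat[ord_rows, ord_cols, drop = FALSE])
}

#' Cut a Ward clustering into k groups
#'
#' Removes the k-1 highest merges (equivalently, keeps the first n-k,
#' heights being monotone) and labels the components 1..k, ids assigned in
#' order of each cluster's smallest member index, so partitions for
#' successive k are nested and stably numbered.
#'
#' @param x A `ward_clust`.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return A tibble with columns `species` (leaf label) and `cluster`.
#' @export
cut_tree <- function(x, k) {
  n <- length(x$labels)
  if (k < 1 || k > n) rlang::abort("cut_tree: k out of range")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_root <- integer(n - 1)
  n_used <- n - k
  for (s in seq_len(n_used)) {
    a <- x$merge[s, 1]; b <- x$merge[s, 2]
    ra <- find(if (a < 0) -a else node_root[a])
    rb <- find(if (b < 0) -b else node_root[b])
    parent[rb] <- ra
    node_root[s] <- ra
  }
  if (n_used < n - 1) {
    for (s in (n_used + 1):(n - 1)) {
      a <- x$merge[s, 1]
      node_root[s] <- find(if (a < 0) -a else node_root[a])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  first_member <- tapply(seq_len(n), roots, min)
  ids <- rank(first_member)   # stable ids by smallest member index
  cluster <- ids[as.character(roots)]
  tibble::tibble(species = x$labels, cluster = as.integer(cluster))
}
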