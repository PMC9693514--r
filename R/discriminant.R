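#' Fit a discriminant model on labelled trait space
#'
#' Group centroids are the group means in transformed trait space; the
#' pooled within-group covariance is the within-group scatter divided by
#' `n - g`. Because the trait dimension (16) is close to the smallest group
#' sizes, the pooled covariance is shrunk toward its own diagonal,
#' `(1 - lambda) * S + lambda * diag(diag(S))`, before inversion. The model
#' classifies points by minimum squared Mahalanobis distance to the
#' centroids, which is used both to validate the separation of the
#' functional groups and to report their pairwise separations.
#'
#' @param mat Numeric matrix of points (rows) in transformed trait space.
#' @param labels Group label per row; at least 2 groups with at least 2
#'   members each.
#' @param lambda Shrinkage weight toward the diagonal, default 0.01.
#' @return A `brom_da` object: `centroids` (g x p), `pooled_cov`,
#'   `pooled_inv`, `sizes`, `lambda`.
#' @export
fit_discriminant <- function(mat, labels, lambda = 0.01) {
  mat <- as.matrix(mat)
  labels <- as.character(labels)
  if (length(labels) != nrow(mat)) rlang::abort("one label per row required")
  sizes <- table(labels)
  if (length(sizes) < 2) rlang::abort("need at least 2 groups")
  if (any(sizes < 2)) {
    rlang::abort(paste0("groups with < 2 members: ",
                        paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  groups <- names(sizes)
  p <- ncol(mat)
  centroids <- do.call(rbind, lapply(groups, function(g) {
    colMeans(mat[labels == g, , drop = FALSE])
  }))
  rownames(centroids) <- groups
  scatter <- matrix(0, p, p)
  for (g in groups) {
    xg <- sweep(mat[labels == g, , drop = FALSE], 2, centroids[g, ])
    scatter <- scatter + crossprod(xg)
  }
  S <- scatter / (nrow(mat) - length(groups))
  # a trait with no within-group variation (e.g. a binary flag constant in
  # every group) gets the average within-group variance of the other traits,
  # so it stays informative without degenerating the metric
  d <- diag(S)
  zero <- d <= 1e-12 * max(d, 1e-300)
  if (any(zero) && !all(zero)) {
    iz <- which(zero)
    S[iz, ] <- 0
    S[, iz] <- 0
    S[cbind(iz, iz)] <- mean(d[!zero])
  }
  S <- (1 - lambda) * S + lambda * diag(diag(S), p)
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) {
    rlang::abort(paste0("pooled covariance singular even after shrinkage; ",
                        "reduce the trait dimension or raise lambda"))
  })
  colnames(centroids) <- colnames(mat)
  structure(
    list(centroids = centroids, pooled_cov = S, pooled_inv = Sinv,
         sizes = as.integer(sizes), groups = groups, lambda = lambda),
    class = "brom_da"
  )
}

#' @export
print.brom_da <- function(x, ...) {
  cat(sprintf("Discriminant model: %d groups, %d traits (shrinkage lambda = %g)\n",
              length(x$groups), ncol(x$centroids), x$lambda))
  print(stats::setNames(x$sizes, x$groups))
  invisible(x)
}

#' Classify points by minimum squared Mahalanobis distance
#'
#' @param object A `brom_da` model.
#' @param newdata Matrix of points in the model's trait space.
#' @param ... Unused.
#' @return A tibble with `species` (rownames, if any), the assigned `group`,
#'   and the squared Mahalanobis distance to each centroid.
#' @export
predict.brom_da <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  d2 <- vapply(object$groups, function(g) {
    diff <- sweep(newdata, 2, object$centroids[g, ])
    rowSums((diff %*% object$pooled_inv) * diff)
  }, numeric(nrow(newdata)))
  d2 <- matrix(d2, nrow = nrow(newdata),
               dimnames = list(rownames(newdata), object$groups))
  assigned <- object$groups[apply(d2, 1, which.min)]
  out <- tibble::tibble(
    species = rownames(newdata) %||% as.character(seq_len(nrow(newdata))),
    group = assigned
  )
  dplyr::bind_cols(out, tibble::as_tibble(d2, .name_repair = "minimal"))
}

#' Pairwise squared Mahalanobis distances between group centroids
#'
#' Entry (i, j) is \eqn{(\mu_i - \mu_j)^\top \Sigma^{-1} (\mu_i - \mu_j)}
#' with the pooled (shrunk) covariance; symmetric with a zero diagonal.
#'
#' @param model A `brom_da`.
#' @return A g x g symmetric numeric matrix.
#' @export
mahalanobis_matrix <- function(model) {
  g <- length(model$groups)
  out <- matrix(0, g, g, dimnames = list(model$groups, model$groups))
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (i == j) next
      d <- model$centroids[i, ] - model$centroids[j, ]
      out[i, j] <- as.numeric(d %*% model$pooled_inv %*% d)
    }
  }
  (out + t(out)) / 2
}
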