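#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Spearman correlation matrix
#'
#' @param x A `brom_cor`.
#' @param ... Unused.
#' @return One row per unordered trait pair: `trait_a`, `trait_b`, `rho`,
#'   `p`, `n`, `significant`.
#' @method tidy brom_cor
#' @export
tidy.brom_cor <- function(x, ...) {
  traits <- rownames(x$rho)
  k <- length(traits)
  idx <- which(lower.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    trait_a = traits[idx[, 2]],
    trait_b = traits[idx[, 1]],
    rho = x$rho[idx],
    p = x$p[idx],
    n = x$n[idx],
    significant = x$significant[idx]
  )
}

#' @rdname tidy.brom_cor
#' @method glance brom_cor
#' @export
glance.brom_cor <- function(x, ...) {
  lt <- lower.tri(x$rho)
  tibble::tibble(
    n_traits = ncol(x$rho),
    n_pairs = sum(lt),
    n_defined = sum(!is.na(x$p[lt])),
    n_significant = sum(x$significant[lt]),
    alpha = x$alpha
  )
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [kw_posthoc()] or [anova_tukey()].
#' @param ... Unused.
#' @return The per-group summary tibble with the variable name prepended.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(variable = x$variable), x$summary)
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    variable = x$variable,
    method = x$method,
    statistic = x$statistic,
    df = paste(x$df, collapse = "/"),
    p.value = x$p,
    alpha = x$alpha
  )
}

#' Tidy a Ward clustering
#'
#' @param x A `ward_clust`.
#' @param ... Unused.
#' @return One row per merge: `step`, `a`, `b` (hclust coding: negative =
#'   leaf), `height` (within-SSE increase).
#' @method tidy ward_clust
#' @export
tidy.ward_clust <- function(x, ...) {
  tibble::tibble(
    step = seq_len(nrow(x$merge)),
    a = x$merge[, 1],
    b = x$merge[, 2],
    height = x$height
  )
}

#' @rdname tidy.ward_clust
#' @method glance ward_clust
#' @export
glance.ward_clust <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(x$labels),
    n_merges = nrow(x$merge),
    height_min = min(x$height),
    height_max = max(x$height)
  )
}

#' Tidy a discriminant model
#'
#' @param x A `brom_da`.
#' @param ... Unused.
#' @return Long tibble of centroids: `group`, `trait`, `centroid`.
#' @method tidy brom_da
#' @export
tidy.brom_da <- function(x, ...) {
  tibble::as_tibble(x$centroids, rownames = "group") |>
    tidyr::pivot_longer(-"group", names_to = "trait", values_to = "centroid")
}

#' @rdname tidy.brom_da
#' @method glance brom_da
#' @export
glance.brom_da <- function(x, ...) {
  tibble::tibble(
    n_groups = length(x$groups),
    n_traits = ncol(x$centroids),
    n = sum(x$sizes),
    lambda = x$lambda
  )
}

#' Tidy an imputation report
#'
#' @param x An `impute_report`.
#' @param ... Unused.
#' @return The per-cell records tibble (`species`, `trait`, `method`,
#'   `value`).
#' @method tidy impute_report
#' @export
tidy.impute_report <- function(x, ...) x$cells

#' @rdname tidy.impute_report
#' @method glance impute_report
#' @export
glance.impute_report <- function(x, ...) {
  tibble::tibble(
    n_missing_before = x$n_missing_before,
    n_imputed_phylo = x$n_imputed_phylo,
    n_rejected = x$n_rejected,
    n_imputed_genus = x$n_imputed_genus,
    n_left_empty = x$n_left_empty
  )
}
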