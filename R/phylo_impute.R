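#' Restrict a trait table to a set of traits
#'
#' @param tt A `trait_tbl`.
#' @param traits Character vector of trait abbreviations to keep.
#' @return A `trait_tbl` with only those trait columns (plus species, genus
#'   and morphology flags).
#' @export
select_traits <- function(tt, traits = clustering_traits(registry_of(tt))) {
  keep <- c("species", "genus", intersect(c("tankless", "acicular"), names(tt)),
            intersect(traits, names(tt)))
  rebuild_trait_tbl(tt[keep], tt,
                    provenance_of(tt)[intersect(traits, names(tt))])
}

#' Iterative 70% coverage filter
#'
#' Repeatedly removes traits observed for fewer than `min_frac` of the
#' species, then species observed for fewer than `min_frac` of the remaining
#' traits, until both criteria hold (traits first, then species, repeated to
#' a fixed point — a deterministic order).
#'
#' @param tt A `trait_tbl`.
#' @param min_frac Minimum coverage fraction, default 0.70.
#' @return The filtered `trait_tbl`; errors if nothing survives.
#' @export
coverage_filter <- function(tt, min_frac = 0.70) {
  if (nrow(tt) == 0) rlang::abort("coverage_filter: empty trait table")
  repeat {
    traits <- trait_cols(tt)
    if (length(traits) == 0 || nrow(tt) == 0) {
      rlang::abort("coverage filter removed all rows")
    }
    m <- !is.na(as.data.frame(tt[traits]))
    trait_cov <- colMeans(m)
    drop_tr <- names(trait_cov)[trait_cov < min_frac]
    if (length(drop_tr) > 0) {
      tt <- select_traits(tt, setdiff(traits, drop_tr))
      next
    }
    sp_cov <- rowMeans(m)
    drop_sp <- sp_cov < min_frac
    if (any(drop_sp)) {
      tt <- rebuild_trait_tbl(tt[!drop_sp, ], tt, provenance_of(tt)[!drop_sp, ])
      next
    }
    break
  }
  if (nrow(tt) == 0 || length(trait_cols(tt)) == 0) {
    rlang::abort("coverage filter removed all rows")
  }
  tt
}

#' Read and validate a newick phylogeny
#'
#' Parses a rooted tree with branch lengths via \pkg{ape} and checks the
#' invariants used downstream: unique tip labels, branch lengths present and
#' nonnegative.
#'
#' @param path Newick file path.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) rlang::abort(paste0("newick parse error: ",
                                                           conditionMessage(e))))
  if (is.null(tree)) rlang::abort("newick parse error: no tree found")
  validate_phylogeny(tree)
}

#' @rdname read_newick
#' @param tree A `phylo` object to validate or write.
#' @export
validate_phylogeny <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    rlang::abort(paste0("duplicated tip labels: ", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) rlang::abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) rlang::abort("negative branch length in tree")
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

new_impute_report <- function(cells, n_missing_before) {
  structure(
    list(
      n_missing_before = n_missing_before,
      n_imputed_phylo = sum(cells$method == "imputed_phylo"),
      n_rejected = sum(cells$method == "rejected"),
      n_imputed_genus = sum(cells$method == "imputed_genus"),
      n_left_empty = sum(cells$method == "left_empty"),
      cells = cells
    ),
    class = "impute_report"
  )
}

#' @export
print.impute_report <- function(x, ...) {
  cat("Imputation report\n")
  cat(sprintf("  missing before: %d\n", x$n_missing_before))
  cat(sprintf("  imputed (phylogenetic BM): %d (of which rejected: %d)\n",
              x$n_imputed_phylo, x$n_rejected))
  cat(sprintf("  imputed (genus mean): %d\n", x$n_imputed_genus))
  cat(sprintf("  left empty: %d\n", x$n_left_empty))
  invisible(x)
}

empty_cells_tbl <- function() {
  tibble::tibble(species = character(), trait = character(),
                 method = character(), value = numeric())
}

continuous_traits <- function(tt) {
  reg <- registry_of(tt)
  intersect(trait_cols(tt), reg$abbreviation[reg$kind == "continuous"])
}

#' Phylogenetic imputation under a multivariate Brownian-motion model
#'
#' Fits, by maximum likelihood with an EM algorithm over the missing
#' entries, a multivariate Brownian-motion model for the continuous traits
#' of the species present on the tree: an ancestral mean vector \eqn{\mu}
#' and a trait covariance rate matrix \eqn{R}, with tip covariance
#' \eqn{C \otimes R} where \eqn{C} is the shared branch-length matrix of
#' the tree. Each missing cell of a tree-member species is then replaced by
#' its conditional expectation given every observed cell, so the fill uses
#' both trait correlations and phylogenetic proximity. Species absent from
#' the tree are untouched (they fall through to the genus-mean stage);
#' binary and categorical traits are never imputed.
#'
#' @param tt A `trait_tbl`, typically restricted to the clustering traits.
#' @param tree A `phylo` with branch lengths; tips not present in `tt`
#'   are dropped with a warning.
#' @param max_iter,tol EM stopping rule: stop when the observed-data
#'   log-likelihood improves by less than `tol` (default 1e-8) or after
#'   `max_iter` (default 500) iterations.
#' @return A list with elements `table` (the imputed `trait_tbl`, filled
#'   cells tagged `imputed_phylo`), `report` (an imputation report), and
#'   `fit` (list with `mu`, `R`, `loglik`, `iterations`).
#' @export
impute_bm <- function(tt, tree, max_iter = 500, tol = 1e-8) {
  validate_phylogeny(tree)
  extra <- setdiff(tree$tip.label, tt$species)
  if (length(extra) > 0) {
    rlang::warn(paste0("dropping ", length(extra), " tree tips absent from trait table"))
    tree <- ape::drop.tip(tree, extra)
  }
  traits <- continuous_traits(tt)
  on_tree <- tt$species %in% tree$tip.label
  X_all <- as.matrix(as.data.frame(tt[traits]))
  rownames(X_all) <- tt$species
  n_missing_before <- sum(is.na(X_all))

  X <- X_all[tt$species[on_tree], , drop = FALSE]
  if (sum(is.na(X)) == 0) {
    return(list(table = tt, report = new_impute_report(empty_cells_tbl(),
                                                       n_missing_before),
                fit = NULL))
  }
  C <- ape::vcv(tree)[rownames(X), rownames(X)]
  fit <- bm_em(X, C, max_iter = max_iter, tol = tol)

  cells <- empty_cells_tbl()
  out <- tt
  miss <- which(is.na(X), arr.ind = TRUE)
  for (r in seq_len(nrow(miss))) {
    sp <- rownames(X)[miss[r, 1]]
    trn <- traits[miss[r, 2]]
    val <- fit$X_imputed[miss[r, 1], miss[r, 2]]
    out <- set_cells(out, sp, trn, val, "imputed_phylo")
    cells <- dplyr::bind_rows(cells, tibble::tibble(
      species = sp, trait = trn, method = "imputed_phylo", value = val))
  }
  list(table = out, report = new_impute_report(cells, n_missing_before),
       fit = fit[c("mu", "R", "loglik", "iterations")])
}

# EM for X ~ matrix-normal(1 mu', C, R) with missing entries.
# Stacked vectorization x = vec(t(X)) has covariance kron(C, R).
bm_em <- function(X, C, max_iter = 500, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  obs <- !is.na(X)
  if (any(colSums(obs) < 1)) {
    rlang::abort("impute_bm: a trait has no observed value on the tree")
  }
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e) {
    rlang::abort("tree covariance matrix is not positive definite")
  })
  one <- rep(1, n)
  wC <- as.numeric(one %*% Cinv %*% one)

  mu <- colMeans(X, na.rm = TRUE)
  Xc0 <- sweep(X, 2, mu)
  R <- diag(pmax(apply(Xc0, 2, stats::var, na.rm = TRUE), 1e-6), p)

  idx <- function(i, j) (i - 1L) * p + j   # stacked index, species-major
  miss <- which(!obs, arr.ind = TRUE)
  m_idx <- idx(miss[, 1], miss[, 2])
  obs_rc <- which(obs, arr.ind = TRUE)
  o_idx <- idx(obs_rc[, 1], obs_rc[, 2])
  x_full <- as.numeric(t(X))   # stacked, NAs at m_idx

  ll_old <- -Inf
  iters <- 0
  X_hat <- X
  repeat {
    iters <- iters + 1
    R <- (R + t(R)) / 2
    R <- R + diag(1e-8 * sum(diag(R)) / p, p)
    Sigma <- kronecker(C, R)
    mean_full <- rep(mu, times = n)

    Soo <- Sigma[o_idx, o_idx]
    ch <- tryCatch(chol(Soo), error = function(e) {
      rlang::abort(paste0("degenerate trait covariance during EM; ",
                          "consider genus-mean imputation instead"))
    })
    resid_o <- x_full[o_idx] - mean_full[o_idx]
    alpha <- backsolve(ch, forwardsolve(t(ch), resid_o))
    # observed-data log-likelihood
    ll <- -0.5 * (length(o_idx) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                    sum(resid_o * alpha))

    Smo <- Sigma[m_idx, o_idx, drop = FALSE]
    x_m <- mean_full[m_idx] + as.numeric(Smo %*% alpha)
    K <- backsolve(ch, forwardsolve(t(ch), t(Smo)))     # Soo^-1 Som
    V_mm <- Sigma[m_idx, m_idx, drop = FALSE] - Smo %*% K

    X_hat <- X
    X_hat[cbind(miss[, 1], miss[, 2])] <- x_m

    # M-step
    mu <- as.numeric((one %*% Cinv %*% X_hat) / wC)
    Xc <- sweep(X_hat, 2, mu)
    S1 <- t(Xc) %*% Cinv %*% Xc
    # second-moment correction: only missing-missing pairs have nonzero
    # conditional covariance
    W <- matrix(0, p, p)
    nm <- nrow(miss)
    for (r in seq_len(nm)) {
      ar <- miss[r, 1]; jr <- miss[r, 2]
      for (s in seq_len(nm)) {
        W[jr, miss[s, 2]] <- W[jr, miss[s, 2]] + Cinv[ar, miss[s, 1]] * V_mm[r, s]
      }
    }
    R <- (S1 + W) / n

    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    if (iters >= max_iter) break
    ll_old <- ll
  }
  list(mu = mu, R = R, loglik = ll, iterations = iters, X_imputed = X_hat)
}

#' Reject phylogenetically imputed values outside the observed range
#'
#' The expected range of a trait is defined by the data: the minimum and
#' maximum over cells that were not phylogenetically imputed. Any
#' `imputed_phylo` cell strictly outside that range is reverted to missing
#' and counted as rejected (it re-enters the genus-mean pool).
#'
#' @param tt A `trait_tbl` after [impute_bm()].
#' @param report The corresponding imputation report.
#' @return A list with the cleaned `table` and the updated `report`.
#' @export
reject_out_of_range <- function(tt, report) {
  prov <- provenance_of(tt)
  cells <- report$cells
  for (tr in continuous_traits(tt)) {
    imp <- !is.na(prov[[tr]]) & prov[[tr]] == "imputed_phylo"
    if (!any(imp)) next
    base <- tt[[tr]][!is.na(tt[[tr]]) & !imp]
    if (length(base) == 0) next
    lo <- min(base); hi <- max(base)
    bad <- imp & !is.na(tt[[tr]]) & (tt[[tr]] < lo | tt[[tr]] > hi)
    if (any(bad)) {
      sp_bad <- tt$species[bad]
      cells$method[cells$trait == tr & cells$species %in% sp_bad &
                     cells$method == "imputed_phylo"] <- "rejected"
      tt[[tr]][bad] <- NA_real_
      prov[[tr]][bad] <- NA_character_
    }
  }
  attr(tt, "provenance") <- prov
  list(table = tt, report = new_impute_report(cells, report$n_missing_before))
}

#' Genus-mean fallback imputation
#'
#' Fills each remaining missing continuous cell with the arithmetic mean of
#' the non-missing values of the same trait among other species of the same
#' genus. Cells with no genus reference (monotypic genus, or genus entirely
#' missing for that trait) are left empty.
#'
#' @param tt A `trait_tbl` with genus annotation.
#' @param report Optional imputation report to extend (from earlier stages).
#' @return A list with the imputed `table` and the updated `report`.
#' @export
impute_genus_mean <- function(tt, report = NULL) {
  cells <- if (is.null(report)) empty_cells_tbl() else report$cells
  n_before <- if (is.null(report)) sum(is.na(as.data.frame(tt[continuous_traits(tt)])))
              else report$n_missing_before
  for (tr in continuous_traits(tt)) {
    i_missing <- which(is.na(tt[[tr]]))
    for (i in i_missing) {
      g <- tt$genus[i]
      ref <- tt[[tr]][!is.na(tt[[tr]]) & tt$genus == g & tt$species != tt$species[i]]
      if (!is.na(g) && length(ref) > 0) {
        val <- mean(ref)
        tt <- set_cells(tt, tt$species[i], tr, val, "imputed_genus")
        cells <- dplyr::bind_rows(cells, tibble::tibble(
          species = tt$species[i], trait = tr, method = "imputed_genus", value = val))
      } else {
        cells <- dplyr::bind_rows(cells, tibble::tibble(
          species = tt$species[i], trait = tr, method = "left_empty",
          value = NA_real_))
      }
    }
  }
  list(table = tt, report = new_impute_report(cells, n_before))
}

#' Full gap-filling chain
#'
#' Coverage filter, then (when a tree is supplied) phylogenetic
#' Brownian-motion imputation with out-of-range rejection, then genus-mean
#' fallback. Observed cells are never altered.
#'
#' @inheritParams impute_bm
#' @param tree Optional phylogeny; `NULL` skips straight to genus means.
#' @param min_frac Coverage threshold passed to [coverage_filter()].
#' @return A list with `table` and `report`.
#' @export
impute_traits <- function(tt, tree = NULL, min_frac = 0.70, max_iter = 500,
                          tol = 1e-8) {
  tt <- coverage_filter(tt, min_frac = min_frac)
  if (!is.null(tree)) {
    step <- impute_bm(tt, tree, max_iter = max_iter, tol = tol)
    step <- reject_out_of_range(step$table, step$report)
    impute_genus_mean(step$table, step$report)
  } else {
    impute_genus_mean(tt)
  }
}

#' Write an imputation report
#'
#' Per-cell records as CSV plus a JSON summary of the stage counts.
#'
#' @param report An imputation report.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_impute_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(report$cells, csv_path, na = "")
  if (!is.null(json_path)) {
    jsonlite::write_json(report[c("n_missing_before", "n_imputed_phylo",
                                  "n_rejected", "n_imputed_genus",
                                  "n_left_empty")],
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
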