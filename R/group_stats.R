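#' Spearman rank correlation matrix across traits
#'
#' Pairwise-complete Spearman rho over the continuous traits, with midranks
#' for ties and two-sided p-values from the t approximation
#' (`stats::cor.test`). Pairs with fewer than 3 complete observations are
#' undefined (`NA`). No multiple-testing correction is applied by default
#' (set `adjust = "holm"` for a corrected significance mask).
#'
#' @param tt A `trait_tbl` or data frame of trait columns.
#' @param alpha Significance level for the mask, default 0.05.
#' @param adjust P-value adjustment method (`"none"` default, any
#'   [stats::p.adjust()] method otherwise), applied to the lower-triangle
#'   p-values for the significance mask only.
#' @return A `brom_cor` object: `rho`, `p`, `n` matrices, `significant`
#'   logical mask, `alpha`.
#' @export
spearman_matrix <- function(tt, alpha = 0.05, adjust = "none") {
  df <- if (inherits(tt, "trait_tbl")) {
    as.data.frame(tt[continuous_traits(tt)])
  } else {
    df0 <- as.data.frame(tt)
    df0[vapply(df0, is.numeric, logical(1))]
  }
  traits <- names(df)
  k <- length(traits)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  nmat <- matrix(0L, k, k, dimnames = list(traits, traits))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k)) nmat[i, i] <- sum(!is.na(df[[i]]))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- !is.na(df[[i]]) & !is.na(df[[j]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3) next
      x <- df[[i]][ok]; y <- df[[j]][ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE)
      )
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  p_mask <- p
  if (adjust != "none") {
    lower <- lower.tri(p)
    p_mask[lower] <- stats::p.adjust(p[lower], method = adjust)
    p_mask[upper.tri(p_mask)] <- t(p_mask)[upper.tri(p_mask)]
  }
  sig <- !is.na(p_mask) & p_mask < alpha
  diag(sig) <- FALSE
  structure(
    list(rho = rho, p = p, n = nmat, significant = sig,
         alpha = alpha, adjust = adjust),
    class = "brom_cor"
  )
}

#' @export
print.brom_cor <- function(x, ...) {
  k <- ncol(x$rho)
  cat(sprintf("Spearman correlation matrix: %d traits, %d pairs, %d significant at alpha = %g\n",
              k, k * (k - 1) / 2, sum(x$significant[lower.tri(x$significant)]),
              x$alpha))
  invisible(x)
}

#' Filter strong correlations
#'
#' Reports trait pairs with p below `alpha` and rho^2 above `r2_min`
#' (default 0.60, i.e. |rho| > 0.775).
#'
#' @param x A `brom_cor`.
#' @param alpha Significance threshold.
#' @param r2_min Minimum squared correlation.
#' @return A tibble of pairs with `trait_a`, `trait_b`, `rho`, `p`, `n`.
#' @export
strong_correlations <- function(x, alpha = 0.05, r2_min = 0.60) {
  tidy(x) |>
    dplyr::filter(!is.na(.data$p), .data$p < alpha, .data$rho^2 > r2_min)
}

# Greedy insert-absorb compact letter display from a pairwise p matrix.
# Groups sharing a letter are not significantly different; every
# non-significant pair shares at least one letter.
cld_letters <- function(pmat, alpha) {
  groups <- rownames(pmat)
  sets <- list(groups)
  for (i in seq_along(groups)[-length(groups)]) {
    for (j in (i + 1):length(groups)) {
      pij <- pmat[i, j]
      if (is.na(pij) || pij >= alpha) next
      gi <- groups[i]; gj <- groups[j]
      new_sets <- list()
      for (s in sets) {
        if (gi %in% s && gj %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, gi)), list(setdiff(s, gj)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[a] && all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))]
  out <- vapply(groups, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  out
}

new_group_comparison <- function(variable, method, summary, statistic, df, p,
                                 pairwise, alpha, data = NULL) {
  structure(
    list(variable = variable, method = method, summary = summary,
         statistic = statistic, df = df, p = p, pairwise = pairwise,
         alpha = alpha, data = data),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  stat_name <- if (x$method == "kruskal-wallis") "H" else "F"
  cat(sprintf("%s comparison of %s: %s = %.3f, df = %s, p = %.4g\n",
              x$method, x$variable, stat_name, x$statistic,
              paste(x$df, collapse = "/"), x$p))
  print(x$summary)
  invisible(x)
}

prep_groups <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    rlang::warn(paste0("excluding groups with < 2 observations: ",
                       paste(small, collapse = ", ")))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  list(values = values, groups = factor(groups))
}

#' Kruskal-Wallis test with Wilcoxon rank-sum post hoc and letters
#'
#' Omnibus Kruskal-Wallis H (tie-corrected, chi-square p on g-1 degrees of
#' freedom) followed by two-sided pairwise Wilcoxon rank-sum tests (exact
#' for groups of at most 10 without ties, normal approximation with tie and
#' continuity correction otherwise) and a compact letter display from the
#' unadjusted pairwise p matrix: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param values Numeric measurements.
#' @param groups Group label per measurement; groups with fewer than 2
#'   observations are excluded with a warning.
#' @param alpha Significance level, default 0.05.
#' @param variable Name used in reports.
#' @return A `group_comparison`: per-group `summary` tibble (n, median,
#'   mean, letters), omnibus `statistic`, `df`, `p`, and the `pairwise`
#'   p matrix.
#' @export
kw_posthoc <- function(values, groups, alpha = 0.05, variable = "value") {
  d <- prep_groups(values, groups)
  lv <- levels(d$groups)
  if (length(lv) < 2) rlang::abort("kw_posthoc: need at least 2 usable groups")

  if (stats::sd(d$values) == 0) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(d$values, d$groups)
    H <- unname(kt$statistic); p <- kt$p.value
  }
  pm <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)[-length(lv)]) {
    for (j in (i + 1):length(lv)) {
      xi <- d$values[d$groups == lv[i]]
      xj <- d$values[d$groups == lv[j]]
      if (stats::sd(c(xi, xj)) == 0) {
        pij <- 1
      } else {
        use_exact <- length(xi) <= 10 && length(xj) <= 10 &&
          !any(duplicated(c(xi, xj)))
        pij <- suppressWarnings(
          stats::wilcox.test(xi, xj, exact = use_exact, correct = TRUE)$p.value
        )
      }
      pm[i, j] <- pm[j, i] <- pij
    }
  }
  letters_by_group <- cld_letters(pm, alpha)
  summary <- tibble::tibble(
    group = lv,
    n = as.integer(table(d$groups)),
    median = as.numeric(tapply(d$values, d$groups, stats::median)),
    mean = as.numeric(tapply(d$values, d$groups, mean)),
    letters = unname(letters_by_group[lv])
  )
  new_group_comparison(variable, "kruskal-wallis", summary, H,
                       length(lv) - 1, p, pm, alpha,
                       tibble::tibble(value = d$values, group = d$groups))
}

#' One-way ANOVA with Tukey HSD post hoc and letters
#'
#' One-way F test followed by Tukey honest significant differences from the
#' studentized range, and the same compact letter display as
#' [kw_posthoc()]. Used for variables whose distribution is adequately
#' normal (leaf water content on an area basis in the source analysis).
#'
#' @inheritParams kw_posthoc
#' @return A `group_comparison`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05, variable = "value") {
  d <- prep_groups(values, groups)
  lv <- levels(d$groups)
  if (length(lv) < 2) rlang::abort("anova_tukey: need at least 2 usable groups")
  fit <- stats::aov(d$values ~ d$groups)
  tab <- summary(fit)[[1]]
  Fval <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  tuk <- stats::TukeyHSD(fit)[[1]]
  pm <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  pairs <- strsplit(rownames(tuk), "-", fixed = TRUE)
  for (r in seq_along(pairs)) {
    a <- pairs[[r]][1]; b <- pairs[[r]][2]
    pm[a, b] <- pm[b, a] <- tuk[r, "p adj"]
  }
  letters_by_group <- cld_letters(pm, alpha)
  summary <- tibble::tibble(
    group = lv,
    n = as.integer(table(d$groups)),
    median = as.numeric(tapply(d$values, d$groups, stats::median)),
    mean = as.numeric(tapply(d$values, d$groups, mean)),
    letters = unname(letters_by_group[lv])
  )
  new_group_comparison(variable, "anova", summary, Fval,
                       c(length(lv) - 1, length(d$values) - length(lv)), p,
                       pm, alpha,
                       tibble::tibble(value = d$values, group = d$groups))
}

#' FAO-style ecological zone vocabulary
#'
#' The declared vocabulary for occurrence-record ecozone labels.
#' @export
fao_ecozones <- function() {
  c("Tropical rainforest", "Tropical moist forest", "Tropical dry forest",
    "Tropical shrubland", "Tropical desert", "Tropical mountain system",
    "Subtropical humid forest", "Subtropical dry forest",
    "Subtropical desert", "Subtropical mountain system",
    "Temperate oceanic forest", "Temperate mountain system")
}

#' Environmental variables of occurrence records
#' @export
env_variables <- function() c("VPD", "PPT", "TMIN", "TMAX", "ET0", "AI", "Elev")

#' Read occurrence-environment records
#'
#' CSV with header `species,lat,lon,VPD,PPT,TMIN,TMAX,ET0,AI,Elev,ecozone`.
#' Coordinates are validated; ecozone labels outside the declared
#' vocabulary ([fao_ecozones()]) produce a warning.
#'
#' @param path CSV path.
#' @return A tibble of records.
#' @export
read_env_records <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_env_records(df)
}

#' @rdname read_env_records
#' @param records Records tibble to validate or write.
#' @export
validate_env_records <- function(records) {
  if (any(!is.na(records$lat) & abs(records$lat) > 90) ||
      any(!is.na(records$lon) & abs(records$lon) > 180)) {
    rlang::abort("coordinates out of range in records")
  }
  unknown <- setdiff(unique(records$ecozone), c(fao_ecozones(), NA))
  if (length(unknown) > 0) {
    rlang::warn(paste0("ecozone labels outside the declared vocabulary: ",
                       paste(unknown, collapse = ", ")))
  }
  tibble::as_tibble(records)
}

#' @rdname read_env_records
#' @export
write_env_records <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Species richness per functional group and ecological zone
#'
#' Counts, for each group and zone, the number of distinct species with at
#' least one record in the zone: presence, not abundance, so duplicated
#' records of a species in a zone count once.
#'
#' @param records Records tibble with `species` and `ecozone`.
#' @param labels Tibble with `species` and `label`; records of unlabeled
#'   species are excluded with a warning.
#' @return A group x ecozone integer matrix.
#' @export
ecozone_presence <- function(records, labels) {
  if (is.data.frame(labels)) {
    lab <- stats::setNames(labels$label, labels$species)
  } else {
    lab <- labels
  }
  records <- tibble::as_tibble(records)
  records$label <- lab[records$species]
  if (anyNA(records$label)) {
    missing_sp <- unique(records$species[is.na(records$label)])
    rlang::warn(paste0("excluding records of unlabeled species: ",
                       paste(missing_sp, collapse = ", ")))
    records <- records[!is.na(records$label), ]
  }
  d <- dplyr::distinct(records, .data$label, .data$ecozone, .data$species)
  groups <- sort(unique(d$label))
  zones <- sort(unique(d$ecozone))
  out <- matrix(0L, length(groups), length(zones),
                dimnames = list(groups, zones))
  tab <- dplyr::count(d, .data$label, .data$ecozone)
  out[cbind(tab$label, tab$ecozone)] <- as.integer(tab$n)
  out
}

#' Compare environmental variables across functional groups
#'
#' Runs [kw_posthoc()] per environmental variable on raw records (each
#' record is a comparison unit; set `unit = "species_mean"` to collapse to
#' one mean per species first, a non-default mode).
#'
#' @param records Records tibble.
#' @param labels Tibble with `species`, `label`.
#' @param variables Variables to compare, default [env_variables()].
#' @param alpha Significance level.
#' @param unit `"record"` (default) or `"species_mean"`.
#' @return A named list of `group_comparison` objects; variables with
#'   fewer than 2 usable groups are skipped with a notice.
#' @export
env_group_compare <- function(records, labels, variables = env_variables(),
                              alpha = 0.05, unit = c("record", "species_mean")) {
  unit <- match.arg(unit)
  df <- dplyr::inner_join(tibble::as_tibble(records),
                          tibble::as_tibble(labels)[c("species", "label")],
                          by = "species")
  out <- list()
  for (v in intersect(variables, names(df))) {
    dv <- df[!is.na(df[[v]]) & !is.na(df$label), ]
    if (unit == "species_mean") {
      dv <- dv |>
        dplyr::group_by(.data$species, .data$label) |>
        dplyr::summarise(value = mean(.data[[v]]), .groups = "drop")
    } else {
      dv$value <- dv[[v]]
    }
    usable <- names(which(table(dv$label) >= 2))
    if (length(usable) < 2) {
      rlang::inform(paste0("env_group_compare: skipping ", v,
                           " (fewer than 2 usable groups)"))
      next
    }
    out[[v]] <- kw_posthoc(dv$value, dv$label, alpha = alpha, variable = v)
  }
  out
}
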