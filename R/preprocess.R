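#' Default per-trait transformation recipes
#'
#' Builds the transformation table applied before clustering: every
#' clustering trait is log10-transformed except nitrogen content (`N`) and
#' `d15N`, which stay raw, and the binary `PB`, which passes through; tank
#' capacity gets a +0.5 mL offset before the log so that tankless species
#' (0 mL) remain representable; `d13C` is converted to absolute value
#' before the log, which maps the most negative (most C3-like) signatures
#' to the largest transformed values. Every recipe ends with a min-max
#' rescale to \[0, 1\].
#'
#' @param registry Trait registry, default [default_registry()].
#' @param traits Traits to include; default the clustering set.
#' @return A tibble with columns `trait`, `recipe`
#'   (`none`/`log10`/`offset_then_log10`/`abs_then_log10`), `offset`,
#'   `rescale`.
#' @export
default_transform_spec <- function(registry = default_registry(),
                                   traits = clustering_traits(registry)) {
  purrr::map_dfr(traits, function(tr) {
    kind <- registry$kind[registry$abbreviation == tr]
    recipe <- if (tr %in% c("N", "d15N") || kind != "continuous") {
      "none"
    } else if (tr == "TC") {
      "offset_then_log10"
    } else if (tr == "d13C") {
      "abs_then_log10"
    } else {
      "log10"
    }
    tibble::tibble(trait = tr, recipe = recipe,
                   offset = if (tr == "TC") 0.5 else 0,
                   rescale = TRUE)
  })
}

apply_recipe <- function(x, recipe, offset, trait, species) {
  y <- switch(recipe,
    none = x,
    log10 = x,
    offset_then_log10 = x + offset,
    abs_then_log10 = abs(x),
    rlang::abort(paste0("unknown recipe: ", recipe))
  )
  if (recipe != "none") {
    bad <- y <= 0
    if (any(bad)) {
      rlang::abort(paste0("non-positive value entering log10 for trait ", trait,
                          " (species ", paste(species[bad], collapse = ", "), ")"))
    }
    y <- log10(y)
  }
  y
}

#' Transform clustering traits to the 0-1 analysis scale
#'
#' Applies each trait's recipe (see [default_transform_spec()]) and then
#' rescales each column to \[0, 1\] by `(x - min) / (max - min)`, computed
#' on the analysis set itself. Constant columns map to 0. All cells must be
#' non-missing (run the imputation chain first).
#'
#' @param tt A `trait_tbl` whose clustering cells are complete.
#' @param spec Transformation table, default [default_transform_spec()] for
#'   the traits present.
#' @return A numeric species-by-trait matrix with values in \[0, 1\];
#'   species as rownames. The per-trait back-transformation parameters are
#'   attached as attribute `"inverse"` (see [inverse_report()]).
#' @export
transform_traits <- function(tt, spec = NULL) {
  reg <- registry_of(tt)
  traits <- intersect(trait_cols(tt), reg$abbreviation[reg$kind != "categorical"])
  if (is.null(spec)) spec <- default_transform_spec(reg, traits)
  spec <- spec[spec$trait %in% traits, ]

  out <- matrix(NA_real_, nrow(tt), nrow(spec),
                dimnames = list(tt$species, spec$trait))
  inv <- tibble::tibble(trait = spec$trait, recipe = spec$recipe,
                        offset = spec$offset, min = NA_real_, max = NA_real_)
  for (r in seq_len(nrow(spec))) {
    tr <- spec$trait[r]
    x <- tt[[tr]]
    if (anyNA(x)) {
      rlang::abort(paste0("missing cell in trait ", tr,
                          " (species ", paste(tt$species[is.na(x)], collapse = ", "),
                          "); impute before transforming"))
    }
    y <- apply_recipe(x, spec$recipe[r], spec$offset[r], tr, tt$species)
    lo <- min(y); hi <- max(y)
    inv$min[r] <- lo; inv$max[r] <- hi
    out[, r] <- if (spec$rescale[r]) {
      if (hi > lo) (y - lo) / (hi - lo) else rep(0, length(y))
    } else y
  }
  attr(out, "inverse") <- inv
  out
}

#' Back-transformation parameters of a transformed matrix
#'
#' Returns, per trait, the recipe and the (post-recipe) min/max used for
#' rescaling, which suffice to map 0-1 coordinates back to raw units:
#' `raw = inverse_recipe(min + z * (max - min))`.
#'
#' @param mat A matrix produced by [transform_traits()].
#' @return A tibble with columns `trait`, `recipe`, `offset`, `min`, `max`.
#' @export
inverse_report <- function(mat) {
  inv <- attr(mat, "inverse")
  if (is.null(inv)) rlang::abort("matrix has no inverse-transform attribute")
  inv
}

#' Map transformed 0-1 values back to raw trait units
#'
#' @param z Numeric vector on the 0-1 scale.
#' @param trait Trait abbreviation.
#' @param inv Inverse table from [inverse_report()].
#' @return Raw-unit values.
#' @export
untransform <- function(z, trait, inv) {
  r <- inv[inv$trait == trait, ]
  if (nrow(r) != 1) rlang::abort(paste0("trait not in inverse table: ", trait))
  y <- r$min + z * (r$max - r$min)
  switch(r$recipe,
    none = y,
    log10 = 10^y,
    offset_then_log10 = 10^y - r$offset,
    abs_then_log10 = -(10^y)   # sign not recoverable; d13C values are negative
  )
}

#' Write a transformed matrix as CSV
#'
#' @param mat Matrix from [transform_traits()].
#' @param path Output path; species become the first column.
#' @export
write_transformed <- function(mat, path) {
  df <- tibble::as_tibble(mat)
  df <- dplyr::bind_cols(tibble::tibble(species = rownames(mat)), df)
  readr::write_csv(df, path)
  invisible(path)
}
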