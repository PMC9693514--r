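#' Build a species-by-trait table
#'
#' A trait table is a tibble with one row per species: a `species` column,
#' a `genus` column, optional morphology flags (`tankless`, `acicular`), and
#' one numeric column per registry trait (character for categorical traits
#' such as `PP`). Missing values are encoded as `NA`, never as sentinel
#' numbers. A per-cell provenance tibble (same shape as the trait columns,
#' values `measured`, `literature`, `herbarium`, `derived`, `imputed_phylo`,
#' `imputed_genus`, or `NA` for missing cells) travels as the `"provenance"`
#' attribute so derived and imputed data stay distinguishable from
#' measurements downstream.
#'
#' @param data A data frame with `species`, `genus` and trait columns.
#' @param registry Trait registry tibble, default [default_registry()].
#' @param provenance Optional provenance tibble; defaults to `"measured"`
#'   for every non-missing cell.
#' @return A validated `trait_tbl` (subclass of `tbl_df`).
#' @export
trait_table <- function(data, registry = default_registry(), provenance = NULL) {
  data <- tibble::as_tibble(data)
  if (!"species" %in% names(data)) rlang::abort("trait table needs a `species` column")
  if (!"genus" %in% names(data)) data$genus <- NA_character_
  data$species <- as.character(data$species)
  data$genus <- as.character(data$genus)

  traits <- intersect(registry$abbreviation, names(data))
  extra <- setdiff(names(data), c("species", "genus", "tankless", "acicular",
                                  registry$abbreviation))
  if (length(extra) > 0) {
    rlang::warn(paste0("ignoring unknown columns: ", paste(extra, collapse = ", ")))
    data <- data[setdiff(names(data), extra)]
  }
  for (tr in traits) {
    kind <- registry$kind[registry$abbreviation == tr]
    if (kind != "categorical") data[[tr]] <- as.numeric(data[[tr]])
  }
  keep <- c("species", "genus", intersect(c("tankless", "acicular"), names(data)), traits)
  data <- data[keep]

  if (is.null(provenance)) {
    provenance <- purrr::map_dfc(data[traits], function(col) {
      ifelse(is.na(col), NA_character_, "measured")
    })
  }
  provenance <- tibble::as_tibble(provenance)[traits]

  out <- structure(data,
    registry = registry,
    provenance = provenance,
    class = c("trait_tbl", class(tibble::tibble()))
  )
  validate_trait_table(out)
}

#' @export
print.trait_tbl <- function(x, ...) {
  n_tr <- length(trait_cols(x))
  cat(sprintf("# A trait table: %d species x %d traits\n", nrow(x), n_tr))
  NextMethod()
}

trait_cols <- function(tt) {
  intersect(attr(tt, "registry")$abbreviation, names(tt))
}

provenance_of <- function(tt) attr(tt, "provenance")

registry_of <- function(tt) attr(tt, "registry")

set_cells <- function(tt, species, trait, values, tag) {
  # low-level setter keeping values and provenance in sync
  prov <- provenance_of(tt)
  i <- match(species, tt$species)
  tt[[trait]][i] <- values
  prov[[trait]][i] <- tag
  attr(tt, "provenance") <- prov
  tt
}

rebuild_trait_tbl <- function(data, template, provenance) {
  structure(tibble::as_tibble(data),
    registry = registry_of(template),
    provenance = provenance,
    class = class(template)
  )
}

#' Validate a trait table
#'
#' Checks the structural invariants: unique species identifiers, finite
#' non-missing values, nonnegative tank capacity and trichome/stomatal
#' densities, positive leaf index, and binary traits restricted to 0/1.
#'
#' @param tt A `trait_tbl`.
#' @return `tt`, invisibly usable in pipes; errors describe the offending
#'   species and trait.
#' @export
validate_trait_table <- function(tt) {
  if (anyDuplicated(tt$species)) {
    dup <- unique(tt$species[duplicated(tt$species)])
    rlang::abort(paste0("duplicate species in trait table: ",
                        paste(dup, collapse = ", ")))
  }
  reg <- registry_of(tt)
  for (tr in trait_cols(tt)) {
    kind <- reg$kind[reg$abbreviation == tr]
    col <- tt[[tr]]
    if (kind == "categorical") next
    bad <- !is.na(col) & !is.finite(col)
    if (any(bad)) {
      rlang::abort(paste0("non-finite value for trait ", tr, " in species ",
                          paste(tt$species[bad], collapse = ", ")))
    }
    if (kind == "binary" && any(!is.na(col) & !(col %in% c(0, 1)))) {
      rlang::abort(paste0("binary trait ", tr, " has values outside {0,1}"))
    }
  }
  for (tr in intersect(c("TC", "TD", "SD"), names(tt))) {
    bad <- !is.na(tt[[tr]]) & tt[[tr]] < 0
    if (any(bad)) {
      rlang::abort(paste0(tr, " must be >= 0; offending species: ",
                          paste(tt$species[bad], collapse = ", ")))
    }
  }
  if ("LI" %in% names(tt) && any(!is.na(tt$LI) & tt$LI <= 0)) {
    rlang::abort("LI must be > 0 where present")
  }
  prov <- provenance_of(tt)
  for (tr in trait_cols(tt)) {
    mism <- xor(is.na(tt[[tr]]), is.na(prov[[tr]]))
    if (any(mism)) {
      rlang::abort(paste0("provenance out of sync with values for trait ", tr))
    }
  }
  tt
}

#' Read a trait table from CSV
#'
#' The CSV has a header `species,genus,<abbrev>,...` using registry
#' abbreviations, one row per species, `.` as decimal separator, and empty
#' cells for missing values. Unknown columns are reported and dropped.
#'
#' @inheritParams trait_table
#' @param path CSV file path.
#' @return A validated `trait_tbl`.
#' @export
read_trait_table <- function(path, registry = default_registry()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"))
  for (tr in intersect(registry$abbreviation[registry$kind != "categorical"],
                       names(df))) {
    if (!is.numeric(df[[tr]])) {
      bad <- which(!is.na(df[[tr]]) & is.na(suppressWarnings(as.numeric(df[[tr]]))))
      if (length(bad) > 0) {
        rlang::abort(paste0("non-numeric value in continuous trait ", tr,
                            " at row ", bad[1], " ('", df[[tr]][bad[1]], "')"))
      }
      df[[tr]] <- as.numeric(df[[tr]])
    }
  }
  for (fl in intersect(c("tankless", "acicular"), names(df))) {
    df[[fl]] <- as.logical(df[[fl]])
  }
  trait_table(df, registry)
}

#' Write a trait table to CSV
#'
#' Trait columns are emitted in registry order; missing cells become empty
#' strings, so `read_trait_table()` of the output reproduces the values and
#' the missingness mask exactly.
#'
#' @param tt A `trait_tbl`.
#' @param path Output CSV path.
#' @export
write_trait_table <- function(tt, path) {
  readr::write_csv(tibble::as_tibble(tt), path, na = "")
  invisible(path)
}

#' Drop species with too few observed traits
#'
#' Removes species whose number of non-missing trait values is below
#' `min_traits` (default 5: species observed for fewer than five traits are
#' excluded; a species with exactly five is retained).
#'
#' @param tt A `trait_tbl`.
#' @param min_traits Minimum number of non-missing traits to retain a species.
#' @return The filtered `trait_tbl`, with a `"removed"` attribute listing the
#'   dropped species and their trait counts.
#' @export
drop_sparse_species <- function(tt, min_traits = 5) {
  traits <- trait_cols(tt)
  n_obs <- rowSums(!is.na(as.data.frame(tt[traits])))
  keep <- n_obs >= min_traits
  removed <- tibble::tibble(species = tt$species[!keep], n_traits = n_obs[!keep])
  if (nrow(removed) > 0) {
    rlang::inform(paste0("drop_sparse_species: removed ", nrow(removed),
                         " species with < ", min_traits, " traits"))
  }
  out <- rebuild_trait_tbl(tt[keep, ], tt, provenance_of(tt)[keep, ])
  attr(out, "removed") <- removed
  out
}

#' Allometric leaf-area estimate from leaf width and length
#'
#' Bromeliad leaves are intermediate between a triangle and a rectangle, so
#' leaf area is estimated as `LA = LW * LL / 1.5` (cm2).
#'
#' @param LW Maximal leaf width (cm), > 0.
#' @param LL Leaf length (cm), > 0.
#' @return Estimated leaf area (cm2); vectorized.
#' @export
#' @examples
#' estimate_leaf_area(LW = 3, LL = 30) # 60
estimate_leaf_area <- function(LW, LL) {
  if (any(LW <= 0, na.rm = TRUE) || any(LL <= 0, na.rm = TRUE)) {
    rlang::abort("estimate_leaf_area: LW and LL must be > 0")
  }
  LW * LL / 1.5
}

#' Allometric tank-capacity estimate from leaf area
#'
#' Quadratic allometry `TC = 0.0041 LA^2 + 1.929 LA - 22.285` (mL), with
#' negative raw predictions (small leaves, LA below about 11.4 cm2) clamped
#' to 0 mL because a tank volume cannot be negative.
#'
#' @param LA Leaf area (cm2), > 0.
#' @return Estimated tank capacity (mL), >= 0; vectorized.
#' @export
#' @examples
#' estimate_tank_capacity(100) # 211.615
#' estimate_tank_capacity(5)   # 0 (raw prediction negative)
estimate_tank_capacity <- function(LA) {
  if (any(LA <= 0, na.rm = TRUE)) {
    rlang::abort("estimate_tank_capacity: LA must be > 0")
  }
  pmax(0, 0.0041 * LA^2 + 1.929 * LA - 22.285)
}

#' Photosynthetic-pathway call from leaf carbon isotope signature
#'
#' Leaf d13C of -20 permil or higher is called CAM; values below -20 are
#' called C3. The boundary itself is CAM.
#'
#' @param d13C Leaf carbon isotope signature (permil); `NA` yields no call.
#' @return A tibble with columns `label` (`"CAM"`/`"C3"`/`NA`) and `source`
#'   (`"measured-threshold"` where called, `NA` otherwise).
#' @export
#' @examples
#' call_pathway(c(-15.9, -28, -20))
call_pathway <- function(d13C) {
  if (any(!is.na(d13C) & !is.finite(d13C))) {
    rlang::abort("call_pathway: d13C must be finite")
  }
  label <- ifelse(is.na(d13C), NA_character_, ifelse(d13C >= -20, "CAM", "C3"))
  tibble::tibble(
    label = label,
    source = ifelse(is.na(label), NA_character_, "measured-threshold")
  )
}

#' Fill derived traits
#'
#' Applies the derivation chain in order, filling only missing cells and
#' tagging them with provenance `"derived"`:
#' leaf index `LI = LL / LW`; leaf area `LA` from [estimate_leaf_area()];
#' tank capacity `TC` from [estimate_tank_capacity()], except that species
#' flagged `tankless` get `TC = 0` (tank absence is morphological knowledge,
#' an input flag, never inferred); pathway `PP` from [call_pathway()] where
#' `d13C` is present. Idempotent: a second application changes nothing.
#'
#' @param tt A `trait_tbl`.
#' @return The augmented `trait_tbl`.
#' @export
fill_derived_traits <- function(tt) {
  has <- function(tr) tr %in% names(tt)

  if (has("LI") && has("LL") && has("LW")) {
    i <- which(is.na(tt$LI) & !is.na(tt$LL) & !is.na(tt$LW) & tt$LW > 0)
    if (length(i)) tt <- set_cells(tt, tt$species[i], "LI", tt$LL[i] / tt$LW[i], "derived")
  }
  if (has("LA") && has("LL") && has("LW")) {
    i <- which(is.na(tt$LA) & !is.na(tt$LL) & !is.na(tt$LW) & tt$LW > 0 & tt$LL > 0)
    if (length(i)) {
      tt <- set_cells(tt, tt$species[i], "LA",
                      estimate_leaf_area(tt$LW[i], tt$LL[i]), "derived")
    }
  }
  if (has("TC")) {
    tankless <- if ("tankless" %in% names(tt)) !is.na(tt$tankless) & tt$tankless else rep(FALSE, nrow(tt))
    i <- which(is.na(tt$TC) & tankless)
    if (length(i)) tt <- set_cells(tt, tt$species[i], "TC", 0, "derived")
    if (has("LA")) {
      i <- which(is.na(tt$TC) & !tankless & !is.na(tt$LA) & tt$LA > 0)
      if (length(i)) {
        tt <- set_cells(tt, tt$species[i], "TC",
                        estimate_tank_capacity(tt$LA[i]), "derived")
      }
    }
  }
  if (has("PP") && has("d13C")) {
    i <- which(is.na(tt$PP) & !is.na(tt$d13C))
    if (length(i)) {
      tt <- set_cells(tt, tt$species[i], "PP",
                      call_pathway(tt$d13C[i])$label, "derived")
    }
  }
  validate_trait_table(tt)
}
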