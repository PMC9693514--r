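#' Default functional-trait registry
#'
#' The 25-trait registry used throughout the package: abbreviation, full
#' name, unit, kind (continuous/binary/categorical), whether the trait is a
#' member of the 16-trait clustering set, and the compilation summary of the
#' source database (median, range, record/species/genus counts).
#'
#' Sixteen traits form the clustering set; the only non-continuous traits
#' are pseudobulb presence (`PB`, binary, in the clustering set) and
#' photosynthetic pathway (`PP`, categorical, outside it). Isotope columns
#' use ASCII codes `d13C` and `d15N` so they survive CSV headers.
#'
#' @return A tibble with one row per trait definition.
#' @export
#' @examples
#' default_registry()
#' sum(default_registry()$clustering_member)
default_registry <- function() {
  tibble::tribble(
    ~abbreviation, ~name, ~unit, ~kind, ~clustering_member,
      ~median, ~range_min, ~range_max, ~n_records, ~n_species, ~n_genera,
    "Height", "Adult plant height",                       "m",            "continuous", TRUE,  0.4,    0.03,   2.7,   507L,  126L, 16L,
    "FP",     "Force to punch",                           "N mm-1",       "continuous", FALSE, 1.4,    0.17,   6.2,   706L,  36L,  7L,
    "LA",     "Leaf area",                                "cm2",          "continuous", TRUE,  8678,   29,     1033,  1702L, 201L, 23L,
    "C",      "Leaf carbon content per dry mass",         "%",            "continuous", FALSE, 45.2,   27.9,   69.3,  502L,  59L,  11L,
    "d13C",   "Leaf carbon isotope signature",            "permil",       "continuous", TRUE,  -15.9,  -35.08, -11,   903L,  197L, 23L,
    "LCh",    "Leaf chlorophyll content per dry mass",    "ug g-1",       "continuous", FALSE, 2800,   200,    12200, 43L,   35L,  6L,
    "LD",     "Leaf dry matter content",                  "mg g-1",       "continuous", FALSE, 161.2,  37.3,   520,   1440L, 49L,  8L,
    "LI",     "Leaf index",                               "",             "continuous", TRUE,  13.4,   2.2,    250,   212L,  202L, 22L,
    "LL",     "Leaf length",                              "cm",           "continuous", TRUE,  38.7,   1.8,    161,   539L,  204L, 23L,
    "d15N",   "Leaf nitrogen isotope signature",          "permil",       "continuous", TRUE,  -4.7,   -15.2,  7.5,   643L,  69L,  12L,
    "N",      "Leaf nitrogen content per dry mass",       "mg g-1",       "continuous", TRUE,  7.4,    1,      25.5,  554L,  71L,  12L,
    "P",      "Leaf phosphorus content per dry mass",     "mg g-1",       "continuous", FALSE, 0.6,    0.02,   5,     185L,  61L,  11L,
    "LT",     "Leaf thickness",                           "mm",           "continuous", TRUE,  0.6,    0.07,   4.5,   1751L, 97L,  17L,
    "TD",     "Leaf trichome density",                    "mm-2",         "continuous", TRUE,  35.2,   2.8,    120.9, 1104L, 74L,  11L,
    "LWA",    "Leaf water content on area basis",         "g m-2",        "continuous", TRUE,  540.8,  91.7,   6017,  936L,  92L,  16L,
    "LW",     "Leaf width",                               "cm",           "continuous", TRUE,  3.0,    0.05,   17.5,  449L,  202L, 22L,
    "Amax",   "Light saturated photosynthetic rate",      "umol m-2 s-1", "continuous", FALSE, 2.3,    0.7,    4.7,   42L,   36L,  9L,
    "SLA",    "Specific leaf area",                       "mm2 mg-1",     "continuous", TRUE,  8.9,    0.01,   68.5,  1709L, 109L, 16L,
    "SD",     "Stomatal density",                         "mm-2",         "continuous", TRUE,  21.0,   2.8,    88.8,  975L,  102L, 14L,
    "SL",     "Stomatal length",                          "um",           "continuous", FALSE, 39.8,   14.4,   284.3, 257L,  45L,  8L,
    "SW",     "Stomatal width",                           "um",           "continuous", FALSE, 35.0,   9.7,    338.5, 56L,   32L,  7L,
    "TC",     "Tank capacity",                            "mL",           "continuous", TRUE,  85.7,   0,      4924,  213L,  190L, 23L,
    "LWC",    "Total leaf water content",                 "g",            "continuous", TRUE,  3.1,    0.001,  147,   738L,  92L,  16L,
    "PB",     "Pseudobulb presence",                      "",             "binary",     TRUE,  NA,     0,      1,     204L,  204L, 23L,
    "PP",     "Photosynthetic pathway",                   "",             "categorical", FALSE, NA,    NA,     NA,    204L,  204L, 23L
  )
}

#' Per-genus record summary of the source trait database
#'
#' Record, species and trait counts per genus as compiled for the source
#' database. Used for reporting record shares per genus; the grand total of
#' this table and the registry's record total are both reported and are not
#' reconciled against each other (they disagree by 100 in the compilation).
#'
#' @return A tibble with columns `genus`, `n_records`, `n_species`, `n_traits`.
#' @export
genus_records <- function() {
  tibble::tribble(
    ~genus,          ~n_records, ~n_species, ~n_traits,
    "Aechmea",        1549L,  36L, 25L,
    "Araeococcus",    43L,    2L,  18L,
    "Billbergia",     280L,   8L,  22L,
    "Canistropsis",   52L,    1L,  10L,
    "Canistrum",      18L,    2L,  8L,
    "Catopsis",       1138L,  7L,  25L,
    "Fascicularia",   78L,    1L,  11L,
    "Goudaea",        15L,    1L,  10L,
    "Guzmania",       2069L,  31L, 25L,
    "Josemania",      13L,    1L,  12L,
    "Lemeltonia",     206L,   1L,  21L,
    "Lutheria",       21L,    1L,  18L,
    "Lymania",        10L,    1L,  9L,
    "Mezobromelia",   9L,     1L,  9L,
    "Neoregelia",     63L,    5L,  14L,
    "Nidularium",     92L,    8L,  19L,
    "Quesnelia",      21L,    2L,  11L,
    "Racinaea",       878L,   5L,  22L,
    "Ronnbergia",     18L,    2L,  8L,
    "Tillandsia",     9522L,  81L, 25L,
    "Vriesea",        93L,    5L,  14L,
    "Wallisia",       411L,   1L,  24L,
    "Werauhia",       75L,    6L,  19L
  )
}

#' Abbreviations of the clustering trait set
#'
#' @param registry A registry tibble, by default [default_registry()].
#' @return Character vector of the trait abbreviations flagged as clustering
#'   members (16 in the default registry).
#' @export
clustering_traits <- function(registry = default_registry()) {
  registry$abbreviation[registry$clustering_member]
}

#' Read or write a trait registry as YAML
#'
#' The registry file is a YAML list of trait definitions with the fields of
#' [default_registry()]; numeric summary fields are optional.
#'
#' @param path File path.
#' @return `read_registry()` returns a registry tibble.
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  reg <- purrr::map_dfr(raw, function(x) {
    tibble::tibble(
      abbreviation = as.character(x$abbreviation),
      name = as.character(x$name %||% x$abbreviation),
      unit = as.character(x$unit %||% ""),
      kind = as.character(x$kind %||% "continuous"),
      clustering_member = isTRUE(x$clustering_member),
      median = as.numeric(x$median %||% NA),
      range_min = as.numeric(x$range_min %||% NA),
      range_max = as.numeric(x$range_max %||% NA),
      n_records = as.integer(x$n_records %||% NA),
      n_species = as.integer(x$n_species %||% NA),
      n_genera = as.integer(x$n_genera %||% NA)
    )
  })
  validate_registry(reg)
  reg
}

#' @rdname read_registry
#' @param registry Registry tibble to serialize.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  yaml::write_yaml(
    purrr::transpose(lapply(registry, function(col) col)),
    path
  )
  invisible(path)
}

validate_registry <- function(registry) {
  if (anyDuplicated(registry$abbreviation)) {
    dup <- registry$abbreviation[duplicated(registry$abbreviation)]
    rlang::abort(paste0("duplicate trait abbreviation in registry: ",
                        paste(unique(dup), collapse = ", ")))
  }
  if (!all(registry$kind %in% c("continuous", "binary", "categorical"))) {
    rlang::abort("registry kind must be continuous, binary or categorical")
  }
  invisible(registry)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
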