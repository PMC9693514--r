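#' Functional group levels
#'
#' The five epiphytic bromeliad functional groups: nebulophytes, pseudobulbs,
#' shallow tanks, C3 tanks and CAM tanks.
#' @export
fg_levels <- function() c("NEB", "BULB", "SHALLOW_T", "C3_T", "CAM_T")

#' Default classification thresholds
#'
#' Tank-capacity and morphology thresholds of the rule engine: CAM species
#' with tanks of 2-61 mL are shallow tanks (the interval is closed at both
#' ends); C3 species need > 5 mL to count as deep C3 tanks, smaller tanks
#' joining the shallow group; the leaf-index fallback for the nebulophyte
#' call (used only when no explicit `acicular` flag is supplied) defaults to
#' 40, between the group mean leaf indices of nebulophytes (83) and
#' non-nebulophytes (15); the pathway boundary is -20 permil (CAM at or
#' above).
#'
#' @return A named list of thresholds.
#' @export
default_thresholds <- function() {
  list(
    cam_shallow_tc_min = 2,
    cam_shallow_tc_max = 61,
    c3_deep_min_tc = 5,
    nebulophyte_min_li = 40,
    pathway_threshold = -20
  )
}

#' Read or write rule thresholds as YAML
#' @param path File path.
#' @export
read_thresholds <- function(path) {
  thr <- utils::modifyList(default_thresholds(), yaml::read_yaml(path))
  if (thr$cam_shallow_tc_min >= thr$cam_shallow_tc_max) {
    rlang::abort("shallow-tank TC range must have lower < upper")
  }
  thr
}

#' @rdname read_thresholds
#' @param thresholds Threshold list to serialize.
#' @export
write_thresholds <- function(thresholds, path) {
  yaml::write_yaml(thresholds, path)
  invisible(path)
}

classify_one <- function(species, PP, d13C, TC, tankless, PB, acicular, LI, thr) {
  fail <- function(reason) {
    tibble::tibble(species = species, label = NA_character_,
                   provenance = NA_character_, rule_fired = "unclassifiable",
                   reason = reason)
  }
  ok <- function(label, rule, reason) {
    tibble::tibble(species = species, label = label, provenance = "rule",
                   rule_fired = rule, reason = reason)
  }
  # resolve pathway
  pathway <- if (!is.na(PP)) PP
             else if (!is.na(d13C)) call_pathway(d13C)$label
             else NA_character_
  # resolve tank capacity
  tc <- if (!is.na(TC)) TC
        else if (!is.na(tankless) && tankless) 0
        else NA_real_
  if (is.na(PB)) return(fail("pseudobulb flag (PB) missing"))
  if (PB == 1) return(ok("BULB", "pseudobulb", "PB = 1"))
  acic <- if (!is.na(acicular)) acicular
          else if (!is.na(LI) && !is.na(tc)) LI >= thr$nebulophyte_min_li &&
                                             tc < thr$cam_shallow_tc_min
          else NA
  if (!is.na(acic) && acic) {
    return(ok("NEB", "acicular",
              if (!is.na(acicular)) "acicular morphology flag"
              else sprintf("LI >= %g with TC < %g mL", thr$nebulophyte_min_li,
                           thr$cam_shallow_tc_min)))
  }
  if (is.na(pathway)) return(fail("pathway unresolvable (no PP, no d13C)"))
  if (is.na(tc)) return(fail("tank capacity unresolvable (no TC, no tankless flag)"))
  if (pathway == "CAM") {
    if (tc >= thr$cam_shallow_tc_min && tc <= thr$cam_shallow_tc_max) {
      return(ok("SHALLOW_T", "cam_shallow",
                sprintf("CAM with TC in [%g, %g] mL", thr$cam_shallow_tc_min,
                        thr$cam_shallow_tc_max)))
    }
    if (tc > thr$cam_shallow_tc_max) {
      return(ok("CAM_T", "cam_deep",
                sprintf("CAM with TC > %g mL", thr$cam_shallow_tc_max)))
    }
    # CAM, essentially tankless, not acicular, no pseudobulb: no rule covers it
    return(fail(paste0("CAM with TC < ", thr$cam_shallow_tc_min,
                       " mL, non-acicular, no pseudobulb; candidates NEB/BULB")))
  }
  if (tc > thr$c3_deep_min_tc) {
    return(ok("C3_T", "c3_deep", sprintf("C3 with TC > %g mL", thr$c3_deep_min_tc)))
  }
  ok("SHALLOW_T", "c3_negligible_tank",
     sprintf("C3 with negligible tank (TC <= %g mL)", thr$c3_deep_min_tc))
}

#' Rule-based assignment to the five functional groups
#'
#' Deterministic decision order: (1) pseudobulb present -> pseudobulb group;
#' (2) acicular morphology (explicit flag, or the leaf-index fallback when
#' the flag is absent: LI at or above the threshold with a negligible tank)
#' -> nebulophyte; (3) CAM species by tank capacity: shallow tank within the
#' 2-61 mL window, CAM tank above it, unclassifiable below it (no published
#' rule covers a tankless non-acicular CAM rosette; candidates are
#' reported, never silently binned); (4) C3 species: deep C3 tank above
#' 5 mL, otherwise shallow tank. Pathway comes from `PP` or is called from
#' `d13C`; tank capacity from `TC` or the `tankless` flag.
#'
#' @param traits A data frame (or `trait_tbl`) with columns among `species`,
#'   `PP`, `d13C`, `TC`, `tankless`, `PB`, `acicular`, `LI`.
#' @param thresholds Threshold list, default [default_thresholds()].
#' @return A tibble with columns `species`, `label` (`NA` when
#'   unclassifiable), `provenance` (`"rule"`), `rule_fired`, `reason`.
#' @export
classify_species <- function(traits, thresholds = default_thresholds()) {
  df <- tibble::as_tibble(traits)
  n <- nrow(df)
  col <- function(nm, default) if (nm %in% names(df)) df[[nm]] else rep(default, n)
  purrr::pmap_dfr(
    list(
      species = col("species", NA_character_),
      PP = as.character(col("PP", NA_character_)),
      d13C = as.numeric(col("d13C", NA_real_)),
      TC = as.numeric(col("TC", NA_real_)),
      tankless = as.logical(col("tankless", NA)),
      PB = as.numeric(col("PB", NA_real_)),
      acicular = as.logical(col("acicular", NA)),
      LI = as.numeric(col("LI", NA_real_))
    ),
    classify_one, thr = thresholds
  )
}

#' Name clusters and reconcile cluster output with the rule engine
#'
#' Clusters from [cut_tree()] are first named by the majority rule-derived
#' label of their members. Two reconciliation moves are then applied, each
#' logged: CAM species landing in the C3-tank cluster move to the CAM tank
#' group (pathway mismatch), and acicular species landing in the
#' shallow-tank cluster move to the nebulophytes (morphological override).
#' Applying the function to its own output changes nothing.
#'
#' @param cluster_map Tibble with `species` and `cluster` (from [cut_tree()])
#'   or with `species` and `label` (already named, for idempotent re-runs).
#' @param traits Trait table or data frame used by the rule engine.
#' @param thresholds Threshold list.
#' @return A list with `labels` (tibble: `species`, `label`, `provenance` in
#'   cluster/override) and `changes` (tibble: `species`, `from`, `to`,
#'   `reason`).
#' @export
reconcile_with_clusters <- function(cluster_map, traits,
                                    thresholds = default_thresholds()) {
  rules <- classify_species(traits, thresholds)
  if ("label" %in% names(cluster_map)) {
    named <- tibble::tibble(species = cluster_map$species,
                            label = cluster_map$label,
                            provenance = cluster_map$provenance %||% "cluster")
  } else {
    named <- dplyr::left_join(cluster_map, rules[c("species", "label")],
                              by = "species") |>
      dplyr::group_by(.data$cluster) |>
      dplyr::mutate(label = majority_label(.data$label)) |>
      dplyr::ungroup() |>
      dplyr::transmute(species = .data$species, label = .data$label,
                       provenance = "cluster")
  }
  df <- dplyr::left_join(named, tibble::as_tibble(traits), by = "species")
  d13c <- if ("d13C" %in% names(df)) df$d13C else rep(NA_real_, nrow(df))
  pathway <- dplyr::coalesce(
    if ("PP" %in% names(df)) as.character(df$PP) else NA_character_,
    call_pathway(d13c)$label
  )
  acic <- if ("acicular" %in% names(df)) !is.na(df$acicular) & df$acicular
          else rep(FALSE, nrow(df))

  changes <- tibble::tibble(species = character(), from = character(),
                            to = character(), reason = character())
  move1 <- df$label == "C3_T" & !is.na(pathway) & pathway == "CAM"
  if (any(move1, na.rm = TRUE)) {
    i <- which(move1)
    changes <- dplyr::bind_rows(changes, tibble::tibble(
      species = df$species[i], from = "C3_T", to = "CAM_T",
      reason = "pathway mismatch"))
    named$label[i] <- "CAM_T"; named$provenance[i] <- "override"
  }
  move2 <- df$label == "SHALLOW_T" & acic
  if (any(move2, na.rm = TRUE)) {
    i <- which(move2)
    changes <- dplyr::bind_rows(changes, tibble::tibble(
      species = df$species[i], from = "SHALLOW_T", to = "NEB",
      reason = "acicular morphology"))
    named$label[i] <- "NEB"; named$provenance[i] <- "override"
  }
  list(labels = named, changes = changes)
}

majority_label <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return(NA_character_)
  tab <- sort(table(labels), decreasing = TRUE)
  names(tab)[1]
}

#' Group composition table
#'
#' Counts and percentage shares per functional group; percentages are
#' reported both exactly and rounded to integers.
#'
#' @param labels Character vector of group labels, or a tibble with a
#'   `label` column.
#' @return A tibble with `label`, `n`, `fraction`, `percent` (counts sum to
#'   the number of labelled species).
#' @export
group_composition <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- labels[!is.na(labels)]
  lv <- fg_levels()
  counts <- table(factor(labels, levels = lv))
  tibble::tibble(
    label = lv,
    n = as.integer(counts),
    fraction = as.numeric(counts) / max(1L, length(labels)),
    percent = as.integer(round(100 * as.numeric(counts) / max(1L, length(labels))))
  )
}
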