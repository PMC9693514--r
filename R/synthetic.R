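#' Synthetic study configuration
#'
#' Bundles every knob of the synthetic generator: group sizes, archetype
#' trait means and spreads for the 16 clustering traits, the missingness
#' rate, tree and Brownian-motion settings, per-group climate niches, and
#' ecozone membership probabilities. Defaults emulate the study conditions
#' of the source compilation: 76 species across the five groups, 7.2%
#' missing cells, archetypes whose medians sit inside the registry ranges
#' and whose contrasts trigger the classification rules they represent
#' (nebulophytes with high leaf index and no tank, pseudobulbs with PB = 1
#' and high succulence, shallow tanks with 2-61 mL, CAM tanks above 61 mL,
#' C3 tanks with d13C below -20 and high SLA).
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_per_group Named integer vector of species counts per group.
#' @param missing_rate Fraction of the species-by-clustering-trait grid to
#'   mask, in \[0, 0.5\]; default 0.072.
#' @param birth_rate Pure-birth speciation rate for the tree.
#' @param bm_sd Brownian-motion deviation SD at unit tree depth (log10
#'   units for log-scale traits).
#' @param noise_sd Independent per-species noise SD (same scales).
#' @param records_per_species Occurrence records per species.
#' @param tree_coverage Fraction of species present on the tree (the rest
#'   exercise the genus-mean fallback), default 50/76.
#' @param n_genera Number of genera (clade-based assignment).
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(seed = 1,
                             n_per_group = c(NEB = 11, BULB = 7, SHALLOW_T = 13,
                                             C3_T = 25, CAM_T = 20),
                             missing_rate = 0.072,
                             birth_rate = 1,
                             bm_sd = 0.08,
                             noise_sd = 0.1,
                             records_per_species = 20,
                             tree_coverage = 50 / 76,
                             n_genera = 8) {
  cfg <- list(
    seed = as.integer(seed),
    n_per_group = n_per_group,
    missing_rate = missing_rate,
    birth_rate = birth_rate,
    bm_sd = bm_sd,
    noise_sd = noise_sd,
    records_per_species = records_per_species,
    tree_coverage = tree_coverage,
    n_genera = n_genera,
    archetypes = default_archetypes(),
    additive_sd = c(d13C = 1.2, d15N = 1.5, N = 1.5),
    niches = default_niches(),
    ecozone_probs = default_ecozone_probs()
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' Archetype trait means per functional group
#'
#' Raw-unit group means for the 16 clustering traits, encoding the
#' directional contrasts between groups: nebulophytes narrow-leaved with
#' the highest leaf index and no tank; pseudobulbs succulent (high LT,
#' LWA) with PB = 1; shallow tanks small CAM rosettes holding 2-61 mL;
#' C3 tanks C3-signed d13C, high SLA and stomatal density; CAM tanks the
#' largest plants with the deepest tanks.
#'
#' @return A tibble, one row per group.
#' @export
default_archetypes <- function() {
  tibble::tribble(
    ~group,      ~Height, ~LA, ~d13C, ~LI, ~LL, ~d15N, ~N, ~LT, ~TD, ~LWA, ~LW, ~SLA, ~SD, ~TC, ~LWC, ~PB,
    "NEB",       0.15,  15,  -15,  83, 35, -9, 6, 0.4, 70,  150, 0.4, 10, 10,   0,  0.2, 0,
    "BULB",      0.25,  80,  -14,  15, 25, -6, 7, 1.5, 60, 1200, 1.5,  6, 12,   0,  2,   1,
    "SHALLOW_T", 0.3,  120,  -15,  15, 30, -6, 7, 0.5, 40,  500, 2,   12, 18,  20,  3,   0,
    "C3_T",      0.5,  400,  -28,   8, 35, -2, 8, 0.3,  8,  300, 4.5, 20, 40, 150,  8,   0,
    "CAM_T",     0.9,  900,  -14,   6, 50, -4, 7, 0.8, 30,  900, 6,    8, 35, 800, 40,   0
  )
}

#' Per-group climate niche means
#'
#' Gaussian niche centres per environmental variable, encoding the
#' published ordering of the groups: nebulophytes at the arid, high-VPD
#' end, C3 tanks at the wet, cool, high-elevation end, CAM tanks and
#' pseudobulbs in warm lowlands, shallow tanks intermediate.
#'
#' @return A list with `mean` (group x variable tibble) and `sd` (named
#'   vector per variable).
#' @export
default_niches <- function() {
  list(
    mean = tibble::tribble(
      ~group,      ~VPD, ~PPT, ~TMIN, ~TMAX, ~ET0, ~AI,  ~Elev,
      "NEB",       1.6,   600, 12,    28,    1700, 0.35, 1200,
      "BULB",      1.3,  1200, 18,    31,    1600, 0.75,  400,
      "SHALLOW_T", 1.1,  1400, 14,    28,    1500, 0.9,   800,
      "C3_T",      0.6,  2500,  8,    22,    1100, 2.2,  1800,
      "CAM_T",     0.9,  1800, 19,    32,    1650, 1.1,   300
    ),
    sd = c(VPD = 0.15, PPT = 150, TMIN = 1.5, TMAX = 1.5, ET0 = 100,
           AI = 0.12, Elev = 150)
  )
}

default_ecozone_probs <- function() {
  z <- function(...) {
    v <- c(...)
    stats::setNames(v / sum(v), c("Tropical rainforest", "Tropical moist forest",
                                  "Tropical dry forest", "Tropical mountain system",
                                  "Tropical desert", "Subtropical desert",
                                  "Temperate oceanic forest",
                                  "Temperate mountain system"))
  }
  list(
    NEB       = z(0.15, 0.15, 0.15, 0.20, 0.12, 0.10, 0.06, 0.07),
    BULB      = z(0.30, 0.30, 0.20, 0.20, 0, 0, 0, 0),
    SHALLOW_T = z(0.30, 0.30, 0.15, 0.25, 0, 0, 0, 0),
    C3_T      = z(0.35, 0.25, 0.00, 0.40, 0, 0, 0, 0),
    CAM_T     = z(0.35, 0.30, 0.25, 0.10, 0, 0, 0, 0)
  )
}

validate_synthetic_config <- function(cfg) {
  thr <- default_thresholds()
  a <- cfg$archetypes
  g <- function(grp, tr) a[[tr]][a$group == grp]
  if (!(g("SHALLOW_T", "TC") >= thr$cam_shallow_tc_min &&
        g("SHALLOW_T", "TC") <= thr$cam_shallow_tc_max)) {
    rlang::abort("archetype inconsistent: SHALLOW_T mean TC outside [2, 61] mL")
  }
  if (g("CAM_T", "TC") <= thr$cam_shallow_tc_max) {
    rlang::abort("archetype inconsistent: CAM_T mean TC must exceed 61 mL")
  }
  if (g("C3_T", "TC") <= thr$c3_deep_min_tc) {
    rlang::abort("archetype inconsistent: C3_T mean TC must exceed 5 mL")
  }
  if (g("C3_T", "d13C") >= thr$pathway_threshold) {
    rlang::abort("archetype inconsistent: C3_T mean d13C must be below -20")
  }
  for (grp in c("NEB", "BULB", "SHALLOW_T", "CAM_T")) {
    if (g(grp, "d13C") < thr$pathway_threshold) {
      rlang::abort(paste0("archetype inconsistent: ", grp,
                          " mean d13C must be CAM-side (>= -20)"))
    }
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.5) {
    rlang::abort("missing_rate must be in [0, 0.5]")
  }
  if (any(cfg$n_per_group < 0) ||
      !setequal(names(cfg$n_per_group), fg_levels())) {
    rlang::abort("n_per_group must name all five groups")
  }
  invisible(cfg)
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Starts from a root split into two lineages; with k lineages alive the
#' waiting time to the next event is exponential with rate `k * birth_rate`
#' and a uniformly chosen lineage splits, until `n_tips` lineages have each
#' also lived through a final exponential period at rate `n * birth_rate`.
#' The tree is ultrametric with expected root-to-tip depth
#' \eqn{\sum_{k=2}^{n} 1/(k\lambda)} and bit-reproducible under `seed`.
#'
#' @param n_tips Number of tips, at least 2.
#' @param birth_rate Speciation rate \eqn{\lambda}.
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with tips `sp_001`, `sp_002`, ...
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1) {
  if (n_tips < 2) rlang::abort("simulate_tree: need n_tips >= 2")
  set.seed(seed)
  n <- n_tips
  # lineages: parent internal node (creation order) and pendant edge length
  parent <- c(1L, 1L)
  len <- c(0, 0)
  next_internal <- 2L
  edges_p <- integer(0); edges_c <- integer(0); edges_len <- numeric(0)
  child_internal <- integer(0)  # internal node id per recorded edge child
  for (k in 2:n) {
    dt <- stats::rexp(1, rate = k * birth_rate)
    len <- len + dt
    if (k < n) {
      i <- sample.int(k, 1)
      node <- next_internal; next_internal <- next_internal + 1L
      edges_p <- c(edges_p, parent[i]); edges_c <- c(edges_c, node)
      edges_len <- c(edges_len, len[i])
      parent <- c(parent[-i], node, node)
      len <- c(len[-i], 0, 0)
    }
  }
  n_int <- next_internal - 1L
  # ape numbering: tips 1..n, internals n+1..n+n_int (creation order)
  tip_edges_p <- parent + n
  int_edges_p <- edges_p + n
  int_edges_c <- edges_c + n
  edge <- rbind(cbind(int_edges_p, int_edges_c),
                cbind(tip_edges_p, seq_len(n)))
  edge_len <- c(edges_len, len)
  tree <- list(edge = edge, edge.length = edge_len,
               tip.label = sprintf("sp_%03d", seq_len(n)),
               Nnode = n_int)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_phylogeny(tree)
}

log_scale_traits <- function() {
  c("Height", "LA", "LI", "LL", "LT", "TD", "LWA", "LW", "SLA", "SD", "LWC")
}

#' Simulate a five-archetype trait table on a phylogeny
#'
#' Each species draws its clustering traits as archetype mean plus a
#' Brownian-motion deviation along the tree plus independent noise
#' (deviations act on the log10 scale for size-like traits and additively
#' for isotopes and nitrogen). Tank capacity of nebulophytes and
#' pseudobulbs is exactly 0 (the `tankless` flag is set); shallow-tank
#' draws are confined to the 2-61 mL window by their small spread;
#' pseudobulb presence is deterministic per group; nebulophytes carry the
#' `acicular` flag. Genera are clades: the tree is cut into `n_genera`
#' cophenetic clades. Group identities are returned as ground truth.
#'
#' @param cfg A [synthetic_config()].
#' @param tree Optional phylogeny for every species (defaults to a
#'   simulated tree over all species).
#' @return A list with `table` (a complete `trait_tbl`), `labels` (tibble
#'   `species`, `label`), `tree` (covering `tree_coverage` of the species),
#'   `full_tree`, and `config`.
#' @export
simulate_traits <- function(cfg = synthetic_config(), tree = NULL) {
  validate_synthetic_config(cfg)
  set.seed(cfg$seed)
  n <- sum(cfg$n_per_group)
  if (is.null(tree)) tree <- simulate_tree(n, cfg$birth_rate, seed = cfg$seed + 1L)
  set.seed(cfg$seed + 2L)
  species <- tree$tip.label
  labels <- sample(rep(names(cfg$n_per_group), cfg$n_per_group))

  C <- ape::vcv(tree)[species, species]
  C <- C / max(diag(C))
  L <- t(chol(C + diag(1e-10, n)))

  arch <- cfg$archetypes
  traits <- setdiff(names(arch), "group")
  vals <- matrix(NA_real_, n, length(traits), dimnames = list(species, traits))
  for (tr in traits) {
    mu <- stats::setNames(arch[[tr]], arch$group)[labels]
    if (tr == "PB") {
      vals[, tr] <- mu
      next
    }
    bm <- as.numeric(L %*% stats::rnorm(n)) * cfg$bm_sd
    e <- stats::rnorm(n, 0, cfg$noise_sd)
    if (tr %in% names(cfg$additive_sd)) {
      # rescale the combined deviation so the marginal SD is the configured one
      sd_tot <- sqrt(cfg$bm_sd^2 + cfg$noise_sd^2)
      vals[, tr] <- mu + (bm + e) / max(sd_tot, 1e-9) * cfg$additive_sd[[tr]]
    } else if (tr == "TC") {
      tankless <- labels %in% c("NEB", "BULB")
      v <- 10^(log10(pmax(mu, 1e-9)) + 0.6 * (bm + e))
      v[tankless] <- 0
      vals[, tr] <- v
    } else {
      vals[, tr] <- 10^(log10(mu) + bm + e)
    }
  }

  genus_id <- stats::cutree(stats::hclust(stats::as.dist(ape::cophenetic.phylo(tree)),
                                          method = "average"),
                            k = min(cfg$n_genera, n))
  df <- tibble::as_tibble(vals)
  df$species <- species
  df$genus <- sprintf("genus_%02d", genus_id[species])
  df$tankless <- labels %in% c("NEB", "BULB")
  df$acicular <- labels == "NEB"
  tt <- trait_table(df)

  keep_n <- max(2L, round(cfg$tree_coverage * n))
  set.seed(cfg$seed + 3L)
  on_tree <- sort(sample.int(n, keep_n))
  sub_tree <- if (keep_n < n) ape::drop.tip(tree, species[-on_tree]) else tree

  list(table = tt,
       labels = tibble::tibble(species = species, label = labels),
       tree = sub_tree, full_tree = tree, config = cfg)
}

#' Mask cells completely at random
#'
#' Masks `rate` of the species-by-clustering-trait grid (missing completely
#' at random), drawing only from continuous cells — pseudobulb presence is
#' always scored in practice — and never leaving a species with fewer than
#' `min_traits` observed values. The achieved count is within one cell of
#' `rate` times the grid size.
#'
#' @param tt A complete `trait_tbl`.
#' @param rate Fraction in \[0, 0.5\].
#' @param seed Integer seed.
#' @param min_traits Per-species floor of retained values, default 5.
#' @return The masked `trait_tbl`.
#' @export
mask_missing <- function(tt, rate, seed = 1, min_traits = 5) {
  if (rate < 0 || rate > 0.5) rlang::abort("mask_missing: rate must be in [0, 0.5]")
  if (rate == 0) return(tt)
  set.seed(seed)
  traits <- trait_cols(tt)
  cont <- continuous_traits(tt)
  target <- round(rate * nrow(tt) * length(traits))
  cand <- expand.grid(row = seq_len(nrow(tt)), trait = cont,
                      stringsAsFactors = FALSE)
  cand <- cand[!is.na(as.matrix(as.data.frame(tt[cont]))[cbind(cand$row,
               match(cand$trait, cont))]), ]
  cand <- cand[sample.int(nrow(cand)), ]
  n_obs <- rowSums(!is.na(as.data.frame(tt[traits])))
  masked <- 0
  prov <- provenance_of(tt)
  for (r in seq_len(nrow(cand))) {
    if (masked >= target) break
    i <- cand$row[r]; tr <- cand$trait[r]
    if (n_obs[i] - 1 < min_traits) next
    tt[[tr]][i] <- NA_real_
    prov[[tr]][i] <- NA_character_
    n_obs[i] <- n_obs[i] - 1
    masked <- masked + 1
  }
  attr(tt, "provenance") <- prov
  if (abs(masked - target) > 1) {
    rlang::warn(sprintf("mask_missing: achieved %d of %d target cells",
                        masked, target))
  }
  tt
}

#' Simulate occurrence-environment records
#'
#' Gaussian draws per environmental variable around each species' group
#' niche, an ecozone sampled from the group's membership distribution, and
#' plausible Neotropical coordinates. Exactly `records_per_species` records
#' per species.
#'
#' @param cfg A [synthetic_config()].
#' @param labels Tibble with `species` and `label`.
#' @param records_per_species Records per species; defaults to the config.
#' @param seed Integer seed; defaults to the config seed.
#' @return A records tibble (`species`, `lat`, `lon`, the variables of
#'   [env_variables()], `ecozone`).
#' @export
simulate_env_records <- function(cfg, labels,
                                 records_per_species = cfg$records_per_species,
                                 seed = cfg$seed + 4L) {
  set.seed(seed)
  nm <- cfg$niches$mean
  nsd <- cfg$niches$sd
  lat_centre <- c(NEB = 20, BULB = 18, SHALLOW_T = 15, C3_T = 5, CAM_T = 10)
  purrr::pmap_dfr(labels, function(species, label) {
    m <- nm[nm$group == label, ]
    k <- records_per_species
    rec <- tibble::tibble(
      species = species,
      lat = pmin(40, pmax(-40, stats::rnorm(k, lat_centre[[label]], 8))),
      lon = pmin(-35, pmax(-115, stats::rnorm(k, -75, 12)))
    )
    for (v in env_variables()) {
      lo <- if (v %in% c("PPT", "ET0", "AI", "VPD")) 0 else -Inf
      rec[[v]] <- pmax(lo, stats::rnorm(k, m[[v]], nsd[[v]]))
    }
    probs <- cfg$ecozone_probs[[label]]
    rec$ecozone <- sample(names(probs), k, replace = TRUE, prob = probs)
    rec
  })
}

#' Simulate a complete synthetic study
#'
#' One call producing everything the pipeline consumes: the full and
#' tree-coverage phylogenies, a complete trait table, its masked version,
#' ground-truth labels, and occurrence records.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `table` (masked), `complete_table`, `labels`, `tree`,
#'   `full_tree`, `records`, `config`.
#' @export
simulate_study <- function(cfg = synthetic_config()) {
  sim <- simulate_traits(cfg)
  masked <- mask_missing(sim$table, cfg$missing_rate, seed = cfg$seed + 5L)
  records <- simulate_env_records(cfg, sim$labels)
  list(table = masked, complete_table = sim$table, labels = sim$labels,
       tree = sim$tree, full_tree = sim$full_tree, records = records,
       config = cfg)
}
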