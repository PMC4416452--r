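#' Default absorption-feature table
#'
#' Gaussian absorption features multiplying the baseline leaf curve. Centers
#' follow published leaf biochemistry: chlorophyll bands in the visible
#' (430, 460, 640, 660, 678 nm), protein / N-bond features in the NIR-SWIR
#' (910, 1020, 1165, 1270, 1375, 1510, 1690, 1730, 1770 nm) and water bands
#' (970, 1200, 1450, 1780, 1940 nm). `depth` is the fractional absorption at
#' the center for reference traits; `n_sensitivity` adds depth per unit N%
#' above the reference, `water_sensitivity` per unit GWC, and
#' `iso_sensitivity` is a fractional width response per permil delta15N
#' (the heavy isotope subtly shifts bond vibration frequencies, modeled as a
#' band-width change).
#'
#' @param iso_sensitivity fractional width change per permil applied to the
#'   chlorophyll and N-bond features (default 0.008; set 0 for a
#'   no-isotope-effect negative control).
#' @param iso_mode whether delta15N perturbs feature `width` (default) or
#'   `depth`.
#' @return data.frame with columns `center`, `width`, `depth`,
#'   `n_sensitivity`, `water_sensitivity`, `iso_sensitivity`, `kind`.
#' @export
default_features <- function(iso_sensitivity = 0.008,
                             iso_mode = c("width", "depth")) {
  iso_mode <- match.arg(iso_mode)
  chl <- data.frame(center = c(430, 460, 640, 660, 678),
                    width = c(18, 16, 14, 12, 11),
                    depth = c(0.35, 0.30, 0.20, 0.28, 0.32),
                    n_sensitivity = 0.02, water_sensitivity = 0,
                    iso_sensitivity = iso_sensitivity, kind = "chlorophyll")
  nb <- data.frame(center = c(910, 1020, 1165, 1270, 1375, 1510, 1690, 1730,
                              1770),
                   width = c(12, 15, 15, 15, 15, 15, 12, 12, 12),
                   depth = c(0.045, 0.045, 0.05, 0.05, 0.06, 0.05, 0.05,
                             0.05, 0.05),
                   n_sensitivity = 0.015, water_sensitivity = 0,
                   iso_sensitivity = iso_sensitivity,
                   kind = rep(c("n_bond_nir", "n_bond_swir"), c(5, 4)))
  wat <- data.frame(center = c(970, 1200, 1450, 1780, 1940),
                    width = c(30, 40, 45, 60, 60),
                    depth = c(0.05, 0.09, 0.32, 0.10, 0.42),
                    n_sensitivity = 0, water_sensitivity = 0.05,
                    iso_sensitivity = 0, kind = "water")
  out <- rbind(chl, nb, wat)
  attr(out, "iso_mode") <- iso_mode
  out
}

#' Simulation configuration
#'
#' The generating model for synthetic fresh-leaf reflectance: a smooth
#' species baseline (low visible reflectance, red-edge sigmoid, NIR plateau)
#' multiplied by Gaussian absorption features, then distorted by per-sensor
#' splice factors and heteroscedastic noise (elevated in SWIR2, emulating a
#' weak halogen source in that region). Species profiles carry the trait
#' distributions; in the greenhouse design delta15N is set by the labeling
#' treatment and varies independently of N%, GWC and SLA.
#'
#' @param grid integer nm axis (default 350:2500).
#' @param features absorption-feature table, see [default_features()].
#' @param species_profiles named list per species: `nir_plateau`,
#'   `vis_base`, `red_edge` (nm), `n_mean`, `n_sd` (%), `gwc_mean`,
#'   `gwc_sd`, `sla_mean`, `sla_sd`, `d15n_baseline` (permil),
#'   `uptake` (named: young/mature/stressed fraction of the nominal
#'   enrichment reaching the leaf), `n_plants`, `treatments`.
#' @param d15n_noise_sd permil SD of leaf-level isotope noise.
#' @param jump_sd named c(vnir, swir2) SD of the multiplicative splice
#'   distortion factors.
#' @param noise_sd named c(vnir, swir1, swir2) reflectance noise SDs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(grid = 350:2500,
                       features = default_features(),
                       species_profiles = default_species_profiles(),
                       d15n_noise_sd = 1.0,
                       jump_sd = c(vnir = 0.02, swir2 = 0.03),
                       noise_sd = c(vnir = 0.0015, swir1 = 0.002,
                                    swir2 = 0.012)) {
  stopifnot(all(diff(grid) == 1), all(noise_sd >= 0), all(jump_sd >= 0),
            d15n_noise_sd >= 0)
  structure(list(grid = as.integer(grid), features = features,
                 species_profiles = species_profiles,
                 d15n_noise_sd = d15n_noise_sd, jump_sd = jump_sd,
                 noise_sd = noise_sd),
            class = "sim_config")
}

#' Default greenhouse species profiles
#'
#' Three species with distinct leaf types and baselines: a large
#' mesophyllic leaf (high NIR plateau), a small pubescent leaf, and a
#' sclerophyllous leaf (low plateau, thick cuticle). Plant numbers are
#' 16 / 12 / 11; the smallest species is allocated to the 0 and 20 permil
#' treatments only, the others to 0 / 10 / 20. Mature leaves take up less
#' label than young and stressed leaves, and uptake fails entirely in
#' mature leaves of the sclerophyllous species.
#'
#' @return Named list of species profiles.
#' @export
default_species_profiles <- function() {
  list(
    "H. halimifolium" = list(
      nir_plateau = 0.46, vis_base = 0.055, red_edge = 712,
      n_mean = 1.6, n_sd = 0.18, gwc_mean = 1.4, gwc_sd = 0.25,
      sla_mean = 9.0, sla_sd = 1.2, d15n_baseline = -1.0,
      uptake = c(young = 0.78, mature = 0.45, stressed = 0.72),
      iso_weight_by_kind = list(chlorophyll = -0.9, n_bond_nir = -0.5,
                                n_bond_swir = -0.3),
      n_plants = 16L, treatments = c(0, 10, 20)),
    "H. rosa-sinensis" = list(
      nir_plateau = 0.54, vis_base = 0.045, red_edge = 705,
      n_mean = 2.2, n_sd = 0.22, gwc_mean = 2.4, gwc_sd = 0.35,
      sla_mean = 16.0, sla_sd = 1.8, d15n_baseline = -0.5,
      uptake = c(young = 0.82, mature = 0.50, stressed = 0.75),
      iso_weight_by_kind = list(chlorophyll = 0.3, n_bond_nir = 0.4,
                                n_bond_swir = 1.2),
      n_plants = 12L, treatments = c(0, 10, 20)),
    "A. unedo" = list(
      nir_plateau = 0.40, vis_base = 0.050, red_edge = 718,
      n_mean = 1.1, n_sd = 0.12, gwc_mean = 1.1, gwc_sd = 0.18,
      sla_mean = 6.0, sla_sd = 0.8, d15n_baseline = -1.5,
      uptake = c(young = 0.72, mature = 0.0, stressed = 0.68),
      iso_weight_by_kind = list(chlorophyll = 1.2, n_bond_nir = 0.3,
                                n_bond_swir = -0.2),
      n_plants = 11L, treatments = c(0, 20)))
}

# smooth stylized leaf baseline: low VIS, red-edge sigmoid, NIR plateau with
# gentle SWIR decline
leaf_baseline <- function(grid, profile) {
  sig <- 1 / (1 + exp(-(grid - profile$red_edge) / 18))
  decline <- 1 - 0.25 / (1 + exp(-(grid - 1900) / 180))
  profile$vis_base + (profile$nir_plateau - profile$vis_base) * sig * decline +
    0.025 * exp(-(grid - 550)^2 / (2 * 30^2))   # green reflectance bump
}

#' Simulate one leaf reflectance spectrum
#'
#' `r(lambda) = baseline(lambda) * prod_f [1 - depth_f(traits) *
#' exp(-(lambda - c_f)^2 / (2 * sigma_f(d15N)^2))]`, followed by per-sensor
#' splice distortion factors and heteroscedastic Gaussian noise; values are
#' kept strictly positive.
#'
#' @param traits list/row with `delta15N`, `n_content`, `gwc`, `sla` and
#'   `species`.
#' @param config a [sim_config].
#' @param noise logical: add measurement noise and splice jumps (default
#'   TRUE). With `FALSE` the closed-form generating curve is returned.
#' @return Numeric reflectance vector on `config$grid`.
#' @export
simulate_leaf_spectrum <- function(traits, config = sim_config(),
                                   noise = TRUE) {
  grid <- config$grid
  profile <- config$species_profiles[[traits$species]]
  if (is.null(profile)) stop("unknown species: ", traits$species)
  r <- leaf_baseline(grid, profile)
  ft <- config$features
  iso_mode <- attr(ft, "iso_mode")
  if (is.null(iso_mode)) iso_mode <- "width"
  n_ref <- profile$n_mean
  g_ref <- profile$gwc_mean
  iso_w <- profile$iso_weight_by_kind
  for (f in seq_len(nrow(ft))) {
    depth <- ft$depth[f] +
      ft$n_sensitivity[f] * (traits$n_content - n_ref) +
      ft$water_sensitivity[f] * (traits$gwc - g_ref)
    width <- ft$width[f]
    # species may express the isotope response in different band families
    # (differential use of assimilated N); default weight 1 everywhere
    wgt <- if (is.null(iso_w)) 1 else {
      w <- iso_w[[ft$kind[f]]]
      if (is.null(w) || is.na(w)) 1 else w
    }
    if (iso_mode == "width") {
      width <- width * (1 + wgt * ft$iso_sensitivity[f] * traits$delta15N)
    } else {
      depth <- depth * (1 + wgt * ft$iso_sensitivity[f] * traits$delta15N)
    }
    if (depth >= 1) stop("absorption depth >= 1 after sensitivity scaling")
    depth <- max(depth, 0)
    r <- r * (1 - depth * exp(-(grid - ft$center[f])^2 / (2 * width^2)))
  }
  if (noise) {
    f_v <- stats::rnorm(1L, 1, config$jump_sd[["vnir"]])
    f_s <- stats::rnorm(1L, 1, config$jump_sd[["swir2"]])
    r[grid <= 1000] <- r[grid <= 1000] * f_v
    r[grid >= 1801] <- r[grid >= 1801] * f_s
    sd_band <- ifelse(grid <= 1000, config$noise_sd[["vnir"]],
                      ifelse(grid <= 1800, config$noise_sd[["swir1"]],
                             config$noise_sd[["swir2"]]))
    r <- r + stats::rnorm(length(grid), 0, sd_band)
  }
  pmax(r, 1e-6)
}

#' Generate the greenhouse labeling dataset
#'
#' Emulates a 15N fertilization experiment: per species, plants are split
#' over the enrichment treatments (0 / 10 / 20 permil; the smallest species
#' over 0 / 20 only) and each plant contributes three young, three mature
#' and three drought-stressed leaves. Foliar delta15N is the species
#' baseline plus the treatment enrichment scaled by the leaf-type uptake
#' fraction plus leaf-level noise; N%, GWC and SLA are drawn independently
#' of treatment, so the isotope signature is uncorrelated with the other
#' leaf traits by construction.
#'
#' @param config a [sim_config].
#' @param seed integer seed; generation is fully seed-deterministic.
#' @return list with `spectra` (a [spectra_set], raw state) and `records`
#'   (metadata data.frame).
#' @export
generate_greenhouse_dataset <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("seed is required")
  force(seed)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  rec_list <- list()
  spec_list <- list()
  idx <- 0L
  for (sp in names(config$species_profiles)) {
    profile <- config$species_profiles[[sp]]
    n_plants <- profile$n_plants
    treatments <- profile$treatments
    # balanced random allocation of plants to treatments
    alloc <- sample(rep_len(treatments, n_plants))
    for (plant in seq_len(n_plants)) {
      trt <- alloc[plant]
      for (lt in c("young", "mature", "stressed")) {
        for (leaf in 1:3) {
          idx <- idx + 1L
          d15n <- profile$d15n_baseline + trt * profile$uptake[[lt]] +
            stats::rnorm(1L, 0, config$d15n_noise_sd)
          gwc_mult <- if (lt == "stressed") 0.8 else 1
          traits <- list(
            species = sp,
            delta15N = d15n,
            n_content = max(stats::rnorm(1L, profile$n_mean, profile$n_sd),
                            0.2),
            gwc = max(stats::rnorm(1L, profile$gwc_mean * gwc_mult,
                                   profile$gwc_sd), 0.05),
            sla = max(stats::rnorm(1L, profile$sla_mean, profile$sla_sd), 1))
          rec_list[[idx]] <- data.frame(
            sample_id = sprintf("%s_p%02d_%s_%d", gsub("[ .]", "", sp),
                                plant, lt, leaf),
            species = sp, leaf_type = lt, treatment = trt,
            delta15N = traits$delta15N, n_content = traits$n_content,
            gwc = traits$gwc, sla = traits$sla)
          spec_list[[idx]] <- simulate_leaf_spectrum(traits, config)
        }
      }
    }
  }
  records <- do.call(rbind, rec_list)
  m <- do.call(rbind, spec_list)
  set <- suppressWarnings(spectra_set(m, config$grid, records$sample_id,
                                      state = "raw"))
  list(spectra = set, records = records)
}

#' Generate the field gradient dataset
#'
#' Emulates sampling a non-fixing shrub along transects of increasing
#' distance to an N2-fixing invader: foliar delta15N is a two-endmember mix
#' of the depleted background (-12 permil) and atmospheric fixed N
#' (0 permil), with the fixed-N fraction decaying exponentially with
#' distance; N content is generated to covary with delta15N (target Pearson
#' r around 0.75) inside the 0.47-0.96% band.
#'
#' @param config a [sim_config] (a single field species profile is used).
#' @param n number of plants (default 40).
#' @param seed integer seed.
#' @param max_distance transect length (m, default 25).
#' @param decay e-folding distance of the fixed-N influence (m, default 10).
#' @param f0 fixed-N mixing fraction at distance zero (default 0.79, so the
#'   gradient spans about -12 to -2.5 permil).
#' @return list with `spectra` and `records` (including
#'   `distance_to_canopy`).
#' @export
generate_field_dataset <- function(config = field_sim_config(), n = 40L,
                                   seed, max_distance = 25, decay = 10,
                                   f0 = 0.79) {
  if (missing(seed)) stop("seed is required")
  force(seed)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sp <- names(config$species_profiles)[1L]
  profile <- config$species_profiles[[sp]]

  d <- stats::runif(n, 0, max_distance)
  f <- f0 * exp(-d / decay)                       # fixed-N mixing fraction
  d15n <- -12 * (1 - f) + 0 * f + stats::rnorm(n, 0, 0.4)
  d15n <- pmin(pmax(d15n, -12), -2.5)
  # N% tracks the same mixing fraction plus independent noise -> r ~ 0.75
  n_pct <- 0.47 + 0.49 * ((d15n + 12) / 9.5) + stats::rnorm(n, 0, 0.11)
  n_pct <- pmin(pmax(n_pct, 0.47), 0.96)

  rec_list <- vector("list", n)
  spec_list <- vector("list", n)
  for (i in seq_len(n)) {
    traits <- list(species = sp, delta15N = d15n[i], n_content = n_pct[i],
                   gwc = max(stats::rnorm(1L, profile$gwc_mean,
                                          profile$gwc_sd), 0.05),
                   sla = max(stats::rnorm(1L, profile$sla_mean,
                                          profile$sla_sd), 1))
    rec_list[[i]] <- data.frame(
      sample_id = sprintf("field_%03d", i), species = sp,
      leaf_type = "mature", delta15N = traits$delta15N,
      n_content = traits$n_content, gwc = traits$gwc, sla = traits$sla,
      distance_to_canopy = d[i])
    spec_list[[i]] <- simulate_leaf_spectrum(traits, config)
  }
  records <- do.call(rbind, rec_list)
  m <- do.call(rbind, spec_list)
  set <- suppressWarnings(spectra_set(m, config$grid, records$sample_id,
                                      state = "raw"))
  list(spectra = set, records = records)
}

#' Field scenario configuration
#'
#' A single-species config for the distance-gradient design (small
#' needle-like leaves measured pooled; N% sits in the 0.47-0.96 band).
#'
#' @param ... overrides passed to [sim_config()].
#' @return A [sim_config].
#' @export
field_sim_config <- function(...) {
  profiles <- list("C. album" = list(
    nir_plateau = 0.42, vis_base = 0.05, red_edge = 715,
    n_mean = 0.7, n_sd = 0.1, gwc_mean = 1.0, gwc_sd = 0.15,
    sla_mean = 5.0, sla_sd = 0.6, d15n_baseline = -12,
    uptake = c(young = 0, mature = 0, stressed = 0),
    n_plants = 0L, treatments = 0))
  sim_config(species_profiles = profiles, ...)
}

# AIR 15N/14N isotope ratio (standard literature constant)
R_AIR <- 0.0036765

delta_to_atom_fraction <- function(delta) {
  r <- R_AIR * (1 + delta / 1000)
  r / (1 + r)
}

atom_fraction_to_delta <- function(x) {
  r <- x / (1 - x)
  1000 * (r / R_AIR - 1)
}

#' delta15N after adding isotopically labeled N to a pool
#'
#' Exact isotope bookkeeping for a labeling recipe: the pool's delta value
#' is converted to an atom fraction via the AIR ratio, 15N and total N are
#' summed over the pool and all additions, and the result converted back to
#' delta notation.
#'
#' @param pool_mol_N mol N in the pool (> 0).
#' @param pool_delta pool delta15N (permil vs AIR).
#' @param additions list of `c(mol_N, atom_fraction)` pairs (atom fraction
#'   in `[0, 1]`: e.g. 0.98 for 98 atom-% 15N label).
#' @return Resulting delta15N (permil).
#' @export
delta_after_label_addition <- function(pool_mol_N, pool_delta, additions) {
  if (pool_mol_N <= 0) stop("pool_mol_N must be > 0")
  n15 <- pool_mol_N * delta_to_atom_fraction(pool_delta)
  ntot <- pool_mol_N
  for (ad in additions) {
    mol <- ad[[1L]]; af <- ad[[2L]]
    if (mol < 0) stop("addition amounts must be >= 0")
    if (af < 0 || af > 1) stop("atom fraction must be in [0, 1]")
    n15 <- n15 + mol * af
    ntot <- ntot + mol
  }
  atom_fraction_to_delta(n15 / ntot)
}

#' Rank correlation of delta15N with the other leaf traits
#'
#' Spearman rank correlations of delta15N against N%, GWC and SLA within
#' each species, with two-sided p-values — the generator acceptance gate for
#' the labeling design, where delta15N must vary independently of the other
#' traits.
#'
#' @param records metadata data.frame.
#' @param min_n minimum records per species (default 5).
#' @return data.frame: `species`, `covariate`, `rho`, `p_value`.
#' @export
check_covariate_independence <- function(records, min_n = 5L) {
  validate_records(records)
  out <- list()
  for (sp in unique(records$species)) {
    sub <- records[records$species == sp, ]
    if (nrow(sub) < min_n) stop("fewer than ", min_n, " records for ", sp)
    for (cv in c("n_content", "gwc", "sla")) {
      if (stats::sd(sub[[cv]]) == 0) {
        out[[length(out) + 1L]] <- data.frame(species = sp, covariate = cv,
                                              rho = NA_real_,
                                              p_value = NA_real_)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(sub$delta15N, sub[[cv]], method = "spearman"))
      out[[length(out) + 1L]] <- data.frame(species = sp, covariate = cv,
                                            rho = unname(ct$estimate),
                                            p_value = ct$p.value)
    }
  }
  do.call(rbind, out)
}
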