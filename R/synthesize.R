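# Synthetic populations and spectra emulating native MS of a glycosylated
# membrane-protein heterodimer (~127 kDa apoprotein carrying four complex
# N-glycans), its desialylated and dissociated derivatives, and
# mass-photometry event streams.

#' Simulation configuration
#'
#' Defaults emulate the wild-type complex: apoprotein base mass 127027 Da;
#' a fixed glycan "core" of 4 x (HexNAc2Hex3 + core Fuc) = HexNAc8 Hex12
#' Fuc4; a total branch count across the four N-glycans spanning ten
#' consecutive values (the P1-P10 series, one branch = +365.33 Da);
#' antennary fucosylation 0-4 above the core (aF0-aF4, with the tri- and
#' tetra-fucosylated forms more abundant than the bi-fucosylated one);
#' total sialylation 9-16 Neu5Ac; sub-stoichiometric phospho (+79.98),
#' palmitoyl (+238.41) and phospholipid PE (+731, up to two sites)
#' adducts; a charge envelope centred on +26; Gaussian peaks in m/z; and
#' optional detergent-monomer satellite tailing.
#'
#' @param base_mass apoprotein (glycan-free) average mass in Da.
#' @param core named counts of the fixed per-complex glycan core.
#' @param branch_support,branch_prob support and probabilities of the total
#'   branch count.
#' @param afuc_support,afuc_prob antennary-Fuc count distribution.
#' @param neu5ac_support,neu5ac_prob total Neu5Ac count distribution.
#' @param p_phospho,p_palmitoyl per-molecule occupancy probabilities.
#' @param pe_support,pe_prob PE adduct count distribution.
#' @param z_center,z_spread charge-envelope centre and spread (discretized
#'   Gaussian over integer z, truncated at 3 spreads).
#' @param peak_fwhm Gaussian peak full width at half maximum in m/z.
#' @param noise_level additive Gaussian noise s.d. as a fraction of the
#'   maximum peak intensity.
#' @param detergent,detergent_decay,detergent_max detergent monomer name
#'   (see [adduct_table()]), geometric intensity ratio per bound monomer
#'   (0 disables tailing) and maximum satellite order.
#' @param n_molecules number of molecules drawn per population.
#' @param seed RNG seed recorded in all outputs.
#' @return a `sim_config` list (validated).
#' @export
sim_config <- function(base_mass = 127027,
                       core = c(HexNAc = 8, Hex = 12, Fuc = 4),
                       branch_support = 12:21,
                       branch_prob = dnorm(12:21, 16.2, 1.8),
                       afuc_support = 0:4,
                       afuc_prob = c(0.42, 0.12, 0.08, 0.20, 0.18),
                       neu5ac_support = 9:16,
                       neu5ac_prob = dnorm(9:16, 12.5, 1.6),
                       p_phospho = 0.10,
                       p_palmitoyl = 0,
                       pe_support = 0:2,
                       pe_prob = c(0.6, 0.3, 0.1),
                       z_center = 26, z_spread = 2,
                       peak_fwhm = 1.2,
                       noise_level = 0.02,
                       detergent = "OGNG",
                       detergent_decay = 0,
                       detergent_max = 4,
                       n_molecules = 20000,
                       seed = 42) {
  norm1 <- function(p, what) {
    if (any(p < 0) || sum(p) <= 0) stop(what, " probabilities invalid", call. = FALSE)
    p / sum(p)
  }
  stopifnot(base_mass > 0, peak_fwhm > 0, noise_level >= 0,
            z_spread > 0, n_molecules >= 1,
            length(branch_support) == length(branch_prob),
            length(afuc_support) == length(afuc_prob),
            length(neu5ac_support) == length(neu5ac_prob),
            length(pe_support) == length(pe_prob))
  for (p in c(p_phospho, p_palmitoyl, detergent_decay)) {
    if (p < 0 || p > 1) stop("occupancy/decay probabilities must be in [0,1]",
                             call. = FALSE)
  }
  cfg <- list(base_mass = base_mass, core = core,
              branch_support = branch_support,
              branch_prob = norm1(branch_prob, "branch"),
              afuc_support = afuc_support,
              afuc_prob = norm1(afuc_prob, "antennary-Fuc"),
              neu5ac_support = neu5ac_support,
              neu5ac_prob = norm1(neu5ac_prob, "Neu5Ac"),
              p_phospho = p_phospho, p_palmitoyl = p_palmitoyl,
              pe_support = pe_support, pe_prob = norm1(pe_prob, "PE"),
              z_center = z_center, z_spread = z_spread,
              peak_fwhm = peak_fwhm, noise_level = noise_level,
              detergent = detergent, detergent_decay = detergent_decay,
              detergent_max = detergent_max,
              n_molecules = n_molecules, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

# run code under a private seeded RNG stream, restoring global RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# total mass of one proteoform row given a config's base + core
.proteoform_mass <- function(base_mass, core, branch, aFuc, Neu5Ac,
                             phospho, palmitoyl, PE,
                             rt = residue_table(), at = adduct_table()) {
  base_mass +
    composition_mass(core, "average", rt) +
    branch * residue_mass("branch", "average", rt) +
    aFuc * residue_mass("Fuc", "average", rt) +
    Neu5Ac * residue_mass("Neu5Ac", "average", rt) +
    phospho * adduct_mass("phospho", at) +
    palmitoyl * adduct_mass("palmitoyl", at) +
    PE * adduct_mass("PE", at)
}

.relabel_population <- function(pop, branch_origin) {
  p_idx <- pop$branch - branch_origin + 1L
  lab <- paste0("P", p_idx, " aF", pop$aFuc)
  lab <- ifelse(pop$Neu5Ac > 0, paste0(lab, " S", pop$Neu5Ac), lab)
  lab <- ifelse(pop$phospho > 0, paste0(lab, " +P"), lab)
  lab <- ifelse(pop$palmitoyl > 0, paste0(lab, " +Palm"), lab)
  lab <- ifelse(pop$PE > 0, paste0(lab, " +", pop$PE, "PE"), lab)
  pop$label_P <- p_idx
  pop$label <- lab
  pop
}

#' Draw a proteoform population
#'
#' Molecules are drawn independently from the configured glycan and adduct
#' distributions, then aggregated over identical compositions; abundances
#' sum to 1. Labels encode the branch-series index (P, relative to the
#' smallest branch count in the support), the antennary-Fuc count (aF) and
#' any adducts.
#'
#' @param cfg a [sim_config()].
#' @return data.frame (class `proteoform_population`) with columns
#'   `branch`, `aFuc`, `Neu5Ac`, `phospho`, `palmitoyl`, `PE`, `abundance`,
#'   `mass`, `label_P`, `label`; attributes `config` and `seed`.
#' @export
sample_proteoforms <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_molecules
  draws <- with_seed(cfg$seed, {
    data.frame(
      branch = sample(cfg$branch_support, n, TRUE, cfg$branch_prob),
      aFuc = sample(cfg$afuc_support, n, TRUE, cfg$afuc_prob),
      Neu5Ac = sample(cfg$neu5ac_support, n, TRUE, cfg$neu5ac_prob),
      phospho = rbinom(n, 1L, cfg$p_phospho),
      palmitoyl = rbinom(n, 1L, cfg$p_palmitoyl),
      PE = sample(cfg$pe_support, n, TRUE, cfg$pe_prob)
    )
  })
  agg <- aggregate(list(count = rep(1L, n)),
                   by = draws, FUN = sum)
  agg$abundance <- agg$count / n
  agg$count <- NULL
  agg$mass <- .proteoform_mass(cfg$base_mass, cfg$core, agg$branch, agg$aFuc,
                               agg$Neu5Ac, agg$phospho, agg$palmitoyl, agg$PE)
  agg <- .relabel_population(agg, min(cfg$branch_support))
  agg <- agg[order(agg$mass), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("proteoform_population", "data.frame"),
            config = cfg, seed = cfg$seed)
}

#' Charge-envelope weights: discretized Gaussian over integer charge
#' @param cfg a [sim_config()].
#' @return data.frame with `z`, `weight` (sums to 1).
#' @export
charge_weights <- function(cfg) {
  z <- seq.int(max(1L, floor(cfg$z_center - 3 * cfg$z_spread)),
               ceiling(cfg$z_center + 3 * cfg$z_spread))
  w <- dnorm(z, cfg$z_center, cfg$z_spread)
  data.frame(z = z, weight = w / sum(w))
}

#' Render an electrospray spectrum from a proteoform population
#'
#' Each proteoform of mass M contributes Gaussian peaks at
#' `(M + z * 1.00728) / z` for every z in the charge envelope, with
#' intensity proportional to abundance x charge weight. When detergent
#' tailing is enabled, each peak carries satellites at
#' `+k * monomer mass / z` with geometric intensity ratio. Additive
#' Gaussian noise (truncated at 0) is controlled by `noise_level`.
#'
#' @param pop a `proteoform_population` (or data.frame with `mass`,
#'   `abundance`).
#' @param cfg a [sim_config()].
#' @param grid_step m/z grid step; default `peak_fwhm / 6`.
#' @return a `spectrum` object: list with `mz`, `intensity`, `metadata`.
#' @export
render_spectrum <- function(pop, cfg, grid_step = cfg$peak_fwhm / 6) {
  if (nrow(pop) == 0L) stop("empty proteoform population", call. = FALSE)
  zw <- charge_weights(cfg)
  sigma <- cfg$peak_fwhm / (2 * sqrt(2 * log(2)))
  det_m <- if (cfg$detergent_decay > 0) adduct_mass(cfg$detergent) else 0
  kmax <- if (cfg$detergent_decay > 0) cfg$detergent_max else 0L
  det_w <- cfg$detergent_decay^(0:kmax)
  det_w <- det_w / sum(det_w)

  # peak centres and weights for every proteoform x charge x satellite
  M <- rep(pop$mass, each = nrow(zw) * (kmax + 1L))
  ab <- rep(pop$abundance, each = nrow(zw) * (kmax + 1L))
  z <- rep(rep(zw$z, each = kmax + 1L), times = nrow(pop))
  wz <- rep(rep(zw$weight, each = kmax + 1L), times = nrow(pop))
  k <- rep.int(0:kmax, nrow(zw) * nrow(pop))
  mu <- (M + k * det_m + z * PROTON_MASS) / z
  amp <- ab * wz * det_w[k + 1L]

  lo <- min(mu) - 5 * cfg$peak_fwhm
  hi <- max(mu) + 5 * cfg$peak_fwhm
  mz <- seq(lo, hi, by = grid_step)
  y <- numeric(length(mz))
  half <- ceiling(4 * sigma / grid_step)
  idx0 <- round((mu - lo) / grid_step) + 1L
  for (i in seq_along(mu)) {
    j <- max(1L, idx0[i] - half):min(length(mz), idx0[i] + half)
    y[j] <- y[j] + amp[i] * exp(-0.5 * ((mz[j] - mu[i]) / sigma)^2)
  }
  if (cfg$noise_level > 0) {
    y <- with_seed(cfg$seed + 1L, y + rnorm(length(y), 0, cfg$noise_level * max(y)))
    y[y < 0] <- 0
  }
  new_spectrum(mz, y, metadata = list(source = "simulated", seed = cfg$seed,
                                      config_hash = rlang::hash(unclass(cfg))))
}

#' Remove all sialic acid residues (neuraminidase treatment)
#'
#' Sets the Neu5Ac count of every proteoform to zero, recomputes masses
#' and re-aggregates abundances over now-identical compositions. All other
#' residue and adduct counts are untouched; the operation is idempotent.
#'
#' @param pop a `proteoform_population`.
#' @return a `proteoform_population` of size `<= nrow(pop)`.
#' @export
apply_neuraminidase <- function(pop) {
  cfg <- attr(pop, "config")
  pop$Neu5Ac <- 0L
  keys <- c("branch", "aFuc", "Neu5Ac", "phospho", "palmitoyl", "PE")
  agg <- aggregate(list(abundance = pop$abundance), by = pop[keys], FUN = sum)
  agg$mass <- .proteoform_mass(cfg$base_mass, cfg$core, agg$branch, agg$aFuc,
                               agg$Neu5Ac, agg$phospho, agg$palmitoyl, agg$PE)
  agg <- .relabel_population(agg, min(cfg$branch_support))
  agg <- agg[order(agg$mass), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = class(pop), config = cfg, seed = attr(pop, "seed"))
}

#' Dissociate complexes into their two subunits
#'
#' Splits each complex proteoform into a light and a heavy subunit
#' proteoform. N-glycans route to the glycosylated heavy subunit; PTM and
#' lipid adducts route per argument (defaults: phospho, palmitoyl and PE
#' to the light subunit, reflecting their sites on the catalytic chain).
#' Subunit masses sum exactly to the complex mass.
#'
#' @param pop a `proteoform_population` of complexes.
#' @param light_base apoprotein mass of the light subunit (Da); the heavy
#'   subunit base is `base_mass - light_base`.
#' @param lipid_to,phospho_to,palmitoyl_to `"light"` or `"heavy"`.
#' @return list with elements `light` and `heavy`, each a
#'   `proteoform_population`.
#' @export
dissociate <- function(pop, light_base = 55000,
                       lipid_to = "light", phospho_to = "light",
                       palmitoyl_to = "light") {
  cfg <- attr(pop, "config")
  if (light_base <= 0 || light_base >= cfg$base_mass) {
    stop("light_base must lie strictly inside (0, base_mass)", call. = FALSE)
  }
  route <- function(sub) {
    q <- pop
    glyco <- sub == "heavy"
    if (!glyco) { q$branch <- 0L; q$aFuc <- 0L; q$Neu5Ac <- 0L }
    if (phospho_to != sub) q$phospho <- 0L
    if (palmitoyl_to != sub) q$palmitoyl <- 0L
    if (lipid_to != sub) q$PE <- 0L
    base <- if (glyco) cfg$base_mass - light_base else light_base
    core <- if (glyco) cfg$core else cfg$core[0]
    keys <- c("branch", "aFuc", "Neu5Ac", "phospho", "palmitoyl", "PE")
    agg <- aggregate(list(abundance = q$abundance), by = q[keys], FUN = sum)
    agg$mass <- base +
      composition_mass(core, "average") +
      agg$branch * residue_mass("branch", "average") +
      agg$aFuc * residue_mass("Fuc", "average") +
      agg$Neu5Ac * residue_mass("Neu5Ac", "average") +
      agg$phospho * adduct_mass("phospho") +
      agg$palmitoyl * adduct_mass("palmitoyl") +
      agg$PE * adduct_mass("PE")
    agg <- .relabel_population(agg, min(cfg$branch_support))
    agg <- agg[order(agg$mass), , drop = FALSE]
    rownames(agg) <- NULL
    structure(agg, class = class(pop), config = cfg, seed = attr(pop, "seed"))
  }
  list(light = route("light"), heavy = route("heavy"))
}

#' Sample single-particle mass-photometry events from a Gaussian mixture
#'
#' @param components data.frame with columns `mean` (kDa), `sigma` (kDa),
#'   `weight`.
#' @param n number of particles (> 0).
#' @param seed RNG seed.
#' @return numeric vector of event masses (kDa), class `mp_events`, with
#'   attributes `components` and `seed`.
#' @export
sample_mp_events <- function(components, n, seed = 1) {
  stopifnot(is.data.frame(components),
            all(c("mean", "sigma", "weight") %in% names(components)))
  if (n <= 0) stop("n must be positive", call. = FALSE)
  w <- components$weight
  if (any(w < 0) || sum(w) <= 0) stop("invalid mixture weights", call. = FALSE)
  ev <- with_seed(seed, {
    comp <- sample.int(nrow(components), n, TRUE, prob = w / sum(w))
    rnorm(n, components$mean[comp], components$sigma[comp])
  })
  structure(ev, class = "mp_events", components = components, seed = seed)
}
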