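#' Simulation configuration for synthetic qPCR plates
#'
#' Parameters of the synthetic plate generator. The defaults mirror a
#' well-behaved TaqMan assay: calibration Cq = 37.5 - 3.4149 log10(copies)
#' (96.3% efficiency), 0.2-cycle Gaussian Cq noise, every template molecule
#' amplifiable (`per_molecule_efficiency = 1`), and a 10-fold dilution
#' series over seven decades with ten replicates per level.
#'
#' @param curve_slope Calibration slope, cycles per log10(copies); < 0.
#' @param curve_intercept Calibration intercept, cycles at one copy.
#' @param cq_noise_sd Gaussian Cq measurement noise, cycles; >= 0.
#' @param per_molecule_efficiency Probability that a single template
#'   molecule in the reaction is amplified, in (0, 1].
#' @param standards Data frame `copies`, `n_replicates` describing the
#'   dilution series.
#' @param ipc_control_cq Internal-positive-control Cq in a clean reaction.
#' @param replicate_sigma Lognormal replicate-to-replicate variation of
#'   field concentrations, sd on the log10 scale.
#' @param seed Optional integer seed; a fixed seed makes every generated
#'   plate bitwise-reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(curve_slope = -3.4149, curve_intercept = 37.5,
                              cq_noise_sd = 0.2,
                              per_molecule_efficiency = 1.0,
                              standards = data.frame(
                                copies = 10^(0:6),
                                n_replicates = 10L),
                              ipc_control_cq = 28.0,
                              replicate_sigma = 0.3,
                              seed = NULL) {
  stopifnot(curve_slope < 0, cq_noise_sd >= 0,
            per_molecule_efficiency > 0, per_molecule_efficiency <= 1,
            is.data.frame(standards),
            all(c("copies", "n_replicates") %in% names(standards)),
            all(standards$copies > 0), all(standards$n_replicates >= 1),
            replicate_sigma >= 0)
  structure(list(curve_slope = curve_slope,
                 curve_intercept = curve_intercept,
                 cq_noise_sd = cq_noise_sd,
                 per_molecule_efficiency = per_molecule_efficiency,
                 standards = standards,
                 ipc_control_cq = ipc_control_cq,
                 replicate_sigma = replicate_sigma,
                 seed = seed),
            class = "simulation_config")
}

# Cq of a well containing k amplified template molecules (NA when k = 0:
# a reaction with no amplifiable template never crosses the threshold)
sim_cq <- function(k, config) {
  ifelse(k == 0L, NA_real_,
         config$curve_intercept + config$curve_slope * log10(pmax(k, 1)) +
           stats::rnorm(length(k), 0, config$cq_noise_sd))
}

#' Simulate a replicated serial-dilution plate
#'
#' For each standard level with nominal concentration Q, each replicate
#' well receives k ~ Poisson(Q * per_molecule_efficiency) amplifiable
#' templates; the well is a non-detect when k = 0 and otherwise reads
#' Cq = intercept + slope log10(k) + Gaussian noise. Poisson sampling of
#' whole molecules is what produces the rising CV and falling detection
#' probability at low copies that LOD/LOQ estimation relies on.
#'
#' @param config A [simulation_config()].
#' @param assay Assay label written to the plate.
#' @return Plate data frame of `standard` rows (`sample_id`, `replicate`,
#'   `assay`, `reaction_type`, `known_copies`, `cq`).
#' @export
simulate_dilution_series <- function(config = simulation_config(),
                                     assay = "assay1") {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rows <- lapply(seq_len(nrow(config$standards)), function(i) {
    q <- config$standards$copies[i]
    n <- config$standards$n_replicates[i]
    k <- stats::rpois(n, q * config$per_molecule_efficiency)
    data.frame(
      sample_id = sprintf("std_%g", q),
      replicate = seq_len(n),
      assay = assay,
      reaction_type = "standard",
      known_copies = q,
      cq = sim_cq(k, config))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Field-survey design for the synthetic generator
#'
#' Describes a multi-site, two-season, multi-species eDNA survey: site
#' labels with stream class (mainstem vs tributary) and salinity, seasonal
#' per-species mean concentrations, the replicate count per site, and the
#' site-by-season inhibition delay injected into every reaction (species
#' wells and the co-located IPC well alike). When `inhibition_delta` is
#' omitted, delays are generated from salinity as
#' `salinity_inhibition_slope * salinity`, making inhibition positively
#' correlated with salinity by construction.
#'
#' @param sites Data frame `site`, `stream_class`, `salinity`.
#' @param species_means Data frame `assay`, `season`, `mean_copies_per_liter`.
#' @param replicate_count Field replicates (sub-samples) per site.
#' @param inhibition_delta Optional data frame `site`, `season`, `delta_cq`.
#' @param salinity_inhibition_slope Cycles of delay per salinity unit, used
#'   when `inhibition_delta` is `NULL`.
#' @param n_ipc_control Clean IPC control wells per plate.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(sites, species_means, replicate_count = 3L,
                          inhibition_delta = NULL,
                          salinity_inhibition_slope = 0.25,
                          n_ipc_control = 3L) {
  stopifnot(is.data.frame(sites),
            all(c("site", "stream_class", "salinity") %in% names(sites)),
            all(sites$salinity >= 0),
            is.data.frame(species_means),
            all(c("assay", "season", "mean_copies_per_liter") %in%
                  names(species_means)),
            all(species_means$mean_copies_per_liter >= 0),
            replicate_count >= 1L, n_ipc_control >= 1L)
  seasons <- unique(species_means$season)
  if (is.null(inhibition_delta)) {
    inhibition_delta <- expand.grid(site = sites$site, season = seasons,
                                    stringsAsFactors = FALSE)
    inhibition_delta$delta_cq <- salinity_inhibition_slope *
      sites$salinity[match(inhibition_delta$site, sites$site)]
  }
  stopifnot(all(c("site", "season", "delta_cq") %in% names(inhibition_delta)))
  structure(list(sites = sites, seasons = seasons,
                 species_means = species_means,
                 replicate_count = as.integer(replicate_count),
                 inhibition_delta = inhibition_delta,
                 salinity_inhibition_slope = salinity_inhibition_slope,
                 n_ipc_control = as.integer(n_ipc_control)),
            class = "survey_design")
}

#' Default six-site salmon-river survey design
#'
#' A two-season (spawning November / non-spawning March) survey of four
#' Oncorhynchus assays at six sites -- three on the mainstem (1-3) and
#' three on two tributaries (4-6), numbered from downstream. Seasonal mean
#' concentrations follow the field profile of a chum-salmon river: O. keta
#' dominates, rising ~64-fold in the spawning season (1.09e6 vs 1.71e4
#' copies/L), while the three minor species stay low year-round (their
#' spawning-season means sit 626-, 77- and 43-fold below O. keta for
#' O. kisutch, O. masou and O. mykiss). Site-level inhibition delays span
#' -0.33 to 1.33 cycles in the spawning season (seasonal means 0.44 vs
#' 0.07 cycles) and track salinity, which declines upstream.
#'
#' @return A [survey_design()].
#' @export
yangyang_design <- function() {
  sites <- data.frame(
    site = paste0("site", 1:6),
    stream_class = c(rep("mainstem", 3), rep("tributary", 3)),
    salinity = c(4.0, 3.2, 1.5, 0.1, 0.6, 0.3))
  keta_nov <- 1.09e6
  species_means <- rbind(
    data.frame(assay = "O_keta", season = c("spawning", "non_spawning"),
               mean_copies_per_liter = c(keta_nov, 1.71e4)),
    data.frame(assay = "O_kisutch", season = c("spawning", "non_spawning"),
               mean_copies_per_liter = c(keta_nov / 626.10, 1.0e3)),
    data.frame(assay = "O_masou", season = c("spawning", "non_spawning"),
               mean_copies_per_liter = c(keta_nov / 77.11, 1.96e3)),
    data.frame(assay = "O_mykiss", season = c("spawning", "non_spawning"),
               mean_copies_per_liter = c(keta_nov / 42.74, 1.5e3)))
  inhibition_delta <- data.frame(
    site = rep(sites$site, 2),
    season = rep(c("spawning", "non_spawning"), each = 6),
    delta_cq = c(0.80, 1.33, 0.60, -0.33, 0.20, 0.04,
                 0.39, 0.20, 0.10, -0.15, -0.10, -0.02))
  survey_design(sites, species_means, replicate_count = 3L,
                inhibition_delta = inhibition_delta)
}

#' Simulate a multi-site field-survey plate
#'
#' Generates `unknown` wells for every site x season x assay x replicate of
#' the design plus the matching IPC wells and no-template controls. Each
#' replicate's true concentration is the design mean with lognormal
#' replicate variation; copies per reaction are the per-liter concentration
#' divided by the volume factor (50 with default volumes), thinned to whole
#' amplifiable molecules by Poisson sampling. The site's inhibition delay
#' is added to every species Cq and to the co-located `ipc_sample` well, so
#' the inhibition module can recover it; `ipc_control` wells sit at the
#' clean-reaction IPC Cq. Per-site salinity is written to every row.
#'
#' @param design A [survey_design()].
#' @param config A [simulation_config()].
#' @param volumes A [volume_config()]; its copies/L-per-reaction factor is
#'   inverted when converting design means to per-reaction copies, so
#'   simulated and analyzed units round-trip exactly.
#' @return Plate data frame with `unknown`, `ipc_control`, `ipc_sample`,
#'   and `ntc` rows.
#' @export
simulate_field_survey <- function(design, config = simulation_config(),
                                  volumes = volume_config()) {
  stopifnot(inherits(design, "survey_design"),
            inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cpl_per_rxn <- (volumes$elution_volume / volumes$template_volume) /
    volumes$filtration_volume
  assays <- unique(design$species_means$assay)
  delta_key <- paste(design$inhibition_delta$site,
                     design$inhibition_delta$season)

  blank_cols <- function(df, site = NA_character_, season = NA_character_,
                         stream_class = NA_character_, salinity = NA_real_,
                         known_copies = NA_real_) {
    df$site <- site; df$season <- season; df$stream_class <- stream_class
    df$salinity <- salinity; df$known_copies <- known_copies
    df
  }

  rows <- list()
  for (season in design$seasons) {
    for (i in seq_len(nrow(design$sites))) {
      site <- design$sites$site[i]
      scls <- design$sites$stream_class[i]
      sal <- design$sites$salinity[i]
      delta <- design$inhibition_delta$delta_cq[
        match(paste(site, season), delta_key)]
      for (r in seq_len(design$replicate_count)) {
        sid <- sprintf("%s_%s_r%d", site, season, r)
        # species assay wells for this water sub-sample
        for (a in assays) {
          mean_cpl <- design$species_means$mean_copies_per_liter[
            design$species_means$assay == a &
              design$species_means$season == season]
          true_cpl <- mean_cpl *
            10^stats::rnorm(1, 0, config$replicate_sigma)
          lambda <- true_cpl / cpl_per_rxn * config$per_molecule_efficiency
          k <- stats::rpois(1, lambda)
          cq <- sim_cq(k, config)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, replicate = r, assay = a,
            reaction_type = "unknown",
            known_copies = NA_real_,
            cq = if (is.na(cq)) NA_real_ else cq + delta,
            site = site, season = season, stream_class = scls,
            salinity = sal)
        }
        # IPC spiked into the same extract: inhibited by the same delay
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, replicate = r, assay = "IPC",
          reaction_type = "ipc_sample",
          known_copies = NA_real_,
          cq = config$ipc_control_cq + delta +
            stats::rnorm(1, 0, config$cq_noise_sd),
          site = site, season = season, stream_class = scls,
          salinity = sal)
      }
    }
  }
  # clean IPC controls and no-template controls (species + IPC)
  ctrl <- data.frame(
    sample_id = sprintf("ipc_ctrl_r%d", seq_len(design$n_ipc_control)),
    replicate = seq_len(design$n_ipc_control), assay = "IPC",
    reaction_type = "ipc_control",
    cq = config$ipc_control_cq +
      stats::rnorm(design$n_ipc_control, 0, config$cq_noise_sd))
  ntc <- data.frame(
    sample_id = sprintf("ntc_%s", c(assays, "IPC")),
    replicate = 1L, assay = c(assays, "IPC"),
    reaction_type = "ntc", cq = NA_real_)
  out <- rbind(do.call(rbind, rows), blank_cols(ctrl), blank_cols(ntc))
  rownames(out) <- NULL
  out
}

#' Simulate a complete, analysis-ready scenario
#'
#' Bundles a dilution-series plate per assay (for calibration and
#' sensitivity estimation) with a field-survey plate into one table, plus
#' the injected ground truth for parameter-recovery checks.
#'
#' @param scenario `"yangyang-default"` (the [yangyang_design()] survey) or
#'   `"dilution"` (standards only, single assay).
#' @param seed Integer seed driving all randomness.
#' @param config Optional [simulation_config()] overriding the defaults
#'   (its `seed` is replaced by `seed`).
#' @return List with `plate` (combined plate data frame) and `truth`
#'   (the design and configuration that generated it).
#' @export
simulate_scenario <- function(scenario = c("yangyang-default", "dilution"),
                              seed = 1L, config = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(config)) config <- simulation_config()
  config$seed <- NULL  # one seed for the whole scenario, set here
  set.seed(seed)
  if (scenario == "dilution") {
    plate <- simulate_dilution_series(config)
    return(list(plate = plate, truth = list(config = config, seed = seed)))
  }
  design <- yangyang_design()
  assays <- unique(design$species_means$assay)
  std <- do.call(rbind, lapply(assays, function(a)
    simulate_dilution_series(config, assay = a)))
  std$site <- NA_character_; std$season <- NA_character_
  std$stream_class <- NA_character_; std$salinity <- NA_real_
  field <- simulate_field_survey(design, config)
  plate <- rbind(std[names(field)], field)
  rownames(plate) <- NULL
  list(plate = plate, truth = list(design = design, config = config,
                                   seed = seed))
}
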