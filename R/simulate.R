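#' Fluorophore spectral model for the plate simulator
#'
#' Relative excitation response at the three excitation wavelengths used
#' (410/430/477 nm), relative emission response in the two emission
#' channels (477/527 nm), and a brightness scale in RFU per nM. The
#' defaults are hand-set to reproduce the qualitative CFP/YFP behaviour
#' of the assay: the donor bleeds into the acceptor emission channel
#' (emission 527 > 0) and the acceptor is weakly directly excited at the
#' donor wavelengths.
#'
#' @param excitation Named numeric, relative absorption at `"410"`,
#'   `"430"`, `"477"` (values in \[0, 1\]).
#' @param emission Named numeric, relative emission at `"477"`, `"527"`.
#' @param brightness RFU per nM at full excitation/emission response.
#' @return A `fluorophore` list.
#' @export
fluorophore <- function(excitation, emission, brightness) {
  stopifnot(all(c("410", "430", "477") %in% names(excitation)),
            all(c("477", "527") %in% names(emission)),
            all(excitation >= 0 & excitation <= 1),
            all(emission >= 0 & emission <= 1), brightness > 0)
  structure(list(excitation = excitation, emission = emission,
                 brightness = brightness), class = "fluorophore")
}

#' @describeIn fluorophore CFP-like donor: fully excited at 410 nm,
#'   80% at 430 nm, none at 477 nm; bleed-through emission at 527 nm is
#'   25% of the 477 nm emission (so the donor-only alpha coefficient is
#'   0.25).
#' @export
cfp_donor <- function() {
  fluorophore(excitation = c("410" = 1, "430" = 0.8, "477" = 0),
              emission = c("477" = 1, "527" = 0.25), brightness = 10)
}

#' @describeIn fluorophore YFP-like acceptor: fully excited at 477 nm
#'   with weak direct excitation at 410 nm (6%) and 430 nm (8%, so the
#'   acceptor-only beta coefficient is 0.08); emits only at 527 nm.
#' @export
yfp_acceptor <- function() {
  fluorophore(excitation = c("410" = 0.06, "430" = 0.08, "477" = 1),
              emission = c("477" = 0, "527" = 1), brightness = 15)
}

#' Plate noise model
#'
#' Four components: a per-well volume factor shared by every channel read
#' of the well (total dispense error; cancels in the rFRET ratio), a
#' per-well, per-protein concentration jitter (independent dispense error
#' of the donor and acceptor stocks; does NOT cancel in the ratio and is
#' the dominant source of rFRET scatter), a per-read multiplicative
#' factor (detector/flash error), and additive read noise in RFU.
#'
#' @param well_cv CV of the shared per-well volume factor (default 2%).
#' @param conc_cv CV of the independent per-protein concentration jitter
#'   (default 1%).
#' @param read_cv CV of the per-read factor (default 0.2%).
#' @param additive_sd Additive read noise SD in RFU (default 1).
#' @return A `sim_noise` list.
#' @export
sim_noise <- function(well_cv = 0.02, conc_cv = 0.01, read_cv = 0.002,
                      additive_sd = 1) {
  stopifnot(well_cv >= 0, conc_cv >= 0, read_cv >= 0, additive_sd >= 0)
  structure(list(well_cv = well_cv, conc_cv = conc_cv, read_cv = read_cv,
                 additive_sd = additive_sd), class = "sim_noise")
}

#' @describeIn sim_noise All noise components zero (deterministic plates).
#' @export
zero_noise <- function() sim_noise(0, 0, 0, 0)

#' Simulation configuration for one FRET pair
#'
#' Defaults describe the high-affinity assay: donor 100 nM, acceptor
#' 200 nM (1:2 ratio), Kd 35 nM, transfer efficiency 0.25. The companion
#' lower-affinity surface-dimerization assay uses 150/300 nM and
#' Kd 230 nM (`sam_config()`).
#'
#' @param kd_pair Donor-acceptor dissociation constant (molar).
#' @param donor_total,acceptor_total Protein totals (molar).
#' @param donor,acceptor [fluorophore] models.
#' @param transfer_efficiency FRET transfer efficiency E in \[0, 1\]: the
#'   fraction of complexed-donor excitation transferred to the acceptor.
#' @param blank Buffer background intensity (RFU) added to every read.
#' @param noise A [sim_noise] model.
#' @param seed Integer seed; mandatory for any stochastic generator call.
#' @return A `sim_config` list.
#' @export
sim_config <- function(kd_pair = 35e-9, donor_total = 100e-9,
                       acceptor_total = 200e-9, donor = cfp_donor(),
                       acceptor = yfp_acceptor(), transfer_efficiency = 0.25,
                       blank = 150, noise = sim_noise(), seed = 1L) {
  stopifnot(kd_pair >= 0, donor_total >= 0, acceptor_total >= 0,
            transfer_efficiency >= 0, transfer_efficiency <= 1, blank >= 0)
  structure(list(kd_pair = kd_pair, donor_total = donor_total,
                 acceptor_total = acceptor_total, donor = donor,
                 acceptor = acceptor,
                 transfer_efficiency = transfer_efficiency,
                 blank = blank, noise = noise, seed = seed),
            class = "sim_config")
}

#' @describeIn sim_config Configuration of the companion SAM-SAM-like
#'   assay (150/300 nM, Kd 230 nM).
#' @param ... Overrides passed to [sim_config()].
#' @export
sam_config <- function(...) {
  args <- list(...)
  defaults <- list(kd_pair = 230e-9, donor_total = 150e-9,
                   acceptor_total = 300e-9)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# ---------------------------------------------------------------------------
# compound library with seeded ground truth

#' Build a seeded screening library
#'
#' Compound classes and their optical/binding semantics (at the default
#' screening concentration of 100 uM):
#' * `inactive` - no binding, no fluorescence.
#' * `true_inhibitor_A` / `true_inhibitor_B` - competitive binder of the
#'   respective assay's donor with dissociation constant `ki`; optically
#'   silent.
#' * `blue_fluor` - emits at 477 nm under both excitations; alternating
#'   strong (caught by the 5x-background pre-read filter) and moderate
#'   (passes the pre-read, caught by the +/-30% deviation rule)
#'   brightness, so the class splits between the two stage-1 criteria.
#' * `green_fluor` - emits at 527 nm; moderate brightness, caught by the
#'   stage-1 deviation rule.
#' * `excitation_shifted_fluor` - 527 nm emitter excited 20x more
#'   strongly at 430 nm than at 410 nm; invisible to the stage-1 checks
#'   (both run at 410 nm) but caught by the dual-excitation discrepancy.
#' * `dual_quencher` - quenches 20% of the acceptor-emission light in
#'   both assays; ratio change looks like genuine inhibition at both
#'   excitations, so only the pan-assay comparison catches it.
#'
#' @param n_inactive,n_inhibitor_a,n_inhibitor_b,n_blue,n_green,n_shifted,n_quencher
#'   Class counts; the defaults compose a 1,120-compound library.
#' @param ki Inhibitor dissociation constant (molar) for the true
#'   inhibitors.
#' @return Tibble with one row per compound: class, binding parameters
#'   (`ki`, `target_assay`) and optical parameters (relative excitation
#'   `cmp_ex410`/`cmp_ex430`, relative emission `cmp_em477`/`cmp_em527`,
#'   `cmp_brightness` in RFU at 100 uM, and the `quench_527` factor).
#' @export
compound_library <- function(n_inactive = 1079, n_inhibitor_a = 10,
                             n_inhibitor_b = 5, n_blue = 8, n_green = 6,
                             n_shifted = 6, n_quencher = 6, ki = 20e-6) {
  classes <- rep(c("inactive", "true_inhibitor_A", "true_inhibitor_B",
                   "blue_fluor", "green_fluor", "excitation_shifted_fluor",
                   "dual_quencher"),
                 times = c(n_inactive, n_inhibitor_a, n_inhibitor_b,
                           n_blue, n_green, n_shifted, n_quencher))
  n <- length(classes)
  lib <- tibble::tibble(
    compound_id = sprintf("CMP%04d", seq_len(n)),
    class = classes,
    ki = ifelse(grepl("^true_inhibitor", classes), ki, NA_real_),
    target_assay = dplyr::case_when(classes == "true_inhibitor_A" ~ "A",
                                    classes == "true_inhibitor_B" ~ "B",
                                    TRUE ~ NA_character_),
    cmp_ex410 = 0, cmp_ex430 = 0, cmp_em477 = 0, cmp_em527 = 0,
    cmp_brightness = 0, quench_527 = 1)

  blue <- which(classes == "blue_fluor")
  if (length(blue)) {
    lib$cmp_ex410[blue] <- 1; lib$cmp_ex430[blue] <- 1
    lib$cmp_em477[blue] <- 1; lib$cmp_em527[blue] <- 0.05
    # alternate strong / moderate so the class splits between the two
    # stage-1 criteria
    lib$cmp_brightness[blue] <- rep_len(c(1500, 500), length(blue))
  }
  green <- which(classes == "green_fluor")
  if (length(green)) {
    lib$cmp_ex410[green] <- 0.9; lib$cmp_ex430[green] <- 1
    lib$cmp_em527[green] <- 1
    lib$cmp_brightness[green] <- 400
  }
  shifted <- which(classes == "excitation_shifted_fluor")
  if (length(shifted)) {
    lib$cmp_ex410[shifted] <- 0.05; lib$cmp_ex430[shifted] <- 1
    lib$cmp_em527[shifted] <- 1
    lib$cmp_brightness[shifted] <- 400
  }
  quench <- which(classes == "dual_quencher")
  if (length(quench)) lib$quench_527[quench] <- 0.8
  lib
}

# expected per-compound triage outcome under zero noise, per assay
library_truth <- function(lib) {
  excluded <- function(cls) {
    dplyr::case_when(
      cls %in% c("blue_fluor", "green_fluor") ~ "fluorescence",
      cls == "excitation_shifted_fluor" ~ "dual_excitation",
      cls == "dual_quencher" ~ "pan_assay",
      TRUE ~ "none")
  }
  tibble::tibble(
    compound_id = lib$compound_id, class = lib$class,
    excluded_by_a = excluded(lib$class),
    excluded_by_b = excluded(lib$class),
    is_hit_a = lib$class == "true_inhibitor_A",
    is_hit_b = lib$class == "true_inhibitor_B")
}

# ---------------------------------------------------------------------------
# intensity engine

FRET_CHANNELS <- tibble::tibble(
  excitation_nm = c(410, 410, 430, 430, 477),
  emission_nm = c(477, 527, 477, 527, 527))

# Noise-free expected intensity for vectors of well/channel parameters.
# Concentrations in molar; compound brightness referenced to 100 uM.
expected_intensity <- function(config, ex, em, donor, acceptor, da,
                               cmp_ex410 = 0, cmp_ex430 = 0, cmp_em477 = 0,
                               cmp_em527 = 0, cmp_brightness = 0,
                               quench_527 = 1, compound_conc = 0) {
  d_nm <- donor * 1e9; a_nm <- acceptor * 1e9; da_nm <- da * 1e9
  ex_chr <- as.character(ex); em_chr <- as.character(em)
  fd <- config$donor; fa <- config$acceptor
  ex_d <- unname(fd$excitation[ex_chr]); em_d <- unname(fd$emission[em_chr])
  ex_a <- unname(fa$excitation[ex_chr]); em_a <- unname(fa$emission[em_chr])
  e <- config$transfer_efficiency

  donor_term <- (d_nm - e * da_nm) * ex_d * em_d * fd$brightness
  direct_term <- a_nm * ex_a * em_a * fa$brightness
  sens_term <- e * da_nm * ex_d * em_a * fa$brightness
  cmp_ex <- ifelse(ex == 410, cmp_ex410, ifelse(ex == 430, cmp_ex430, 0))
  cmp_em <- ifelse(em == 477, cmp_em477, cmp_em527)
  cmp_term <- cmp_brightness * cmp_ex * cmp_em * (compound_conc / 1e-4)
  quench <- ifelse(em == 527, quench_527, 1)
  config$blank + quench * (donor_term + direct_term + sens_term + cmp_term)
}

# Expand a well table over channels and attach noisy intensities.
# `wells` must carry: well, role, donor_conc, acceptor_conc (numeric,
# zero-filled for blanks) and the compound parameter columns (zeros for
# plain wells). Concentration jitter is drawn here, the complex computed
# from the jittered ("actual") concentrations, then optical noise added.
# Must run inside with_seed().
sim_reads <- function(wells, channels, config, assay = "A") {
  noise <- config$noise
  n <- nrow(wells)
  nominal_d <- wells$donor_conc
  nominal_a <- wells$acceptor_conc
  wells$donor_conc <- nominal_d * (1 + stats::rnorm(n, 0, noise$conc_cv))
  wells$acceptor_conc <- nominal_a * (1 + stats::rnorm(n, 0, noise$conc_cv))
  wells$da <- well_da(wells, config, assay = assay)
  wells$.well_factor <- 1 + stats::rnorm(n, 0, noise$well_cv)
  reads <- tidyr::crossing(wells, channels)
  mu <- expected_intensity(
    config, reads$excitation_nm, reads$emission_nm,
    reads$donor_conc, reads$acceptor_conc, reads$da,
    reads$cmp_ex410, reads$cmp_ex430, reads$cmp_em477, reads$cmp_em527,
    reads$cmp_brightness, reads$quench_527,
    ifelse(is.na(reads$compound_conc), 0, reads$compound_conc))
  m <- nrow(reads)
  reads$intensity <- mu * reads$.well_factor *
    (1 + stats::rnorm(m, 0, noise$read_cv)) +
    stats::rnorm(m, 0, noise$additive_sd)
  dplyr::select(reads, "well", "excitation_nm", "emission_nm", "intensity")
}

blank_compound_cols <- function(wells) {
  defaults <- list(compound_id = NA_character_, compound_conc = NA_real_,
                   cmp_ex410 = 0, cmp_ex430 = 0, cmp_em477 = 0,
                   cmp_em527 = 0, cmp_brightness = 0, quench_527 = 1,
                   ki = NA_real_, target_assay = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(wells)) wells[[nm]] <- defaults[[nm]]
  }
  wells
}

# Equilibrium complex concentration per well (molar). Positive controls
# (chaotrope-disrupted) have no complex; competitive compounds targeting
# this assay displace the probe.
well_da <- function(wells, config, assay = "A") {
  da <- numeric(nrow(wells))
  active <- wells$role != "positive_control" &
    wells$donor_conc > 0 & wells$acceptor_conc > 0
  competing <- active & !is.na(wells$ki) &
    !is.na(wells$target_assay) & wells$target_assay == assay &
    !is.na(wells$compound_conc) & wells$compound_conc > 0
  plain <- active & !competing
  da[plain] <- bound_complex(wells$donor_conc[plain],
                             wells$acceptor_conc[plain], config$kd_pair)
  if (any(competing)) {
    idx <- which(competing)
    combos <- unique(wells[idx, c("donor_conc", "acceptor_conc", "ki",
                                  "compound_conc")])
    combos$da <- vapply(seq_len(nrow(combos)), function(i) {
      competition_equilibrium(combos$donor_conc[i], combos$acceptor_conc[i],
                              config$kd_pair, combos$ki[i],
                              combos$compound_conc[i])$complex_da
    }, 0)
    key <- function(df) paste(df$donor_conc, df$acceptor_conc, df$ki,
                              df$compound_conc)
    da[idx] <- combos$da[match(key(wells[idx, ]), key(combos))]
  }
  da
}

#' Simulate the channel reads of a single well
#'
#' The signal model superimposes, per channel: buffer background, the
#' emission of the non-transferring donor population (D - E*DA), direct
#' acceptor excitation, sensitized emission proportional to E*DA, and any
#' compound fluorescence; compound quenching scales the 527 nm emission.
#' The complex concentration DA comes from [bound_complex()], or from
#' [competition_equilibrium()] when a competitive compound is present.
#'
#' @param config A [sim_config].
#' @param compound Optional single-row compound tibble (as from
#'   [compound_library()]).
#' @param channels Channels to read (data frame with `excitation_nm`,
#'   `emission_nm`); defaults to all five standard channels.
#' @param compound_conc Compound concentration (molar) in the well.
#' @param role Well role; `positive_control` disables binding (chaotrope).
#' @param assay Which assay ("A"/"B") the well belongs to, for
#'   inhibitor targeting.
#' @param seed Seed for the noise draws; `NULL` uses the current RNG
#'   state. Ignored under [zero_noise()].
#' @return Tibble of reads: `well`, `excitation_nm`, `emission_nm`,
#'   `intensity`.
#' @export
simulate_well <- function(config, compound = NULL, channels = FRET_CHANNELS,
                          compound_conc = 100e-6, role = "sample",
                          assay = "A", seed = NULL) {
  if (!all(c("excitation_nm", "emission_nm") %in% names(channels)) ||
      nrow(channels) == 0) {
    abort("Invalid channel specification", class = "fretscreen_error_validation")
  }
  well <- tibble::tibble(well = "A1", role = role,
                         donor_conc = config$donor_total,
                         acceptor_conc = config$acceptor_total)
  well <- blank_compound_cols(well)
  if (!is.null(compound)) {
    compound <- tibble::as_tibble(compound)
    for (nm in intersect(names(compound), names(well))) {
      well[[nm]] <- compound[[nm]][1]
    }
    well$compound_conc <- compound_conc
  }
  with_seed(seed, sim_reads(well, tibble::as_tibble(channels), config,
                            assay = assay))
}

# ---------------------------------------------------------------------------
# scenario generators

#' The standard acceptor concentration ladder for Kd titrations
#'
#' 23 points: 0 to 1,600 nM in 100 nM steps, then 2,000 to 4,000 nM in
#' 400 nM steps, in molar units.
#' @export
default_acceptor_ladder <- function() {
  c(seq(0, 1600, by = 100), seq(2000, 4000, by = 400)) * 1e-9
}

#' Simulate a FRET titration plate
#'
#' Generates three-channel reads ((430,477), (430,527), (477,527)) for a
#' fixed donor concentration against an acceptor ladder, plus donor-only
#' and acceptor-only calibration wells and blanks, as a 384-well plate.
#' The ladder's zero point doubles as the donor-only calibration group.
#'
#' @param config A [sim_config] (kd_pair, donor_total, fluorophores,
#'   noise).
#' @param acceptor_totals Acceptor ladder (molar); default
#'   [default_acceptor_ladder()].
#' @param replicates Wells per ladder point (default 4).
#' @param n_acceptor_only,n_blanks Calibration and blank well counts.
#' @param seed Overrides `config$seed`.
#' @return List: `plate` (a [fret_plate]) and `truth` (tibble with the
#'   generating `kd` and the implied `emfret_max` for the donor used).
#' @export
simulate_titration <- function(config = sim_config(),
                               acceptor_totals = default_acceptor_ladder(),
                               replicates = 4, n_acceptor_only = 4,
                               n_blanks = 4, seed = NULL) {
  if (length(acceptor_totals) < 2) {
    abort("Acceptor ladder needs at least 2 concentrations",
          class = "fretscreen_error_config")
  }
  if (replicates < 1) {
    abort("replicates must be >= 1", class = "fretscreen_error_config")
  }
  seed <- if (is.null(seed)) config$seed else seed

  ladder <- tidyr::crossing(acceptor_conc = acceptor_totals,
                            replicate = seq_len(replicates))
  wells <- dplyr::bind_rows(
    tibble::tibble(role = "sample", donor_conc = config$donor_total,
                   acceptor_conc = ladder$acceptor_conc),
    tibble::tibble(role = "sample", donor_conc = 0,
                   acceptor_conc = rep(2000e-9, n_acceptor_only)),
    tibble::tibble(role = "blank", donor_conc = NA_real_,
                   acceptor_conc = NA_real_)[rep(1, n_blanks), ])
  wells$well <- well_ids(384)[seq_len(nrow(wells))]
  wells <- blank_compound_cols(wells)

  calc <- wells
  calc$donor_conc[is.na(calc$donor_conc)] <- 0
  calc$acceptor_conc[is.na(calc$acceptor_conc)] <- 0

  channels <- dplyr::filter(FRET_CHANNELS, .data$excitation_nm != 410)
  reads <- with_seed(seed, sim_reads(calc, channels, config))
  plate <- fret_plate(
    dplyr::select(wells, "well", "role", "compound_id", "compound_conc",
                  "donor_conc", "acceptor_conc"),
    reads, plate_id = "titration", format = 384)

  emfret_max <- config$transfer_efficiency *
    unname(config$donor$excitation["430"]) *
    unname(config$acceptor$emission["527"]) * config$acceptor$brightness *
    config$donor_total * 1e9
  list(plate = plate,
       truth = tibble::tibble(kd = config$kd_pair, emfret_max = emfret_max,
                              donor_total = config$donor_total))
}

#' Simulate an EmFRET-level titration series
#'
#' Direct generator of corrected EmFRET values from the saturation model
#' with multiplicative Gaussian noise -- the workhorse for Monte-Carlo
#' studies of [fit_kd()] where the spectral plate layer is not under
#' test.
#'
#' @param kd,emfret_max,donor_total Generating parameters (molar / RFU /
#'   molar).
#' @param acceptor_totals Acceptor ladder (molar).
#' @param replicates Replicates per ladder point.
#' @param cv Multiplicative noise CV applied to EmFRET.
#' @param seed Integer seed.
#' @return Tibble: `donor_total`, `acceptor_total`, `replicate`, `emfret`.
#' @export
simulate_titration_emfret <- function(kd, emfret_max = 300,
                                      donor_total = 100e-9,
                                      acceptor_totals = default_acceptor_ladder(),
                                      replicates = 4, cv = 0.02,
                                      seed = 1L) {
  grid <- tidyr::crossing(acceptor_total = acceptor_totals,
                          replicate = seq_len(replicates))
  mu <- emfret_max * bound_complex(donor_total, grid$acceptor_total, kd) /
    donor_total
  with_seed(seed, {
    grid$emfret <- mu * (1 + stats::rnorm(nrow(grid), 0, cv))
  })
  tibble::tibble(donor_total = donor_total,
                 acceptor_total = grid$acceptor_total,
                 replicate = grid$replicate, emfret = grid$emfret)
}

#' Simulate a control plate for quality-control studies
#'
#' Negative controls (intact FRET pair), positive controls (binding
#' disabled, emulating 1 M GdnHCl) and blanks, read at 410 nm excitation
#' in both emission channels.
#'
#' @param config A [sim_config].
#' @param n_neg,n_pos,n_blanks Well counts (defaults mirror the 680+680
#'   replicate verification design in a 1536-well plate).
#' @param format Plate format.
#' @param seed Overrides `config$seed`.
#' @return A [fret_plate].
#' @export
simulate_qc_plate <- function(config = sim_config(), n_neg = 680,
                              n_pos = 680, n_blanks = 16, format = 1536,
                              seed = NULL) {
  seed <- if (is.null(seed)) config$seed else seed
  wells <- tibble::tibble(
    role = rep(c("negative_control", "positive_control", "blank"),
               times = c(n_neg, n_pos, n_blanks)))
  wells$donor_conc <- ifelse(wells$role == "blank", NA_real_,
                             config$donor_total)
  wells$acceptor_conc <- ifelse(wells$role == "blank", NA_real_,
                                config$acceptor_total)
  wells$well <- well_ids(format)[seq_len(nrow(wells))]
  wells <- blank_compound_cols(wells)

  calc <- wells
  calc$donor_conc[is.na(calc$donor_conc)] <- 0
  calc$acceptor_conc[is.na(calc$acceptor_conc)] <- 0

  channels <- dplyr::filter(FRET_CHANNELS, .data$excitation_nm == 410)
  reads <- with_seed(seed, sim_reads(calc, channels, config))
  fret_plate(dplyr::select(wells, "well", "role", "compound_id",
                           "compound_conc", "donor_conc", "acceptor_conc"),
             reads, plate_id = "qc", format = format)
}

#' Simulate the two-assay validatory screen
#'
#' For each assay, generates the compound pre-read plate (compound-only
#' wells at 410 nm excitation, before protein transfer) and the assay
#' plate (FRET pair + compound at 100 uM, read at 410 and 430 nm), with
#' negative/positive controls and blanks, in 1536-well format. A truth
#' table records the intended zero-noise triage outcome of every
#' compound in each assay.
#'
#' @param library Compound table from [compound_library()].
#' @param config_a,config_b Per-assay [sim_config]s (defaults: the
#'   100/200 nM Kd 35 nM pair and the 150/300 nM Kd 230 nM pair).
#' @param compound_conc Screening concentration (molar, default 100 uM).
#' @param n_controls Negative and positive control wells per assay plate.
#' @param n_blanks Blank wells per plate.
#' @param seed Integer seed (single source for all four plates).
#' @return List: `assay_a`, `assay_b` (each `list(pre = , assay = )`,
#'   ready for [run_screen()]) and `truth`.
#' @export
simulate_screen <- function(library = compound_library(),
                            config_a = sim_config(),
                            config_b = sam_config(),
                            compound_conc = 100e-6, n_controls = 32,
                            n_blanks = 16, seed = 1L) {
  if (nrow(library) == 0) {
    abort("Empty compound library", class = "fretscreen_error_config")
  }
  if (nrow(library) + 2 * n_controls + n_blanks > 1536) {
    abort("Library plus controls exceeds the 1536-well plate",
          class = "fretscreen_error_config")
  }

  build_assay <- function(config, assay) {
    cmp_wells <- dplyr::mutate(library, role = "sample",
                               compound_conc = compound_conc)
    # pre-read: compounds only, no proteins
    pre_wells <- dplyr::bind_rows(
      dplyr::mutate(cmp_wells, donor_conc = 0, acceptor_conc = 0),
      blank_compound_cols(
        tibble::tibble(role = rep("blank", n_blanks),
                       donor_conc = 0, acceptor_conc = 0)))
    pre_wells$well <- well_ids(1536)[seq_len(nrow(pre_wells))]
    pre_channels <- dplyr::filter(FRET_CHANNELS, .data$excitation_nm == 410)
    pre_reads <- sim_reads(pre_wells, pre_channels, config, assay = assay)
    pre_map <- dplyr::mutate(
      dplyr::select(pre_wells, "well", "role", "compound_id", "compound_conc"),
      donor_conc = NA_real_, acceptor_conc = NA_real_)
    pre <- fret_plate(pre_map, pre_reads,
                      plate_id = paste0("pre_", assay), format = 1536,
                      assay_label = assay)

    assay_wells <- dplyr::bind_rows(
      dplyr::mutate(cmp_wells, donor_conc = config$donor_total,
                    acceptor_conc = config$acceptor_total),
      blank_compound_cols(tibble::tibble(
        role = rep(c("negative_control", "positive_control"),
                   each = n_controls),
        donor_conc = config$donor_total,
        acceptor_conc = config$acceptor_total)),
      blank_compound_cols(tibble::tibble(
        role = rep("blank", n_blanks), donor_conc = 0, acceptor_conc = 0)))
    assay_wells$well <- well_ids(1536)[seq_len(nrow(assay_wells))]
    assay_channels <- dplyr::filter(FRET_CHANNELS, .data$excitation_nm != 477)
    assay_reads <- sim_reads(assay_wells, assay_channels, config,
                             assay = assay)
    assay_map <- dplyr::select(assay_wells, "well", "role", "compound_id",
                               "compound_conc", "donor_conc", "acceptor_conc")
    assay_map$donor_conc[assay_map$role == "blank"] <- NA_real_
    assay_map$acceptor_conc[assay_map$role == "blank"] <- NA_real_
    plate <- fret_plate(assay_map, assay_reads,
                        plate_id = paste0("assay_", assay), format = 1536,
                        assay_label = assay)
    list(pre = pre, assay = plate)
  }

  out <- with_seed(seed, list(assay_a = build_assay(config_a, "A"),
                              assay_b = build_assay(config_b, "B")))
  out$truth <- library_truth(library)
  out
}

#' Simulate a competition dose-response series
#'
#' Responses are percent inhibition of the probe complex,
#' 100 * (1 - DA(I) / DA(0)), computed from the exact ternary
#' equilibrium, i.e. the normalized readout of a spectrally corrected
#' (EmFRET-style) signal that is linear in the complex concentration.
#' Anchor controls are placed 2 log-units below and above the titrated
#' range: a no-compound control (0% inhibition) and a fully-disrupted
#' control (100%).
#'
#' @param ki True inhibitor dissociation constant (molar).
#' @param donor_total,acceptor_total,kd_probe Probe setup (defaults:
#'   50 nM donor, 100 nM acceptor, Kd 35 nM).
#' @param concentrations Inhibitor ladder (molar); default 11 half-log
#'   points from 10^-7.5 to 10^-2.5 M.
#' @param replicates Replicates per point.
#' @param cv Multiplicative noise CV on the normalized signal.
#' @param anchors Include the two anchor controls.
#' @param seed Integer seed.
#' @return List: `data` (tibble `concentration`, `replicate`, `response`)
#'   and `truth` (tibble with `ki` and the exact half-displacement
#'   concentration `ic50`).
#' @export
simulate_dose_response <- function(ki, donor_total = 50e-9,
                                   acceptor_total = 100e-9,
                                   kd_probe = 35e-9,
                                   concentrations = 10^seq(-7.5, -2.5, 0.5),
                                   replicates = 4, cv = 0, anchors = TRUE,
                                   seed = 1L) {
  if (any(concentrations <= 0)) {
    abort("Inhibitor concentrations must be positive",
          class = "fretscreen_error_config")
  }
  da0 <- bound_complex(donor_total, acceptor_total, kd_probe)
  signal_at <- function(conc) {
    competition_equilibrium(donor_total, acceptor_total, kd_probe, ki,
                            conc)$complex_da / da0
  }
  grid <- tidyr::crossing(concentration = sort(concentrations),
                          replicate = seq_len(replicates))
  grid$signal <- signal_at(grid$concentration)
  if (anchors) {
    anchor <- tidyr::crossing(
      concentration = c(min(concentrations) / 100, max(concentrations) * 100),
      replicate = seq_len(replicates))
    anchor$signal <- rep(c(1, 0), each = replicates)
    grid <- dplyr::bind_rows(anchor[1:replicates, ], grid,
                             anchor[-(1:replicates), ])
  }
  with_seed(seed, {
    grid$signal <- grid$signal * (1 + stats::rnorm(nrow(grid), 0, cv))
  })
  ic50_true <- uniroot(function(lc) signal_at(10^lc) - 0.5,
                       lower = log10(min(concentrations)) - 4,
                       upper = log10(max(concentrations)) + 4,
                       tol = 1e-12)$root
  list(data = tibble::tibble(concentration = grid$concentration,
                             replicate = grid$replicate,
                             response = 100 * (1 - grid$signal)),
       truth = tibble::tibble(ki = ki, ic50 = 10^ic50_true))
}

#' Simulate DSF melting curves for a control and a shifted sample group
#'
#' Each curve is a Boltzmann unfolding transition rising to a peak
#' 10 degrees C above the midpoint, followed by a linear decline
#' (dye-bound aggregate falling apart), sampled at 1 degree C steps over
#' 20-95 degrees C with multiplicative noise.
#'
#' @param tm Control melting temperature (degrees C, inside 20-95).
#' @param delta_tm Stabilization shift of the sample group (degrees C).
#' @param replicates Curves per group (>= 1).
#' @param noise_cv Multiplicative noise CV (default 1%).
#' @param slope Transition width (degrees C).
#' @param seed Integer seed.
#' @return Tibble: `condition` ("control"/"sample"), `replicate`,
#'   `temperature`, `fluorescence`.
#' @export
simulate_melt_curves <- function(tm = 50, delta_tm = 0, replicates = 4,
                                 noise_cv = 0.01, slope = 2, seed = 1L) {
  if (tm <= 20 || tm >= 95 || tm + delta_tm <= 20 || tm + delta_tm >= 95) {
    abort("Melting temperatures must lie inside (20, 95) degrees C",
          class = "fretscreen_error_config")
  }
  if (replicates < 1) {
    abort("replicates must be >= 1", class = "fretscreen_error_config")
  }
  temps <- seq(20, 95, by = 1)
  one_curve <- function(tm_i) {
    peak <- tm_i + 10
    f <- 0.1 + 0.9 / (1 + exp((tm_i - temps) / slope))
    f_peak <- 0.1 + 0.9 / (1 + exp((tm_i - peak) / slope))
    decline <- temps > peak
    f[decline] <- f_peak - 0.02 * (temps[decline] - peak)
    f
  }
  grid <- tidyr::crossing(condition = c("control", "sample"),
                          replicate = seq_len(replicates))
  with_seed(seed, {
    curves <- purrr::pmap(grid, function(condition, replicate) {
      tm_i <- if (condition == "sample") tm + delta_tm else tm
      f <- one_curve(tm_i) * (1 + stats::rnorm(length(temps), 0, noise_cv))
      tibble::tibble(condition = condition, replicate = replicate,
                     temperature = temps, fluorescence = f)
    })
    dplyr::bind_rows(curves)
  })
}
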