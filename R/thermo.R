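#' Sauerbrey conversion of QCM frequency shifts to areal mass
#'
#' Rigid-film Sauerbrey relation `dm = -C * df / n` for an AT-cut quartz
#' crystal, with `C = sqrt(rho_q mu_q) / (2 f0^2)` from standard quartz
#' constants (density 2648 kg m^-3, shear modulus 2.947e10 Pa). For the 5 MHz
#' crystals used in protein adsorption work, C is about 17.7 ng cm^-2 Hz^-1.
#'
#' @param frequency_shift frequency shift df (Hz), vectorized.
#' @param overtone odd overtone number n (1, 3, 5, ...).
#' @param fundamental fundamental resonance frequency (MHz), default 5.
#' @return areal mass (ng cm^-2).
#' @export
sauerbrey_mass <- function(frequency_shift, overtone = 3L, fundamental = 5) {
  if (any(overtone < 1) || any(overtone %% 2 != 1))
    stop_se("'overtone' must be an odd integer >= 1")
  rho_q <- 2648          # kg m^-3
  mu_q <- 2.947e10       # Pa
  f0 <- fundamental * 1e6
  C <- sqrt(rho_q * mu_q) / (2 * f0^2)   # kg m^-2 Hz^-1
  C_ng_cm2 <- C * 1e8                    # 1 kg m^-2 = 1e8 ng cm^-2
  -C_ng_cm2 * frequency_shift / overtone
}

#' Gibbs free energy of adsorption from Langmuir coverage
#'
#' Inverts the Langmuir isotherm at mole-fraction standard state:
#' `theta = mass/gamma_max`, `K = theta / ((1-theta) x)`,
#' `dG = -R T ln K`. Only dG(T) slopes (hence dS) are invariant to the
#' standard-state convention, which is what the barrier extraction uses.
#'
#' @param areal_mass adsorbed areal mass (ng cm^-2); vectorized.
#' @param gamma_max monolayer capacity (ng cm^-2).
#' @param bulk_mole_fraction protein bulk mole fraction x, in (0, 1).
#' @param temperature absolute temperature (K); vectorized with mass.
#' @return dG of adsorption (J mol^-1).
#' @export
coverage_to_dG <- function(areal_mass, gamma_max, bulk_mole_fraction,
                           temperature) {
  if (bulk_mole_fraction <= 0 || bulk_mole_fraction >= 1)
    stop_se("'bulk_mole_fraction' must be in (0,1)")
  if (any(areal_mass <= 0))
    stop_se("'areal_mass' must be > 0")
  if (any(areal_mass >= gamma_max))
    stop_se("'areal_mass' must be < gamma_max (saturated coverage cannot be ",
            "inverted to an equilibrium constant)")
  theta <- areal_mass / gamma_max
  K <- theta / ((1 - theta) * bulk_mole_fraction)
  -.RGAS * temperature * log(K)
}

#' Fit dH and dS from the temperature dependence of dG
#'
#' Linear regression `dG = dH - T dS`; the reported `dS` is minus the slope.
#' Inverse-variance weighting is used when per-point standard errors are
#' supplied.
#'
#' @param series data frame with `temperature_K`, `dG` and optionally
#'   `dG_se`.
#' @return list: `dH`, `dH_se` (J mol^-1), `dS`, `dS_se` (J mol^-1 K^-1),
#'   `n`, `fit` (the underlying `lm`).
#' @export
fit_dG_slope <- function(series) {
  T <- series$temperature_K
  if (length(unique(T)) < 2)
    stop_se("need at least 2 (spec: >= 3) distinct temperatures; slope is ",
            "undefined for a single temperature")
  if (length(unique(T)) < 3)
    warning("fewer than 3 distinct temperatures; slope standard error is unreliable")
  w <- if (!is.null(series$dG_se) && all(series$dG_se > 0))
    1 / series$dG_se^2 else NULL
  fit <- stats::lm(dG ~ temperature_K, data = series, weights = w)
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  list(dH = unname(cf[1]), dH_se = unname(se[1]),
       dS = -unname(cf[2]), dS_se = unname(se[2]),
       n = length(T), fit = fit)
}

#' Per-surface adsorption thermodynamics from a temperature table
#'
#' Runs the coverage-to-dG conversion and the dG(T) slope fit for every
#' surface in a temperature-adsorption table.
#'
#' @param table data frame with `temperature_K`, `mass_ng_cm2`, `surface`
#'   (and optionally `class`).
#' @param gamma_max monolayer capacity (ng cm^-2); a single value or a
#'   named vector per surface. Default `"auto"` estimates it from the
#'   table plateau via [estimate_gamma_max()].
#' @param bulk_mole_fraction protein bulk mole fraction.
#' @return data frame, one row per surface: `surface, class, dH, dH_se,
#'   dS, dS_se, n`.
#' @export
adsorption_thermo <- function(table, gamma_max = "auto",
                              bulk_mole_fraction = 1.26e-7) {
  surfaces <- unique(table$surface)
  rows <- lapply(surfaces, function(s) {
    sub <- table[table$surface == s, ]
    gm <- if (identical(gamma_max, "auto")) estimate_gamma_max(sub)
    else if (length(gamma_max) > 1) gamma_max[[s]] else gamma_max
    dG <- coverage_to_dG(sub$mass_ng_cm2, gm, bulk_mole_fraction,
                         sub$temperature_K)
    sl <- fit_dG_slope(data.frame(temperature_K = sub$temperature_K, dG = dG))
    data.frame(surface = s,
               class = if (!is.null(sub$class)) sub$class[1] else NA_character_,
               dH = sl$dH, dH_se = sl$dH_se, dS = sl$dS, dS_se = sl$dS_se,
               n = sl$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plateau estimate of the monolayer capacity
#'
#' Simple capacity estimate when no instrument calibration is supplied: a
#' small multiple of the largest observed areal mass (the table must then
#' approach saturation somewhere for the estimate to be meaningful).
#'
#' @param table data frame with `mass_ng_cm2`.
#' @param headroom multiplicative headroom above the observed maximum.
#' @return capacity (ng cm^-2).
#' @export
estimate_gamma_max <- function(table, headroom = 1.05) {
  max(table$mass_ng_cm2) * headroom
}

#' Entropic adsorption barrier from SCL vs control slopes
#'
#' The barrier is the excess (negative) adsorption entropy of the
#' orientationally mobile SCL surface relative to the mean of the
#' orientationally fixed SAM controls:
#' `barrier = dS_scl - mean(dS_controls)`, with quadrature error
#' propagation.
#'
#' @param dS_scl adsorption entropy on the SCL surface (J mol^-1 K^-1).
#' @param dS_controls numeric vector of control-surface entropies.
#' @param se_scl,se_controls standard errors (optional).
#' @return list: `barrier`, `barrier_se` (J mol^-1 K^-1).
#' @export
entropic_barrier <- function(dS_scl, dS_controls, se_scl = 0,
                             se_controls = rep(0, length(dS_controls))) {
  if (!length(dS_controls)) stop_se("need at least one control surface")
  m <- length(dS_controls)
  list(barrier = dS_scl - mean(dS_controls),
       barrier_se = sqrt(se_scl^2 + sum(se_controls^2) / m^2))
}

#' Full barrier-recovery chain on a temperature-adsorption table
#'
#' Convenience wrapper: coverage to dG, per-surface slope fits, then
#' SCL-minus-controls barrier. Surface classes are taken from the table's
#' `class` column (`"scl"` vs `"control"`).
#'
#' @inheritParams adsorption_thermo
#' @return list: `barrier`, `barrier_se`, `thermo` (per-surface table).
#' @export
barrier_from_table <- function(table, gamma_max = "auto",
                               bulk_mole_fraction = 1.26e-7) {
  th <- adsorption_thermo(table, gamma_max, bulk_mole_fraction)
  scl <- th[th$class == "scl", ]
  ctl <- th[th$class == "control", ]
  if (nrow(scl) != 1) stop_se("expected exactly one SCL-class surface")
  if (!nrow(ctl)) stop_se("need at least one control-class surface")
  b <- entropic_barrier(scl$dS, ctl$dS, scl$dS_se, ctl$dS_se)
  c(b, list(thermo = th))
}

#' Geometric estimate of the orientational entropy penalty
#'
#' The entropy cost of freezing interfacial orientational fluctuations is
#' estimated from accessible interfacial areas,
#' `dS_unit = R ln(A_constr / A_fluct)` per cooperatively fluctuating unit
#' (a trio of aligned sterols by default), scaled by the number of units
#' constrained under one adsorbing protein.
#'
#' Defaults reconstruct the sterol geometry: constrained upright
#' cross-section 0.38 nm^2, fluctuating long-axis footprint 1.9 nm^2
#' (molecular dimension), trios, and 12 trio units under one lysozyme-sized
#' footprint, giving about -160 J mol^-1 K^-1 per protein.
#'
#' @param area_constrained A_constr (nm^2), interfacial area in the
#'   protein-bound, orientationally constrained state.
#' @param area_fluctuating A_fluct (nm^2), area explored by the free
#'   cooperative orientational fluctuation.
#' @param cooperativity molecules per fluctuating unit (default 3).
#' @param footprint_units fluctuating units constrained per adsorbing
#'   protein (default 12).
#' @return list: `dS_per_unit`, `dS_per_protein` (J mol^-1 K^-1),
#'   `cooperativity`, `footprint_units`.
#' @export
geometric_entropy <- function(area_constrained = 0.38, area_fluctuating = 1.9,
                              cooperativity = 3L, footprint_units = 12L) {
  if (area_constrained <= 0 || area_fluctuating <= 0)
    stop_se("areas must be > 0")
  if (cooperativity < 1 || footprint_units < 1)
    stop_se("'cooperativity' and 'footprint_units' must be >= 1")
  per_unit <- .RGAS * log(area_constrained / area_fluctuating)
  list(dS_per_unit = per_unit,
       dS_per_protein = footprint_units * per_unit,
       cooperativity = as.integer(cooperativity),
       footprint_units = as.integer(footprint_units))
}

#' Express an entropy penalty as hydrogen-bond equivalents
#'
#' `T |dS| / e_hb`: the free-energy cost of the entropy penalty at
#' temperature T, in units of a typical hydrogen-bond energy.
#'
#' @param dS entropy (J mol^-1 K^-1).
#' @param temperature absolute temperature (K), default 310 (37 C).
#' @param e_hb hydrogen-bond energy (kJ mol^-1 per bond), default 20.
#' @return number of hydrogen-bond equivalents.
#' @export
hydrogen_bond_equivalent <- function(dS, temperature = 310, e_hb = 20) {
  if (e_hb <= 0) stop_se("'e_hb' must be > 0")
  temperature * abs(dS) / (e_hb * 1000)
}
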