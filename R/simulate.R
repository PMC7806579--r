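# Seeded generator of ground-truthed ESI-MS1 centroid spectra: adduct and
# replacement-series profiles, multimers, optional 13C envelopes, m/z and
# intensity noise, uniform noise peaks, and co-occurring compounds. Every
# non-noise peak carries its (compound, species) truth so annotation
# recovery is directly checkable.

#' Describe a simulated compound
#'
#' @param name Compound name (appears in the truth table).
#' @param formula Elemental formula string or [parse_formula()] result;
#'   may be `NULL` if `neutral_mass` is given directly.
#' @param base_intensity Intensity of a species with abundance 1, in cps.
#' @param profile Named numeric vector: canonical species label ->
#'   relative abundance in (0, 1]. Must contain `"[M+H]+"` with positive
#'   abundance. Default: a typical positive-ESI small-molecule profile
#'   with sodium/potassium/ammonium adducts, a water loss and a dimer.
#' @param neutral_mass Neutral monoisotopic mass in Da (used when
#'   `formula` is `NULL`).
#' @return A `compound_spec`.
#' @export
compound_spec <- function(name, formula = NULL, base_intensity = 1e5,
                          profile = default_species_profile(),
                          neutral_mass = NULL) {
  if (is.null(formula) && is.null(neutral_mass))
    stop("either formula or neutral_mass is required")
  mass <- if (!is.null(formula)) monoisotopic_mass(formula) else neutral_mass
  if (mass <= 0) stop("neutral mass must be positive")
  if (!("[M+H]+" %in% names(profile)) || profile[["[M+H]+"]] <= 0)
    stop("species profile must contain [M+H]+ with positive abundance")
  if (any(profile <= 0 | profile > 1))
    stop("species abundances must be in (0, 1]")
  carbon <- if (!is.null(formula)) {
    f <- as_formula(formula)
    if ("C" %in% names(f)) unclass(f)[["C"]] else 0L
  } else round(0.045 * mass)  # typical carbon fraction of small metabolites
  structure(list(name = name, neutral_mass = mass, carbon = carbon,
                 base_intensity = base_intensity, profile = profile),
            class = "compound_spec")
}

#' @rdname compound_spec
#' @export
default_species_profile <- function() {
  c("[M+H]+" = 1, "[M+Na]+" = 0.3, "[M+K]+" = 0.15, "[M+NH4]+" = 0.2,
    "[M+H-H2O]+" = 0.1, "[2M+H]+" = 0.1)
}

#' Simulation configuration
#'
#' @param compounds List of [compound_spec()] objects.
#' @param mz_noise_sd Gaussian m/z jitter in Da (default 0.001; TOF-class
#'   accuracy where annotation mass errors have ~1 mmu spread).
#' @param intensity_noise_cv Coefficient of variation of intensities
#'   (default 0.2).
#' @param n_noise_peaks Number of uniform background peaks (default 0).
#' @param noise_mz_range m/z range of noise peaks.
#' @param noise_intensity_range Intensity range of noise peaks (cps).
#' @param isotope_envelopes Add +1/+2 13C peaks with abundance
#'   0.011 x carbon count (default `FALSE`).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `sim_config`.
#' @export
sim_config <- function(compounds, mz_noise_sd = 0.001, intensity_noise_cv = 0.2,
                       n_noise_peaks = 0L, noise_mz_range = c(100, 600),
                       noise_intensity_range = c(500, 5000),
                       isotope_envelopes = FALSE, seed = 1L) {
  if (inherits(compounds, "compound_spec")) compounds <- list(compounds)
  stopifnot(all(vapply(compounds, inherits, logical(1), "compound_spec")))
  structure(list(compounds = compounds, mz_noise_sd = mz_noise_sd,
                 intensity_noise_cv = intensity_noise_cv,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_mz_range = noise_mz_range,
                 noise_intensity_range = noise_intensity_range,
                 isotope_envelopes = isotope_envelopes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a ground-truthed spectrum
#'
#' Places one peak per (compound, profile species) at
#' `ion_mz(M, species) + Normal(0, mz_noise_sd)` with intensity
#' `base x abundance x (1 + Normal(0, cv))`, optionally adds +1/+2 isotope
#' peaks (flaggable by the deisotoper), then appends uniform noise peaks.
#'
#' @param cfg A [sim_config()].
#' @param title Spectrum title.
#' @return List with `spectrum` (an [new_spectrum()]) and `truth`
#'   (data.frame `mz`, `intensity`, `compound`, `species`; isotope and
#'   noise peaks are absent from the truth map).
#' @examples
#' pro <- compound_spec("proline", "C5H9NO2",
#'                      profile = c("[M+H]+" = 1, "[M+K]+" = 0.2, "[2M+H]+" = 0.1))
#' sim <- simulate_spectrum(sim_config(pro, mz_noise_sd = 0, intensity_noise_cv = 0))
#' sim$spectrum
#' @export
simulate_spectrum <- function(cfg, title = "simulated spectrum") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  mz <- numeric(0); int <- numeric(0)
  truth <- data.frame(mz = numeric(0), intensity = numeric(0),
                      compound = character(0), species = character(0),
                      stringsAsFactors = FALSE)
  iso_mz <- numeric(0); iso_int <- numeric(0)
  for (cp in cfg$compounds) {
    for (lab in names(cp$profile)) {
      sp <- parse_species_label(lab)
      m <- ion_mz(cp$neutral_mass, sp) + stats::rnorm(1, 0, cfg$mz_noise_sd)
      i <- cp$base_intensity * cp$profile[[lab]] *
        max(0.05, 1 + stats::rnorm(1, 0, cfg$intensity_noise_cv))
      mz <- c(mz, m); int <- c(int, i)
      truth <- rbind(truth, data.frame(mz = m, intensity = i,
                                       compound = cp$name, species = sp$label,
                                       stringsAsFactors = FALSE))
      if (isTRUE(cfg$isotope_envelopes)) {
        r1 <- 0.011 * cp$carbon * sp$multimer_n
        if (r1 > 0) {
          iso_mz <- c(iso_mz, m + .C13_SPACING); iso_int <- c(iso_int, i * r1)
          if (r1 > 0.2) {  # +2 only worth placing for larger ions
            iso_mz <- c(iso_mz, m + 2 * .C13_SPACING)
            iso_int <- c(iso_int, i * r1^2 / 2)
          }
        }
      }
    }
  }
  if (cfg$n_noise_peaks > 0L) {
    nm <- stats::runif(cfg$n_noise_peaks, cfg$noise_mz_range[1], cfg$noise_mz_range[2])
    ni <- stats::runif(cfg$n_noise_peaks, cfg$noise_intensity_range[1],
                       cfg$noise_intensity_range[2])
    mz <- c(mz, nm); int <- c(int, ni)
  }
  mz <- c(mz, iso_mz); int <- c(int, iso_int)
  s <- new_spectrum(mz, int, title = title)
  list(spectrum = s, truth = truth[order(truth$mz), , drop = FALSE])
}

#' Draw non-interfering compounds for recovery experiments
#'
#' Samples neutral masses uniformly in `mass_range` and rejects draws
#' whose profile species could cross-match another compound's species
#' within `margin` Da under the given closure (so clusters of different
#' compounds stay disjoint by construction).
#'
#' @param n Number of compounds.
#' @param closure Species closure used for the interference check.
#' @param mass_range Neutral mass range in Da.
#' @param profile Species profile given to every compound.
#' @param margin Minimum spacing in Da between any species of one compound
#'   and any closure target of another (default 0.025).
#' @param base_intensity_range Range of base intensities (cps).
#' @return List of [compound_spec()] objects.
#' @export
random_compound_set <- function(n, closure = expand_species_closure(),
                                mass_range = c(100, 400),
                                profile = default_species_profile(),
                                margin = 0.025,
                                base_intensity_range = c(2e4, 2e5)) {
  sp_n <- vapply(closure, function(x) x$multimer_n, integer(1))
  sp_off <- vapply(closure, function(x) x$offset, numeric(1))
  prof_sp <- lapply(names(profile), parse_species_label)
  compounds <- list(); masses <- numeric(0)
  tries <- 0L
  while (length(compounds) < n) {
    tries <- tries + 1L
    if (tries > 1000L) stop("could not place non-interfering compounds; widen mass_range")
    m <- stats::runif(1, mass_range[1], mass_range[2])
    peaks_new <- vapply(prof_sp, function(s) ion_mz(m, s), numeric(1))
    ok <- TRUE
    for (m2 in masses) {
      peaks_old <- vapply(prof_sp, function(s) ion_mz(m2, s), numeric(1))
      # every peak of one compound vs every closure target of the other,
      # plus the 13C window (so isotope-based vetoes cannot cross compounds)
      t_new <- c(as.vector(outer(peaks_new - .PROTON_MASS, seq_along(closure),
                                 function(M, k) sp_n[k] * M + sp_off[k])),
                 peaks_new + .C13_SPACING, peaks_new - .C13_SPACING)
      t_old <- c(as.vector(outer(peaks_old - .PROTON_MASS, seq_along(closure),
                                 function(M, k) sp_n[k] * M + sp_off[k])),
                 peaks_old + .C13_SPACING, peaks_old - .C13_SPACING)
      if (min(abs(outer(t_new, peaks_old, "-"))) < margin ||
          min(abs(outer(t_old, peaks_new, "-"))) < margin) { ok <- FALSE; break }
    }
    if (!ok) next
    masses <- c(masses, m)
    compounds[[length(compounds) + 1L]] <-
      compound_spec(sprintf("compound%02d", length(compounds) + 1L),
                    neutral_mass = m, profile = profile,
                    base_intensity = stats::runif(1, base_intensity_range[1],
                                                  base_intensity_range[2]))
  }
  compounds
}

#' Write a simulated spectrum and its truth table
#'
#' @param sim Result of [simulate_spectrum()].
#' @param mgf_path Output mgf path.
#' @param truth_path Output TSV path for the truth table.
#' @return `mgf_path`, invisibly.
#' @export
write_simulation <- function(sim, mgf_path, truth_path) {
  write_mgf(sim$spectrum, mgf_path)
  utils::write.table(sim$truth, truth_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mgf_path)
}
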