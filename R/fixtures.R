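# Reference fixture spectra, reconstructed deterministically from known
# metabolite formulas and species assignments. These emulate two archetypal
# situations for positive-ESI annotation:
#   - an LC spectrum of co-eluting metabolites where annotation absorbs a
#     neighbour's peaks and a water-loss twin, and
#   - an FIA spectrum with extensive sodium/potassium/calcium replacement
#     series and multimers.
# Intensities are not measured values: they are solved from the ordinal
# facts the fixtures must reproduce (base-peak identity, explained-TIC tie,
# cluster intensity coverages); each block notes the constraint it
# satisfies. A few peaks carry small documented m/z offsets (<= 4 mmu)
# emulating instrument error, so annotation mass errors are realistic.

fixture_peak <- function(formula, label, offset_mmu = 0) {
  ion_mz(monoisotopic_mass(formula), parse_species_label(label)) + offset_mmu / 1000
}

#' Reconstructed LC mixed-metabolite spectrum (19 peaks)
#'
#' A background-subtracted, deisotoped, thresholded spectrum of five
#' co-eluting metabolites: l-proline, trigonelline, creatinine, creatine
#' and homocitrulline, plus a creatinine-proline heterodimer peak and one
#' unrelated background ion. Under the default annotation set it yields
#' three non-singleton clusters (sizes 7, 5, 6: creatine+creatinine,
#' proline+trigonelline, homocitrulline) and one singleton, i.e. 19
#' putative [M+H]+ reduced to 4. Cluster intensity coverages are solved to
#' 37/42/20% (plus 1% for the singleton).
#'
#' @return An `ms_spectrum` with a `truth` attribute (data.frame `mz`,
#'   `compound`, `species`).
#' @export
fixture_lc_mix <- function() {
  pro <- "C5H9NO2"; tri <- "C7H7NO2"; cre <- "C4H9N3O2"
  crn <- "C4H7N3O"; hcit <- "C7H15N3O3"
  p <- list(
    # --- proline cluster (5 peaks, 42% of TIC; 116.0706 is the base peak) ---
    # trigonelline's [M+H]+/[M+K]+ fall inside proline's closure windows
    # ([M+Na]+ at +2.5 mmu, [M+Na+K-H]+ at +2.4 mmu) and are absorbed.
    list(fixture_peak(pro, "[M+H]+"),          3e5, "proline",      "[M+H]+"),
    list(fixture_peak(tri, "[M+H]+"),          4e4, "trigonelline", "[M+H]+"),
    list(fixture_peak(pro, "[M+K]+"),          5e4, "proline",      "[M+K]+"),
    list(fixture_peak(tri, "[M+K]+", -0.8),    1e4, "trigonelline", "[M+K]+"),
    list(fixture_peak(pro, "[2M+H]+"),         2e4, "proline",      "[2M+H]+"),
    # --- creatine cluster (7 peaks, 37% of TIC) ---
    # creatinine differs from creatine by the elements of water, so its
    # [M+H]+/[M+K]+ double as creatine's water losses and merge in.
    list(fixture_peak(crn, "[M+H]+"),          1.2e5, "creatinine", "[M+H]+"),
    list(fixture_peak(cre, "[M+H]+"),          1.5e5, "creatine",   "[M+H]+"),
    list(fixture_peak(cre, "[M+NH4]+"),        1e4,   "creatine",   "[M+NH4]+"),
    list(fixture_peak(crn, "[M+K]+"),          3e4,   "creatinine", "[M+K]+"),
    list(fixture_peak(cre, "[M+Na]+"),         1.5e4, "creatine",   "[M+Na]+"),
    list(fixture_peak(cre, "[M+K]+"),          4e4,   "creatine",   "[M+K]+"),
    list(fixture_peak(cre, "[2M+H]+"),         5e3,   "creatine",   "[2M+H]+"),
    # --- homocitrulline cluster (6 peaks, 20% of TIC) ---
    # +0.9/+0.1 mmu offsets put [M+H]+/[M+H-NH3]+ at their observed values;
    # the bidirectional +/-NH3 edge makes their explained TIC tie exactly,
    # so the candidate must be resolved by connectivity. The [2M+2Na-H]+
    # member is explainable from [M+H]+ (depth 2) but not from the NH3-loss
    # frame (depth 4), which is what gives [M+H]+ the higher connectivity.
    list(fixture_peak(hcit, "[M+H-NH3]+", 0.1), 6e4, "homocitrulline", "[M+H-NH3]+"),
    list(fixture_peak(hcit, "[M+H]+", 0.9),    8e4, "homocitrulline", "[M+H]+"),
    list(fixture_peak(hcit, "[M+Na]+"),        2.5e4, "homocitrulline", "[M+Na]+"),
    list(fixture_peak(hcit, "[M+K]+"),         1.5e4, "homocitrulline", "[M+K]+"),
    # proton-bound creatinine-proline heterodimer; the graph force-fits it
    # as [M+Na+NH3]+ of homocitrulline with a ~+2.6 mmu error
    list(monoisotopic_mass(crn) + monoisotopic_mass(pro) + .PROTON_MASS + 0.0011,
         1.5e4, "creatinine+proline", "heterodimer [M+H]+"),
    list(fixture_peak(hcit, "[2M+2Na-H]+"),    5e3, "homocitrulline", "[2M+2Na-H]+"),
    # --- background singleton (1% of TIC) ---
    list(104.1070, 1e4, "background", "unknown")
  )
  build_fixture(p, "LC mix 1.35 min", rt = 1.35)
}

#' Reconstructed FIA l-proline spectrum (33 peaks)
#'
#' Flow-injection spectrum of l-proline with extensive adduct formation:
#' the main cluster (13 peaks, 61% of TIC) holds the protonated form, its
#' Na/K replacement series, dimers and trimers, with the trimer "potassium"
#' ions actually calcium replacements ([3M+Ca-H]+ series, matched as K
#' forms with ~-8.9 mmu errors since Ca is not in the default set). The
#' equivalent tetramer calcium series forms its own 4-peak cluster (the
#' default set stops at trimers, but the series is internally linked by
#' Na-H steps). Three unrelated 2-peak clusters and 10 background
#' singletons complete the 13+4+2+2+2+10 partition.
#'
#' @return An `ms_spectrum` with a `truth` attribute.
#' @export
fixture_fia_proline <- function() {
  pro <- "C5H9NO2"
  species13 <- c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+2Na-H]+", "[M+3Na-2H]+",
                 "[2M+H]+", "[2M+Na]+", "[2M+K]+", "[2M+2Na-H]+",
                 "[3M+H]+", "[3M+Ca-H]+", "[3M+Na+Ca-2H]+", "[3M+2Na+Ca-3H]+")
  # intensities solved so the main cluster carries exactly 61% of the TIC
  # (and 13/33 = 39% of the peak count); [M+H]+ is the base peak
  int13 <- c(2.5e5, 8e4, 6e4, 5e4, 2e4, 6e4, 3e4, 1.5e4, 1.5e4,
             1e4, 8e3, 7e3, 5e3)
  p <- Map(function(lab, i)
    list(fixture_peak(pro, lab), i, "proline", lab), species13, int13)
  # tetramer calcium replacement series, 6% of TIC, linked by Na-H steps;
  # a shared -3.4 mmu offset emulates the source measurement, keeping the
  # series ~12 mmu away from the [4M+K]+ reading reachable from the dimer
  # peak, so it clusters on its own
  tet <- c("[4M+Ca-H]+", "[4M+Na+Ca-2H]+", "[4M+2Na+Ca-3H]+", "[4M+3Na+Ca-4H]+")
  int4 <- c(2.5e4, 1.5e4, 1.2e4, 8e3)
  p <- c(p, Map(function(lab, i)
    list(fixture_peak(pro, lab, -3.4), i, "proline", lab), tet, int4))
  # three unrelated 2-peak clusters: a water loss, a sodium replacement,
  # and an ambiguous +/-NH3 pair (6.5% of TIC together)
  h2o <- delta_mass("H2O_loss"); na <- delta_mass("Na_adduct"); nh3 <- delta_mass("NH3_adduct")
  p <- c(p, list(
    list(158.0789 + h2o, 1e4, "background pair 1", "[M+H-H2O]+"),
    list(158.0789,       2e4, "background pair 1", "[M+H]+"),
    list(206.1011,       1.2e4, "background pair 2", "[M+H]+"),
    list(206.1011 + na,  8e3,  "background pair 2", "[M+Na]+"),
    list(310.1500,       9e3,  "background pair 3", "[M+H]+ or [M+H-NH3]+"),
    list(310.1500 + nh3, 6e3,  "background pair 3", "[M+NH4]+ or [M+H]+")
  ))
  # background singletons, 26.5% of TIC; values chosen to sit outside every
  # closure window of every other peak
  single_mz <- c(104.1070, 119.0343, 121.0509, 135.0911, 144.1019,
                 166.1452, 195.0876, 218.1385, 244.1656, 288.2031)
  single_int <- c(6e4, 1.5e4, 3e4, 2.5e4, 2e4, 3.5e4, 2.8e4, 2.2e4, 1.2e4, 1.8e4)
  p <- c(p, Map(function(m, i) list(m, i, "background", "unknown"),
                single_mz, single_int))
  build_fixture(p, "FIA l-proline")
}

build_fixture <- function(p, title, rt = NA_real_) {
  mz <- vapply(p, function(x) x[[1]], numeric(1))
  int <- vapply(p, function(x) x[[2]], numeric(1))
  s <- new_spectrum(mz, int, title = title, retention_time = rt)
  truth <- data.frame(mz = mz,
                      compound = vapply(p, function(x) x[[3]], character(1)),
                      species = vapply(p, function(x) x[[4]], character(1)),
                      stringsAsFactors = FALSE)
  attr(s, "truth") <- truth[order(truth$mz), , drop = FALSE]
  s
}
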