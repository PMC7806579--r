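# Independent O(n^2) oracle for the graph builder: a plain double loop over
# all ordered peak pairs and all closure species, with no shared code path
# with build_graph (which uses sorted-vector interval lookups).
oracle_edge_pairs <- function(s, closure, tol) {
  kept <- retained_peaks(s)
  mz <- kept$mz
  pairs <- character(0)
  for (p in seq_along(mz)) {
    M <- mz[p] - proton_mass()
    if (M <= 0) next
    for (q in seq_along(mz)) {
      if (q == p) next
      for (sp in closure) {
        if (sp$label == "[M+H]+") next
        if (abs(mz[q] - ion_mz(M, sp)) <= tol) {
          pairs <- c(pairs, paste(p, q))
          break
        }
      }
    }
  }
  sort(unique(pairs))
}

# edge pairs of a built graph, with bidirectional edges expanded both ways
graph_edge_pairs <- function(g) {
  e <- g$edges
  if (!nrow(e)) return(character(0))
  pairs <- paste(e$parent, e$child)
  rev <- paste(e$child, e$parent)[!e$directed]
  sort(unique(c(pairs, rev)))
}

random_test_spectrum <- function(n_peaks, mz_range = c(80, 600)) {
  mz <- sort(stats::runif(n_peaks, mz_range[1], mz_range[2]))
  new_spectrum(mz, stats::runif(n_peaks, 1e3, 1e5), title = "random")
}

# literal atom-composition mass of an ion species applied to a formula:
# n copies of the molecule plus/minus the species' atom changes, minus one
# electron for the +1 charge; computed without ion_mz/mass_offset
literal_species_mz <- function(formula, sp) {
  f <- parse_formula(formula)
  ems <- element_masses()
  total <- sp$multimer_n * sum(ems[names(f)] * unclass(f))
  # charge-carrier proton as +H
  atoms <- c(H = 1)
  base <- list(Na_adduct = c(Na = 1, H = -1), K_adduct = c(K = 1, H = -1),
               Ca_adduct = c(Ca = 1, H = -2), NH3_adduct = c(N = 1, H = 3),
               H2O_loss = c(O = -1, H = -2), NH3_loss = c(N = -1, H = -3))
  for (nm in names(sp$deltas)) {
    k <- sp$deltas[[nm]]
    if (k == 0) next
    for (el in names(base[[nm]]))
      atoms[el] <- (if (el %in% names(atoms)) atoms[el] else 0) + k * base[[nm]][[el]]
  }
  total + sum(ems[names(atoms)] * atoms) - electron_mass()
}

set_peaks_intensity <- function(s, intensity) {
  s$intensity <- intensity
  s
}
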