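test_that("formula parsing handles counts, implicit 1s and errors", {
  expect_equal(unclass(parse_formula("C5H9NO2"))[c("C", "H", "N", "O")],
               c(C = 5L, H = 9L, N = 1L, O = 2L))
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L),
               ignore_attr = TRUE)
  expect_error(parse_formula("C5Xx2"), "unknown element")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C0H2"), "zero")
})

test_that("monoisotopic masses reproduce known metabolite values", {
  expect_equal(monoisotopic_mass("C5H9NO2"), 115.0633, tolerance = 1e-4)   # l-proline
  expect_equal(monoisotopic_mass("C11H24N6O5"), 320.1808, tolerance = 1e-4) # creatine+homocitrulline dimer
  expect_equal(monoisotopic_mass("C4H7N3O"), 113.0589, tolerance = 1e-4)   # creatinine
  expect_equal(monoisotopic_mass("C4H9N3O2"), 131.0695, tolerance = 1e-4)  # creatine
})

test_that("monoisotopic mass is additive over formula sums", {
  set.seed(42)
  syms <- c("C", "H", "N", "O", "S", "P")
  for (i in 1:25) {
    f1 <- paste0(syms, sample(1:9, 6, replace = TRUE), collapse = "")
    f2 <- paste0(sample(syms, 3), sample(1:9, 3, replace = TRUE), collapse = "")
    both <- paste0(f1, f2)
    expect_equal(monoisotopic_mass(both),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-9)
  }
})

test_that("ion m/z reproduces printed adduct values", {
  k <- ion_species(1, c(K_adduct = 1))
  expect_equal(ion_mz(monoisotopic_mass("C7H7NO2"), k), 176.0108, tolerance = 5e-5) # trigonelline [M+K]+
  expect_equal(ion_mz(monoisotopic_mass("C5H9NO2"), k), 154.0265, tolerance = 5e-5) # proline [M+K]+
  nak <- ion_species(1, c(Na_adduct = 1, K_adduct = 1))
  expect_equal(ion_mz(monoisotopic_mass("C5H9NO2"), nak), 176.0084, tolerance = 5e-5) # proline [M+Na+K-H]+
  # dimer, cross-checked against an element-table-only sum
  dimer <- ion_species(2)
  independent <- 2 * sum(element_masses()[c("C", "H", "N", "O")] *
                           c(5, 9, 1, 2)) + proton_mass()
  expect_equal(ion_mz(monoisotopic_mass("C5H9NO2"), dimer), independent,
               tolerance = 1e-9)
  expect_equal(independent, 231.1339, tolerance = 5e-5)
  expect_error(ion_mz(-5, dimer), "positive")
})

test_that("species deltas match the canonical replacement values", {
  h <- ion_species(1)
  expect_equal(species_delta(h, ion_species(1, c(Na_adduct = 1))), 21.9819,
               tolerance = 5e-5)
  expect_equal(species_delta(h, ion_species(1, c(K_adduct = 1))), 37.9559,
               tolerance = 5e-5)
  expect_equal(species_delta(h, h), 0)
  # Ca-2H computes from standard masses (37.9469, not the rounded 37.9464
  # sometimes quoted from low-precision subtraction)
  expect_equal(species_delta(h, ion_species(1, c(Ca_adduct = 1))), 37.9469,
               tolerance = 5e-5)
  expect_error(species_delta(h, ion_species(2)), "multimer")
})

test_that("creatine and creatinine differ by the elements of water", {
  expect_equal(monoisotopic_mass("C4H9N3O2") - monoisotopic_mass("C4H7N3O"),
               18.0106, tolerance = 5e-5)
})

test_that("species labels round-trip through the parser", {
  cl <- expand_species_closure(max_depth = 3, multimers = 1:3)
  for (sp in cl) {
    back <- parse_species_label(sp$label)
    expect_equal(back$multimer_n, sp$multimer_n, info = sp$label)
    expect_equal(back$offset, sp$offset, tolerance = 1e-9, info = sp$label)
  }
  expect_error(parse_species_label("[M+Mg]+"), "cannot parse")
  expect_error(parse_species_label("[M+2H]+"), "hydrogen balance")
})

test_that("closure contains the sodium replacement series and combinations", {
  cl <- expand_species_closure("Na_adduct", max_depth = 3, multimers = 1)
  labs <- vapply(cl, function(s) s$label, "")
  expect_setequal(labs, c("[M+H]+", "[M+Na]+", "[M+2Na-H]+", "[M+3Na-2H]+"))
  cl2 <- expand_species_closure("H2O_loss", max_depth = 1, multimers = 1)
  expect_setequal(vapply(cl2, function(s) s$label, ""),
                  c("[M+H]+", "[M+H-H2O]+"))
  cl3 <- expand_species_closure(c("Na_adduct", "K_adduct"), max_depth = 2,
                                multimers = 1)
  expect_true("[M+Na+K-H]+" %in% vapply(cl3, function(s) s$label, ""))
})

test_that("replacement series is arithmetic with the Na-H common difference", {
  d <- species_delta(ion_species(1), ion_species(1, c(Na_adduct = 1)))
  M <- monoisotopic_mass("C5H9NO2")
  prev <- ion_mz(M, ion_species(1))
  for (n in 1:5) {
    cur <- ion_mz(M, ion_species(1, c(Na_adduct = n)))
    expect_equal(cur - prev, d, tolerance = 1e-9)
    prev <- cur
  }
})

test_that("closure species offsets equal the sum of their derivation deltas", {
  cl <- expand_species_closure(max_depth = 3, multimers = 1:3, max_losses = 3)
  M <- 222.1234
  for (sp in cl) {
    frame <- ion_species(sp$multimer_n)
    step_sum <- sum(vapply(names(sp$deltas), function(nm)
      sp$deltas[[nm]] * species_delta(ion_species(1),
                                      ion_species(1, stats::setNames(1L, nm))),
      numeric(1)))
    expect_equal(ion_mz(M, sp) - ion_mz(M, frame), step_sum, tolerance = 1e-6)
  }
})

test_that("ion_mz agrees with brute-force atom bookkeeping for random species", {
  set.seed(7)
  formulas <- c("C5H9NO2", "C4H7N3O", "C7H7NO2", "C6H14N2O2", "C9H14N4O3")
  delta_pool <- base_delta_names()
  for (i in 1:100) {
    f <- sample(formulas, 1)
    n <- sample(1:3, 1)
    k <- sample(0:3, 1)
    deltas <- table(sample(delta_pool, k, replace = TRUE))
    sp <- ion_species(n, stats::setNames(as.integer(deltas), names(deltas)))
    expect_equal(ion_mz(monoisotopic_mass(f), sp),
                 literal_species_mz(f, sp), tolerance = 1e-9)
  }
})
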