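cfg <- annotation_config()

test_that("match_delta finds relations within tolerance", {
  m <- match_delta(21.9822, cfg$closure, 0.010)
  expect_equal(m$label[1], "[M+Na]+")
  na_delta <- species_delta(ion_species(1), ion_species(1, c(Na_adduct = 1)))
  expect_equal(m$mass_error[1], 21.9822 - na_delta, tolerance = 1e-9)
  expect_true(all(m$directed[m$label == "[M+Na]+"]))
  expect_equal(nrow(match_delta(5.0, cfg$closure, 0.010)), 0)
  expect_error(match_delta(1, cfg$closure, -1), "positive")
})

test_that("a +17.027 shift is returned as both readings, undirected", {
  m <- match_delta(17.0270, cfg$closure, 0.010)
  expect_setequal(m$label, c("[M+NH4]+", "[M+H-NH3]+"))
  expect_true(all(!m$directed))
})

test_that("the proline three-peak spectrum wires [M+K]+ and [2M+H]+ to [M+H]+", {
  s <- new_spectrum(c(116.0706, 154.0265, 231.1339), c(1e5, 2e4, 1e4))
  g <- build_graph(s, cfg$closure, cfg$tolerance)
  tab <- data.frame(parent = g$nodes$mz[g$edges$parent],
                    child = g$nodes$mz[g$edges$child], label = g$edges$label)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$label, c("[M+K]+", "[2M+H]+"))
  expect_true(all(tab$parent == 116.0706))
})

test_that("unrelated peaks stay unconnected and tiny spectra give empty graphs", {
  s <- new_spectrum(c(100.0, 300.0), c(1e4, 1e4))
  expect_equal(nrow(build_graph(s, cfg$closure, cfg$tolerance)$edges), 0)
  s1 <- new_spectrum(150.0, 1e4)
  g1 <- build_graph(s1, cfg$closure, cfg$tolerance)
  expect_equal(nrow(g1$edges), 0)
  expect_equal(nrow(g1$nodes), 1)
})

test_that("graph builder matches the brute-force pairwise oracle", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    s <- random_test_spectrum(n)
    g <- build_graph(s, cfg$closure, cfg$tolerance)
    expect_identical(graph_edge_pairs(g), oracle_edge_pairs(s, cfg$closure, cfg$tolerance))
  }
  # and on the structured fixtures
  for (s in list(fixture_lc_mix(), fixture_fia_proline())) {
    f <- filter_spectrum(s, cfg$filter)
    g <- build_graph(f, cfg$closure, cfg$tolerance)
    expect_identical(graph_edge_pairs(g), oracle_edge_pairs(f, cfg$closure, cfg$tolerance))
  }
})

test_that("edge errors respect the tolerance and vanish as it tightens", {
  set.seed(23)
  for (i in 1:10) {
    s <- random_test_spectrum(40)
    g <- build_graph(s, cfg$closure, cfg$tolerance)
    if (nrow(g$edges)) expect_true(all(abs(g$edges$mass_error) <= cfg$tolerance))
    g0 <- build_graph(s, cfg$closure, 1e-9)
    expect_equal(nrow(g0$edges), 0)  # random m/z never lands exactly
  }
  # exact synthetic peaks survive a near-zero tolerance
  d <- species_delta(ion_species(1), ion_species(1, c(Na_adduct = 1)))
  s <- new_spectrum(c(116.070605, 116.070605 + d), c(1e5, 1e4))
  g <- build_graph(s, cfg$closure, 1e-7)
  expect_equal(nrow(g$edges), 1)
})

test_that("graph topology depends only on m/z, not intensity", {
  set.seed(29)
  s <- random_test_spectrum(30)
  g1 <- build_graph(s, cfg$closure, cfg$tolerance)
  s2 <- set_peaks_intensity(s, s$intensity * runif(30, 0.5, 2))
  g2 <- build_graph(s2, cfg$closure, cfg$tolerance)
  expect_identical(graph_edge_pairs(g1), graph_edge_pairs(g2))
})

test_that("a larger closure can only add edges (monotonicity)", {
  small <- annotation_config(base_deltas = c("Na_adduct", "H2O_loss"),
                             multimers = 1:2, max_depth = 2)
  set.seed(31)
  for (i in 1:10) {
    s <- random_test_spectrum(30)
    e_small <- graph_edge_pairs(build_graph(s, small$closure, 0.010))
    e_big <- graph_edge_pairs(build_graph(s, cfg$closure, 0.010))
    expect_true(all(e_small %in% e_big))
  }
})

test_that("multimer, loss and adduct edges point in the documented direction", {
  M <- monoisotopic_mass("C5H9NO2")
  s <- new_spectrum(c(M - 18.010565 + 1.007276, M + 1.007276,
                      M + 22.989220, 2 * M + 1.007276),
                    c(1e3, 1e5, 2e4, 5e3))
  g <- build_graph(s, cfg$closure, cfg$tolerance)
  e <- data.frame(parent = g$nodes$mz[g$edges$parent],
                  child = g$nodes$mz[g$edges$child], label = g$edges$label)
  mh <- M + 1.007276
  expect_true(any(e$parent == mh & e$label == "[M+H-H2O]+"))  # precursor -> product
  expect_true(any(e$parent == mh & e$label == "[M+Na]+"))     # protonated -> adducted
  expect_true(any(e$parent == mh & e$label == "[2M+H]+"))     # monomer -> multimer
})

test_that("graph exports to GraphML and DOT", {
  a <- annotate_spectrum(fixture_lc_mix())
  g1 <- withr::local_tempfile(fileext = ".graphml")
  g2 <- withr::local_tempfile(fileext = ".dot")
  write_annotation_graph(a$graph, g1, "graphml")
  write_annotation_graph(a$graph, g2, "dot")
  expect_true(any(grepl("mass_error_mmu", readLines(g1))))
  expect_gt(length(readLines(g2)), nrow(a$graph$nodes))
})
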