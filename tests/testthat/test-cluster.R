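cfg <- annotation_config()

test_that("weak components partition the nodes deterministically", {
  s <- new_spectrum(sort(runif(5, 100, 500)), rep(1e4, 5))
  g <- build_graph(s, cfg$closure, 1e-9)
  cl <- clusters(g)
  expect_length(cl, 5)
  expect_true(all(vapply(cl, `[[`, logical(1), "is_singleton")))
  # a chained replacement series collapses to one cluster
  mzs <- 116.070605 + 21.981944 * 0:4
  g2 <- build_graph(new_spectrum(mzs, rep(1e4, 5)), cfg$closure, 0.010)
  cl2 <- clusters(g2)
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$members, 1:5)
  # ids ordered by minimum member m/z
  a <- annotate_spectrum(fixture_lc_mix())
  mins <- vapply(a$clusters, function(x) min(a$graph$nodes$mz[x$members]), 0)
  expect_false(is.unsorted(mins))
})

test_that("explained set, TIC and connectivity follow edge direction", {
  s <- new_spectrum(c(116.0706, 154.0265, 231.1339), c(1e5, 2e4, 1e4))
  g <- build_graph(s, cfg$closure, cfg$tolerance)
  root <- explain(g, 1)
  expect_equal(root$explained, 1:3)
  expect_equal(root$explained_tic, 1.3e5)
  expect_equal(root$connectivity, 2)  # 116 explains 154 and 231
  leaf <- explain(g, 3)
  expect_equal(leaf$explained, 3)     # 231 explains only itself
  expect_equal(leaf$connectivity, 0)
})

test_that("candidates maximize explained TIC with connectivity tie-break", {
  # simple two-peak [M+H]+/[M+Na]+ cluster: protonated form wins
  s <- new_spectrum(c(116.070605, 138.052549), c(1e5, 2e4))
  g <- build_graph(s, cfg$closure, cfg$tolerance)
  rk <- rank_candidates(g, clusters(g)[[1]])
  expect_equal(rk$mz, 116.070605)
  # candidate explained TIC dominates every member (fixtures + random)
  for (a in list(annotate_spectrum(fixture_lc_mix()),
                 annotate_spectrum(fixture_fia_proline()))) {
    for (i in seq_len(nrow(a$candidates))) {
      cc <- a$clusters[[a$candidates$cluster_id[i]]]
      tics <- vapply(cc$members, function(v) explain(a$graph, v)$explained_tic, 0)
      expect_gte(a$candidates$explained_tic[i] + 1e-9, max(tics))
    }
  }
})

test_that("the homocitrulline-style explained-TIC tie resolves by connectivity", {
  a <- annotate_spectrum(fixture_lc_mix())
  hc <- a$candidates[a$candidates$cluster_id == 4, ]
  expect_equal(hc$candidate_mz, 190.1195, tolerance = 5e-5)
  expect_equal(hc$n_alternates, 1L)  # 173.0922 ties on explained TIC
  # the tie is real: both frames explain the identical peak set
  cc <- a$clusters[[4]]
  tic173 <- explain(a$graph, cc$members[1])$explained_tic
  tic190 <- explain(a$graph, cc$members[2])$explained_tic
  expect_equal(tic173, tic190)
  conn <- vapply(cc$members, function(v) explain(a$graph, v)$connectivity, 0)
  expect_gt(explain(a$graph, cc$members[2])$connectivity,
            explain(a$graph, cc$members[1])$connectivity)
})

test_that("cluster indexes report CGC and percentage coverages", {
  a <- annotate_spectrum(fixture_fia_proline())
  main <- a$candidates[1, ]
  expect_equal(main$cgc, 13)
  expect_equal(round(main$ccc), 39)  # 13 of 33 retained peaks
  # degenerate full-coverage case
  s <- new_spectrum(c(116.070605, 138.052549), c(1e5, 2e4))
  g <- build_graph(s, cfg$closure, cfg$tolerance)
  idx <- cluster_indexes(clusters(g)[[1]], g, s)
  expect_equal(idx$cic, 100)
  expect_equal(idx$ccc, 100)
  expect_error(cluster_indexes(clusters(g)[[1]], g,
                               new_spectrum(numeric(0), numeric(0))),
               "zero-TIC")
})

test_that("CIC and CCC sum to 100% over all clusters of a spectrum", {
  set.seed(37)
  specs <- c(list(fixture_lc_mix(), fixture_fia_proline()),
             lapply(1:8, function(i) random_test_spectrum(sample(5:40, 1))))
  for (s in specs) {
    a <- annotate_spectrum(s)
    expect_equal(sum(a$indexes$cic), 100, tolerance = 1e-9)
    expect_equal(sum(a$indexes$ccc), 100, tolerance = 1e-9)
  }
})

test_that("singletons are reported separately, not ranked", {
  a <- annotate_spectrum(fixture_lc_mix())
  expect_equal(nrow(a$singletons), 1)
  expect_equal(a$singletons$mz, 104.1070)
  expect_false(104.1070 %in% a$candidates$candidate_mz)
  expect_error(rank_candidates(a$graph, a$clusters[[1]]), "singleton")
})

test_that("candidate and annotation tables cover the batch", {
  ann <- annotate_batch(list(fixture_lc_mix(), fixture_fia_proline()))
  ct <- candidate_table(ann)
  expect_equal(nrow(ct), 3 + 5)
  expect_true(all(c("title", "candidate_mz", "cgc", "cic", "ccc", "members")
                  %in% names(ct)))
  at <- annotation_table(ann)
  expect_true(all(abs(at$mass_error_mmu) <= 10))
  expect_equal(nrow(candidate_table(annotate_batch(list(
    new_spectrum(c(100, 300), c(1e4, 1e4)))))), 0)
})

test_that("synthetic multi-compound spectra recover the true [M+H]+ peaks", {
  set.seed(41)
  for (i in 1:10) {
    cps <- random_compound_set(sample(1:4, 1))
    sim <- simulate_spectrum(sim_config(cps, seed = 500 + i))
    a <- annotate_spectrum(sim$spectrum)
    truth_mh <- sort(sim$truth$mz[sim$truth$species == "[M+H]+"])
    expect_equal(sort(a$candidates$candidate_mz), truth_mh, tolerance = 1e-6)
  }
})

test_that("a 18.0106 Da pair reproduces the documented water-loss misannotation", {
  # creatinine co-occurring with creatine: the creatinine [M+H]+ is absorbed
  # as [M+H-H2O]+ of creatine and the cluster candidate is creatine - the
  # documented wrong answer that only chromatography can fix
  crn <- compound_spec("creatinine", "C4H7N3O", base_intensity = 8e4,
                       profile = c("[M+H]+" = 1, "[M+K]+" = 0.25))
  cre <- compound_spec("creatine", "C4H9N3O2", base_intensity = 1.5e5,
                       profile = c("[M+H]+" = 1, "[M+K]+" = 0.25))
  sim <- simulate_spectrum(sim_config(list(crn, cre), mz_noise_sd = 0,
                                      intensity_noise_cv = 0, seed = 1))
  a <- annotate_spectrum(sim$spectrum)
  expect_equal(nrow(a$candidates), 1)  # both compounds merged into one cluster
  expect_equal(a$candidates$candidate_mz,
               ion_mz(monoisotopic_mass("C4H9N3O2"), ion_species(1)),
               tolerance = 1e-6)
  at <- annotation_table(a)
  expect_true(any(at$label == "[M+H-H2O]+"))  # creatinine annotated as the loss
})

test_that("heterodimer scan flags proton-bound combination peaks", {
  crn_mh <- ion_mz(monoisotopic_mass("C4H7N3O"), ion_species(1))
  pro_mh <- ion_mz(monoisotopic_mass("C5H9NO2"), ion_species(1))
  s <- new_spectrum(c(crn_mh, pro_mh, 229.1295), c(1e5, 1e5, 2e3))
  hits <- heterodimer_scan(s, c(crn_mh, pro_mh), tol = 0.010)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mz, 229.1295)
  expect_equal(hits$expected_mz,
               monoisotopic_mass("C4H7N3O") + monoisotopic_mass("C5H9NO2") +
                 proton_mass(), tolerance = 1e-6)
  # creatine + homocitrulline combination near 321.188
  cre_mh <- ion_mz(monoisotopic_mass("C4H9N3O2"), ion_species(1))
  hcit_mh <- ion_mz(monoisotopic_mass("C7H15N3O3"), ion_species(1))
  s2 <- new_spectrum(c(cre_mh, hcit_mh, 321.1881), c(1e5, 1e5, 800))
  hits2 <- heterodimer_scan(s2, c(cre_mh, hcit_mh), tol = 0.010)
  expect_equal(hits2$mz, 321.1881)
  # no candidate pairs -> nothing flagged
  expect_equal(nrow(heterodimer_scan(s, pro_mh, tol = 0.010)), 0)
})
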