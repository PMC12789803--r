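# The synthetic-structure generator: determinism, modification chemistry,
# ensembles, and graceful degradation under coordinate noise.

test_that("builds are deterministic and different seeds differ only in
          noise", {
  s1 <- build_hairpin(hairpin_spec(noise_sigma = 0.1, seed = 5))
  s2 <- build_hairpin(hairpin_spec(noise_sigma = 0.1, seed = 5))
  expect_identical(s1$entry$models[[1]], s2$entry$models[[1]])
  s3 <- build_hairpin(hairpin_spec(noise_sigma = 0.1, seed = 6))
  expect_equal(s3$entry$models[[1]]$atom, s1$entry$models[[1]]$atom)
  expect_false(identical(s3$entry$models[[1]]$x, s1$entry$models[[1]]$x))
})

test_that("generator output always parses and passes the quality screen", {
  bh <- build_hairpin(hairpin_spec(
    stem_seq = "GGG", loop_seq = "UUCAAAG",
    modifications = data.frame(position = c(4, 5),
                               comp_id = c("PSU", "5MU"))))
  path <- withr::local_tempfile(fileext = ".cif")
  write_structure_cif(bh$entry, path)
  e <- parse_structure(path)
  sm <- screen_model(e$models[[1]])
  expect_equal(nrow(sm$rejections), 0)
  expect_equal(nrow(sm$model), nrow(bh$entry$models[[1]]))
})

test_that("each modification edits the chemistry as documented", {
  base <- build_hairpin(hairpin_spec(stem_seq = "GG", loop_seq = "UUCAAAG"))
  m0 <- base$entry$models[[1]]
  n_u <- sum(m0$seq == 3)
  expect_equal(n_u, length(component_atoms("U")))
  gidx <- urimod:::residue_gidx

  m5 <- apply_modification(m0, 3, "5MU")
  expect_equal(sum(m5$seq == 3), n_u + 1)
  expect_true("C5M" %in% m5$atom[m5$seq == 3])
  expect_equal(unique(m5$comp[m5$seq == 3]), "5MU")

  m3 <- apply_modification(m0, 3, "UR3")
  expect_true("C3U" %in% m3$atom[m3$seq == 3])

  mo <- apply_modification(m0, 3, "OMU")
  expect_true("CM2" %in% mo$atom[mo$seq == 3])
  cm2 <- mo[mo$seq == 3 & mo$atom == "CM2", ]
  o2p <- mo[mo$seq == 3 & mo$atom == "O2'", ]
  d <- sqrt((cm2$x - o2p$x)^2 + (cm2$y - o2p$y)^2 + (cm2$z - o2p$z)^2)
  expect_equal(d, 1.43, tolerance = 1e-6)

  ms <- apply_modification(m0, 3, "4SU")
  expect_false("O4" %in% ms$atom[ms$seq == 3])
  s4 <- ms[ms$seq == 3 & ms$atom == "S4", ]
  expect_equal(s4$element, "S")
  c4 <- ms[ms$seq == 3 & ms$atom == "C4", ]
  d <- sqrt((s4$x - c4$x)^2 + (s4$y - c4$y)^2 + (s4$z - c4$z)^2)
  expect_equal(d, 1.68, tolerance = 1e-6)

  mh <- apply_modification(m0, 3, "H2U")
  ring0 <- m0[m0$seq == 3 & m0$atom %in% c("N1", "C2", "N3", "C4"), ]
  c5 <- mh[mh$seq == 3 & mh$atom == "C5", ]
  # C5 has left the plane of the remaining sp2 atoms
  xyz <- as.matrix(ring0[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  nrm <- svd(sweep(xyz, 2, ctr), nu = 0, nv = 3)$v[, 3]
  off <- abs(sum((as.numeric(c5[, c("x", "y", "z")]) - ctr) * nrm))
  expect_gt(off, 0.2)

  mp <- apply_modification(m0, 3, "PSU")
  # the C-glycoside: C5 now sits within bonding distance of C1'
  c5p <- mp[mp$seq == 3 & mp$atom == "C5", ]
  c1p <- mp[mp$seq == 3 & mp$atom == "C1'", ]
  d <- sqrt((c5p$x - c1p$x)^2 + (c5p$y - c1p$y)^2 + (c5p$z - c1p$z)^2)
  expect_lt(d, 1.7)
  # name set is unchanged
  expect_setequal(mp$atom[mp$seq == 3], m0$atom[m0$seq == 3])

  # non-U targets are refused
  expect_error(apply_modification(m0, 1, "PSU"), "not U")
})

test_that("ensembles plant a recoverable representative", {
  bh <- build_hairpin(hairpin_spec(stem_seq = "GG", loop_seq = "GAAA"))
  # sigma = 0: all models identical, tie-break to model 1
  flat <- make_ensemble(bh$entry, 4, 0, seed = 2)
  expect_equal(attr(select_nmr_representative(flat),
                    "representative_index"), 1)
  # planted model at sigma/10 is recovered
  ens <- make_ensemble(bh$entry, 10, 0.5, seed = 7,
                       planted_representative = 3)
  expect_equal(attr(select_nmr_representative(ens),
                    "representative_index"), 3)
  # two seeds: same topology, different coordinates
  e1 <- make_ensemble(bh$entry, 3, 0.3, seed = 1)
  e2 <- make_ensemble(bh$entry, 3, 0.3, seed = 2)
  expect_equal(e1$models[[2]]$atom, e2$models[[2]]$atom)
  expect_false(identical(e1$models[[2]]$x, e2$models[[2]]$x))
})

test_that("infeasible loops raise a generation error", {
  expect_error(build_hairpin(hairpin_spec(stem_seq = "GG", loop_seq = "G")),
               "GENERATION_ERROR")
  expect_error(build_hairpin(hairpin_spec(stem_seq = "G",
                                          loop_seq = "GAAA")),
               "GENERATION_ERROR")
})

test_that("loop-size recovery survives 0.25 A coordinate noise", {
  hits <- 0L
  for (k in 1:50) {
    bh <- build_hairpin(hairpin_spec(stem_seq = "GG", loop_seq = "UUCAAAG",
                                     noise_sigma = 0.25, seed = 2000 + k))
    ann <- annotate_model(bh$entry$models[[1]])
    types <- vapply(ann$sses, `[[`, character(1), "sse_type")
    hp <- ann$sses[types == "HAIRPIN"]
    if (length(hp) == 1 && hp[[1]]$loop_size == 7) hits <- hits + 1L
  }
  expect_equal(hits, 50L)
})

test_that("manifests state the as-built conformational ground truth", {
  bh <- build_hairpin(hairpin_spec(
    stem_seq = "GG", loop_seq = "UUCAAAG",
    pucker = data.frame(position = 4, P = 162, nu_max = 38),
    chi = data.frame(position = 4, chi = 45)))
  cf <- bh$manifest$conformation
  expect_equal(cf$pucker_class[cf$position == 4], "C2'-endo")
  expect_equal(cf$chi_class[cf$position == 4], "syn")
  expect_true(all(cf$pucker_class[cf$position != 4] == "C3'-endo"))
  expect_true(all(cf$chi_class[cf$position != 4] == "anti"))
  expect_equal(bh$manifest$loop_size, 7)
  expect_equal(bh$manifest$clip_length, 9)
  expect_equal(bh$manifest$pairing$pos_b, c(11L, 10L))
})
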