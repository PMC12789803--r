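# SRS selection, atom correspondence across chemistry differences, RMSD
# comparison with the 1.0 A similarity call, and interaction differencing.

clip_first_hairpin <- function(bh) {
  ann <- annotate_model(prepare_model(bh$entry$models[[1]]))
  hp <- Filter(function(s) s$sse_type == "HAIRPIN", ann$sses)[[1]]
  list(motif = clip_motif(bh$entry, hp), ann = ann,
       model = prepare_model(bh$entry$models[[1]]))
}

build_motif <- function(entry_id, mods = NULL, noise = 0, seed = 1,
                        loop = "UUCAAAG", tilt = 0, chi = NULL) {
  bh <- build_hairpin(hairpin_spec(
    stem_seq = "GG", loop_seq = loop, entry_id = entry_id,
    modifications = mods, noise_sigma = noise, seed = seed,
    loop_tilt_deg = tilt, chi = chi))
  clip_first_hairpin(bh)
}

test_that("select_srs picks the member nearest the group mean", {
  members <- lapply(1:5, function(k)
    build_motif(sprintf("E%03d", k), noise = if (k == 2) 0.02 else 0.4,
                seed = 100 + k)$motif)
  srs <- select_srs(members)
  expect_equal(srs$representative_id, members[[2]]$motif_id)
  expect_equal(length(srs$rmsd_to_mean), 5)
  expect_equal(unname(which.min(srs$rmsd_to_mean)), 2)
  # singleton group
  single <- select_srs(members[1])
  expect_equal(single$representative_id, members[[1]]$motif_id)
  expect_equal(unname(single$rmsd_to_mean), 0)
  # two identical members tie-break to the first
  twin <- select_srs(list(members[[1]], members[[1]]))
  expect_equal(twin$representative_id, members[[1]]$motif_id)
  expect_lt(max(twin$rmsd_to_mean), 1e-9)
})

test_that("atom correspondence drops exactly the chemistry differences", {
  u <- build_motif("UUUU")$motif
  u2 <- build_motif("VVVV", noise = 0.05, seed = 3)$motif
  corr <- atom_correspondence(u, u2)
  expect_equal(nrow(corr$dropped_modified), 0)
  expect_equal(nrow(corr$dropped_unmodified), 0)
  expect_equal(nrow(corr$pairs), nrow(u$residues))

  t5 <- build_motif("MMMM", mods = data.frame(position = 3,
                                              comp_id = "5MU"))$motif
  corr5 <- atom_correspondence(t5, u)
  expect_equal(corr5$dropped_modified$atom, "C5M")
  expect_equal(corr5$dropped_modified$position, 2)   # motif position
  expect_equal(nrow(corr5$dropped_unmodified), 0)
  # conservation: paired + dropped = totals per side
  expect_equal(nrow(corr5$pairs) + nrow(corr5$dropped_modified),
               nrow(t5$residues))

  psu <- build_motif("PPPP", mods = data.frame(position = 3,
                                               comp_id = "PSU"))$motif
  corrp <- atom_correspondence(psu, u)
  expect_equal(nrow(corrp$dropped_modified), 0)   # same heavy-atom names
  expect_equal(nrow(corrp$dropped_unmodified), 0)

  omu <- build_motif("OOOO", mods = data.frame(position = 3,
                                               comp_id = "OMU"))$motif
  corro <- atom_correspondence(omu, u)
  expect_equal(corro$dropped_modified$atom, "CM2")

  # oracle: the dropped set is the component-dictionary name difference
  expect_equal(sort(corr5$dropped_modified$atom),
               sort(setdiff(component_atoms("5MU"), component_atoms("U"))))
})

test_that("compare_pair is rigid-invariant, symmetric, and inclusive at the
          threshold", {
  a <- build_motif("AAAA")$motif
  b <- a
  set.seed(111)
  tr <- random_rigid_transform()
  xyz <- apply_rigid(as.matrix(b$residues[, c("x", "y", "z")]), tr)
  b$residues$x <- xyz[, 1]; b$residues$y <- xyz[, 2]; b$residues$z <- xyz[, 3]
  cmp <- compare_pair(a, b)
  expect_lt(cmp$rmsd, 1e-9)
  expect_true(cmp$similar)

  # uniform inflation about the centroid gives a controlled RMSD near 1 A
  infl <- a
  xyz <- as.matrix(a$residues[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  rms_radius <- sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
  s <- 1 + 1.0 / rms_radius
  xyz2 <- sweep(sweep(xyz, 2, ctr) * s, 2, ctr, "+")
  infl$residues$x <- xyz2[, 1]; infl$residues$y <- xyz2[, 2]
  infl$residues$z <- xyz2[, 3]
  cmp2 <- compare_pair(a, infl)
  expect_equal(cmp2$rmsd, 1.0, tolerance = 1e-6)
  # the similarity call is closed at the threshold: rmsd == threshold is
  # similar, any smaller threshold is not
  cmp_at <- compare_pair(a, infl, threshold = cmp2$rmsd)
  expect_true(cmp_at$similar)
  cmp_below <- compare_pair(a, infl, threshold = cmp2$rmsd * (1 - 1e-9))
  expect_false(cmp_below$similar)

  # symmetry of the RMSD under argument exchange
  noisy <- build_motif("BBBB", noise = 0.3, seed = 5)$motif
  expect_equal(compare_pair(a, noisy)$rmsd, compare_pair(noisy, a)$rmsd,
               tolerance = 1e-9)

  # a planted large backbone displacement is structurally distinct
  far <- build_motif("CCCC", tilt = 40,
                     chi = data.frame(position = 4:5, chi = 30))$motif
  cmp3 <- compare_pair(far, a)
  expect_gt(cmp3$rmsd, 1.0)
  expect_false(cmp3$similar)
})

test_that("interaction differencing reports exactly the planted changes", {
  a <- build_motif("AAAA")
  ia <- motif_interactions(a$ann, a$model, a$motif)
  dd0 <- diff_interactions(ia, ia)
  expect_true(all(dd0$status == "shared"))
  # plant one extra hydrogen bond on the modified side
  extra <- data.frame(position = 3L, kind = "HBOND",
                      partner = "LYS(protein)", stringsAsFactors = FALSE)
  dd1 <- diff_interactions(rbind(ia, extra), ia)
  expect_equal(sum(dd1$status == "gained"), 1)
  expect_equal(dd1$partner[dd1$status == "gained"], "LYS(protein)")
  expect_equal(sum(dd1$status == "lost"), 0)
  # a swapped stack partner appears as one lost and one gained
  ib <- ia
  st <- which(ib$kind == "STACK")[1]
  expect_false(is.na(st))   # stem neighbours of the fixture do stack
  old <- ib$partner[st]
  ib$partner[st] <- "A(tertiary)"
  dd2 <- diff_interactions(ib, ia)
  expect_equal(sum(dd2$status == "gained"), 1)
  expect_equal(sum(dd2$status == "lost"), 1)
  expect_setequal(dd2$partner[dd2$status != "shared"],
                  c("A(tertiary)", old))
  # gained and lost never overlap
  key <- paste(dd2$position, dd2$kind, dd2$partner)
  expect_equal(anyDuplicated(key), 0)
})
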