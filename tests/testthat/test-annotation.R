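# Hydrogen bonds, stacking, base pairs and secondary-structure elements on
# constructed fixtures and generator output.

test_that("hydrogen bonds obey the 4.0 A cutoff with a closed boundary", {
  expect_equal(nrow(detect_hbonds(two_atom_model(2.9))), 1)
  expect_equal(nrow(detect_hbonds(two_atom_model(4.0))), 1)   # inclusive
  expect_equal(nrow(detect_hbonds(two_atom_model(4.001))), 0)
  expect_equal(nrow(detect_hbonds(two_atom_model(4.1))), 0)
  hb <- detect_hbonds(two_atom_model(3.5))
  expect_equal(hb$donor_atom, "N3")
  expect_equal(hb$acceptor_atom, "N1")
  expect_equal(hb$distance, 3.5, tolerance = 1e-12)
  # intra-residue pairs are never reported
  res <- test_u_residue()
  hb2 <- detect_hbonds(res)
  expect_equal(nrow(hb2), 0)
})

test_that("the idealized WCF G:C fixture yields exactly the three canonical
          bonds", {
  m <- ideal_pair_model("G", "C", stretch = 0.9)
  hb <- detect_hbonds(m)
  expect_equal(nrow(hb), 3)
  got <- sort(paste(hb$donor_comp, hb$donor_atom, "->",
                    hb$acceptor_comp, hb$acceptor_atom))
  expect_equal(got, sort(c("G N1 -> C N3", "G N2 -> C O2", "C N4 -> G O6")))
  # oracle: the same three contacts measured directly on the fixture
  for (r in seq_len(nrow(hb))) {
    a <- m[m$comp == hb$donor_comp[r] & m$atom == hb$donor_atom[r], ]
    b <- m[m$comp == hb$acceptor_comp[r] & m$atom == hb$acceptor_atom[r], ]
    d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
    expect_equal(hb$distance[r], d, tolerance = 1e-12)
    expect_lte(d, 4.0)
  }
  bp <- detect_base_pairs(hb, m)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$pair_type, "WCF")
  expect_gte(bp$n_hbonds, 3)
})

test_that("wobble pairs classify as WOBBLE and single bonds never pair", {
  m <- ideal_pair_model("G", "U")
  hb <- detect_hbonds(m)
  bp <- detect_base_pairs(hb, m)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$pair_type, "WOBBLE")
  # pair symmetry in residue order
  m2 <- ideal_pair_model("U", "G")
  bp2 <- detect_base_pairs(detect_hbonds(m2), m2)
  expect_equal(bp2$pair_type, "WOBBLE")
  # a single h-bond contact is not a pair
  one <- two_atom_model(3.0)
  expect_equal(nrow(detect_base_pairs(detect_hbonds(one), one)), 0)
})

flat_base <- function(comp, seqno, shift = c(0, 0, 0)) {
  xyz <- urimod:::base_template(comp)
  xyz <- sweep(xyz, 2, shift, "+")
  data.frame(chain = "A", seq = seqno, icode = "", comp = comp,
             atom = rownames(xyz), element = substr(rownames(xyz), 1, 1),
             alt = "", occ = 1, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

test_that("stacking needs parallel planes, close rings, near centroids", {
  stacked <- rbind(flat_base("U", 1), flat_base("U", 2, c(0.8, 0, 3.4)))
  st <- detect_stacks(stacked)
  expect_equal(nrow(st), 1)
  expect_lt(st$normal_angle, 1)
  expect_lte(st$min_ring_dist, 4.0)
  # perpendicular bases at the same distance do not stack
  perp_xyz <- urimod:::base_template("U")
  perp <- flat_base("U", 2)
  rot <- cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))
  xyz <- as.matrix(perp[, c("x", "y", "z")]) %*% rot
  perp$x <- xyz[, 1]; perp$y <- xyz[, 2]; perp$z <- xyz[, 3] + 3.4
  expect_equal(nrow(detect_stacks(rbind(flat_base("U", 1), perp))), 0)
  # coplanar side-by-side bases (paired, not stacked): min ring distance
  # beyond the cutoff
  side <- rbind(flat_base("U", 1), flat_base("U", 2, c(9.0, 0, 0)))
  expect_equal(nrow(detect_stacks(side)), 0)
  # stacked pairs in a built stem are found, paired bases are not stacks
  bh <- build_hairpin(hairpin_spec(stem_seq = "GG", loop_seq = "GAAA"))
  st2 <- detect_stacks(bh$entry$models[[1]])
  expect_true(all(abs(st2$seq_a - st2$seq_b) == 1))
})

test_that("assign_sses recovers hairpins, duplexes and junctions", {
  # generator hairpin: one helix, one hairpin of the requested loop size
  bh <- build_hairpin(hairpin_spec(stem_seq = "GG", loop_seq = "UUCAAAG"))
  ann <- annotate_model(bh$entry$models[[1]])
  types <- vapply(ann$sses, `[[`, character(1), "sse_type")
  expect_setequal(types, c("HELIX", "HAIRPIN"))
  hp <- ann$sses[[which(types == "HAIRPIN")]]
  expect_equal(hp$loop_size, 7)
  expect_equal(hp$closing_pair, c(2, 10))
  # a fully paired duplex has helices but no hairpin
  duplex <- local({
    pg1 <- build_hairpin(hairpin_spec(stem_seq = "GGG", loop_seq = "GAAA"))
    m <- pg1$entry$models[[1]]
    keep <- m$seq %in% c(1:3, 8:10)
    m2 <- m[keep, ]
    m2$chain <- ifelse(m2$seq <= 3, "A", "B")
    m2
  })
  ann2 <- annotate_model(duplex)
  types2 <- vapply(ann2$sses, `[[`, character(1), "sse_type")
  expect_true("HELIX" %in% types2)
  expect_false("HAIRPIN" %in% types2)
})

fake_pairs <- function(pairs_mat) {
  data.frame(gidx_a = pairs_mat[, 1], gidx_b = pairs_mat[, 2],
             n_hbonds = 3L, pair_type = "WCF", stringsAsFactors = FALSE)
}

fake_model <- function(n, chain = rep("A", n)) {
  data.frame(chain = chain, seq = seq_len(n), icode = "", comp = "G",
             atom = "C1'", element = "C", alt = "", occ = 1,
             x = seq_len(n), y = 0, z = 0, stringsAsFactors = FALSE)
}

test_that("a cloverleaf pair topology gives one junction and its hairpins", {
  pr <- fake_pairs(rbind(c(1, 40), c(2, 39), c(3, 38),
                         c(5, 15), c(6, 14), c(7, 13),
                         c(17, 27), c(18, 26), c(19, 25),
                         c(29, 37), c(30, 36), c(31, 35)))
  ss <- assign_sses(pr, fake_model(40))
  types <- vapply(ss, `[[`, character(1), "sse_type")
  expect_equal(sum(types == "HAIRPIN"), 3)
  expect_equal(sum(types == "JUNCTION"), 1)
  loops <- sort(vapply(ss[types == "HAIRPIN"], `[[`, integer(1),
                       "loop_size"))
  expect_equal(loops, c(3L, 5L, 5L))
  jn <- ss[[which(types == "JUNCTION")]]
  expect_setequal(jn$gidx, c(4L, 16L, 28L))
})

test_that("crossing helices are pruned to a maximal nested subset", {
  pr <- fake_pairs(rbind(c(1, 10), c(2, 9), c(3, 8),
                         c(5, 15), c(6, 14)))
  ss <- assign_sses(pr, fake_model(16))
  types <- vapply(ss, `[[`, character(1), "sse_type")
  helices <- ss[types == "HELIX"]
  expect_equal(length(helices), 1)       # the longer helix wins
  expect_equal(min(helices[[1]]$gidx), 1)
  hp <- ss[types == "HAIRPIN"]
  expect_equal(length(hp), 1)
  expect_equal(hp[[1]]$loop_size, 4)     # residues 4..7 enclosed by (3,8)
})

test_that("loop sizes 4-10 are recovered exactly from noiseless builds and
          clip length is loop+2", {
  loops <- c("GAAA", "GCUAA", "GCAAUA", "UUCAAAG", "AGUGGAAC",
             "AGUGGAACA", "AGUGGAACAA")
  for (ls in loops) {
    bh <- build_hairpin(hairpin_spec(stem_seq = "GG", loop_seq = ls))
    ann <- annotate_model(bh$entry$models[[1]])
    types <- vapply(ann$sses, `[[`, character(1), "sse_type")
    hp <- ann$sses[types == "HAIRPIN"]
    expect_equal(length(hp), 1)
    expect_equal(hp[[1]]$loop_size, nchar(ls))
    motif <- clip_motif(bh$entry, hp[[1]])
    expect_equal(nchar(motif$sequence), nchar(ls) + 2)
    expect_equal(motif$loop_size, nchar(ls))
  }
})

test_that("external annotation JSON reads into comparable tables", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"pairs":[{"nt1":"A.G1","nt2":"A.C10","name":"WC"}],
              "hbonds":[{"atom1_id":"N1@A.G1","atom2_id":"N3@A.C10",
                         "distance":2.9}]}', path)
  ext <- read_external_annotation(path)
  expect_equal(nrow(ext$pairs), 1)
  expect_equal(ext$pairs$name, "WC")
  expect_equal(ext$hbonds$distance, 2.9)
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", empty)
  ext2 <- read_external_annotation(empty)
  expect_equal(nrow(ext2$pairs), 0)
})
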