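# Dataset filters, NMR representative selection, canonicalization, motif
# clipping, counterpart matching and RNA-type classification.

fake_entry <- function(id, method, resolution) {
  res <- test_u_residue()
  structure_entry(id, method, resolution, list(res))
}

test_that("the resolution filter keeps X-ray/EM at <= 3.0 A, boundary
          inclusive, and never drops NMR", {
  entries <- list(fake_entry("AAAA", "XRAY", 2.5),
                  fake_entry("BBBB", "EM", 3.2),
                  fake_entry("CCCC", "EM", 3.0),
                  fake_entry("DDDD", "NMR", NA),
                  fake_entry("EEEE", "XRAY", NA))
  fl <- filter_entries(entries)
  kept <- vapply(fl$kept, `[[`, character(1), "entry_id")
  expect_setequal(kept, c("AAAA", "CCCC", "DDDD"))
  lg <- fl$log
  expect_equal(lg$reason[lg$entry_id %in% c("BBBB", "EEEE")],
               c("RESOLUTION", "RESOLUTION"))
  # property: kept iff NMR or resolution <= cutoff
  set.seed(81)
  for (k in 1:50) {
    method <- sample(c("XRAY", "EM", "NMR"), 1)
    resol <- if (method == "NMR") NA_real_ else round(stats::runif(1, 1, 5), 2)
    f <- filter_entries(list(fake_entry("ZZZZ", method, resol)),
                        max_resolution = 3.0)
    expect_equal(length(f$kept) == 1,
                 method == "NMR" || (!is.na(resol) && resol <= 3.0))
  }
})

test_that("canonicalize_sequence reverts display characters and is an
          idempotent, length-preserving map", {
  expect_equal(canonicalize_sequence("GGuAAGC"), "GGUAAGC")
  expect_equal(canonicalize_sequence("UGPPCAAAG"), "UGUUCAAAG")
  expect_equal(canonicalize_sequence("ACGU"), "ACGU")
  expect_equal(canonicalize_sequence("GtPCAAGUC"), "GUUCAAGUC")
  expect_error(canonicalize_sequence("GX"), "UNKNOWN_COMPONENT")
  set.seed(91)
  alphabet <- c("A", "C", "G", "U", "P", "t", "u")
  for (k in 1:25) {
    s <- paste(sample(alphabet, sample(4:12, 1), replace = TRUE),
               collapse = "")
    cs <- canonicalize_sequence(s)
    expect_equal(nchar(cs), nchar(s))
    expect_equal(canonicalize_sequence(cs), cs)
    expect_true(all(strsplit(cs, "")[[1]] %in% c("A", "C", "G", "U")))
  }
})

test_that("NMR representative selection recovers the planted low-noise
          model and matches a brute-force oracle", {
  bh <- build_hairpin(hairpin_spec(stem_seq = "GG", loop_seq = "GCUAA"))
  ens <- make_ensemble(bh$entry, n_models = 10, noise_sigma = 0.5,
                       seed = 99, planted_representative = 4)
  rep <- select_nmr_representative(ens)
  expect_equal(attr(rep, "representative_index"), 4)
  expect_equal(length(rep$models), 1)
  # brute-force oracle: quaternion RMSD of every model to an iterated mean
  mats <- lapply(ens$models, function(m) as.matrix(m[, c("x", "y", "z")]))
  mean_xyz <- mats[[1]]
  for (it in 1:50) {
    fitted <- lapply(mats, function(a) {
      sp <- kabsch_superpose(a, mean_xyz)
      apply_superposition(sp, a)
    })
    mean_xyz <- Reduce(`+`, fitted) / length(fitted)
  }
  oracle <- vapply(mats, quaternion_rmsd, numeric(1),
                   reference = mean_xyz)
  expect_equal(which.min(oracle), 4)
  expect_equal(unname(attr(rep, "rmsd_to_mean")), unname(oracle),
               tolerance = 1e-4)
  # single model passes through; identical models tie-break to model 1
  one <- bh$entry
  expect_equal(attr(select_nmr_representative(one),
                    "representative_index"), 1)
  twin <- make_ensemble(bh$entry, 2, 0, seed = 1)
  expect_equal(attr(select_nmr_representative(twin),
                    "representative_index"), 1)
})

test_that("clip_motif builds provenance ids that parse back exactly", {
  bh <- build_hairpin(hairpin_spec(stem_seq = "GG", loop_seq = "UUCAAAG",
                                   entry_id = "7UCK", chain = "9",
                                   start_seq_num = 819))
  ann <- annotate_model(bh$entry$models[[1]])
  hp <- Filter(function(s) s$sse_type == "HAIRPIN", ann$sses)[[1]]
  motif <- clip_motif(bh$entry, hp)
  expect_equal(motif$entry_id, "7UCK")
  info <- parse_motif_id(motif$motif_id)
  expect_equal(info$entry_id, "7UCK")
  expect_equal(info$chain_id, "9")
  expect_equal(info$start_seq_num, motif$start_seq_num)
  expect_equal(info$sequence, motif$sequence)
  comps <- urimod:::residue_keys(motif$residues)$comp
  want_atoms <- sum(vapply(comps, function(cc) length(component_atoms(cc)),
                           integer(1)))
  expect_equal(nrow(motif$residues), want_atoms)
  # a screen failure inside the clip span raises CLIP_FAIL
  broken <- bh$entry
  m <- broken$models[[1]]
  broken$models[[1]] <- m[!(m$seq == 821 & m$atom == "O2'"), ]
  expect_error(clip_motif(broken, hp), class = "CLIP_FAIL")
})

test_that("match_unmodified demands exact canonical sequences without
          modifications", {
  mk_motif <- function(entry_id, stem, loop, mods = NULL) {
    bh <- build_hairpin(hairpin_spec(stem_seq = stem, loop_seq = loop,
                                     entry_id = entry_id,
                                     modifications = mods))
    ann <- annotate_model(prepare_model(bh$entry$models[[1]]))
    hp <- Filter(function(s) s$sse_type == "HAIRPIN", ann$sses)[[1]]
    clip_motif(bh$entry, hp)
  }
  mod <- mk_motif("MOD1", "GG", "UUCAAAG",
                  data.frame(position = 3, comp_id = "PSU"))
  lib_match <- mk_motif("LIB1", "GG", "UUCAAAG")
  lib_mismatch <- mk_motif("LIB2", "GG", "UUCAAAC")
  lib_modified <- mk_motif("LIB3", "GG", "UUCAAAG",
                           data.frame(position = 4, comp_id = "5MU"))
  hits <- match_unmodified(mod, list(lib_match, lib_mismatch, lib_modified))
  expect_equal(length(hits), 1)
  expect_equal(hits[[1]]$entry_id, "LIB1")
  # no counterpart is an empty result, not an error
  expect_equal(length(match_unmodified(mod, list(lib_mismatch))), 0)
  # returned motifs never contain dictionary components
  expect_false(any(hits[[1]]$residues$comp %in% mod_dictionary()$comp_id))
})

test_that("RNA types classify from molecule descriptions by keyword", {
  mk <- function(desc) {
    e <- fake_entry("QQQQ", "XRAY", 2.0)
    e$molecule_descriptions <- c(A = desc)
    classify_rna_type(e, "A")
  }
  expect_equal(mk("23S ribosomal RNA"), "rRNA")
  expect_equal(mk("transfer RNA-Asp"), "tRNA")
  expect_equal(mk("messenger RNA fragment"), "mRNA")
  expect_equal(mk("U6 snRNA"), "snRNA")
  expect_equal(mk("RNA (5'-R(*GP*CP*A)-3') synthetic construct"), "synthetic")
  expect_equal(mk("ribozyme domain"), "other")
  e <- fake_entry("QQQQ", "XRAY", 2.0)
  expect_equal(classify_rna_type(e, "A"), "other")   # absent description
})

test_that("the modification dictionary round-trips through its editable
          TSV form", {
  shipped <- system.file("extdata", "mod_dictionary.tsv", package = "urimod")
  expect_true(nzchar(shipped))
  d <- mod_dictionary(shipped)
  expect_identical(d, mod_dictionary())
  expect_true(all(d$canonical == "U"))
  expect_equal(d$gly_atom1[d$comp_id == "PSU"], "C5")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mod_dictionary(d, path)
  expect_identical(mod_dictionary(path), d)
})
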