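# Survey tabulation and the end-to-end pipeline on the labeled toy corpus.

test_that("tabulate_survey computes exact counts and collapses only
          sub-percent SSE categories", {
  mk_residues <- function(sse) {
    data.frame(entry_id = sprintf("E%03d", seq_along(sse)),
               comp_id = "PSU", method = "XRAY", sse_class = sse,
               pucker_class = "C3'-endo", chi_class = "anti",
               rna_type = "rRNA", stringsAsFactors = FALSE)
  }
  r <- mk_residues(c(rep("HAIRPIN", 6), rep("HELIX", 4)))
  rep1 <- tabulate_survey(r)
  sse <- rep1$distributions$PSU$sse
  expect_equal(sse$n[sse$category == "HAIRPIN"], 6L)
  expect_equal(sse$percent[sse$category == "HAIRPIN"], 60)
  expect_equal(sum(sse$n), 10L)
  expect_equal(sum(sse$percent), 100, tolerance = 0.1)

  # 5 of 1000 = 0.5% < 1% -> collapsed into MISC
  r2 <- mk_residues(c(rep("HAIRPIN", 995), rep("JUNCTION", 5)))
  sse2 <- tabulate_survey(r2)$distributions$PSU$sse
  expect_false("JUNCTION" %in% sse2$category)
  expect_equal(sse2$n[sse2$category == "MISC"], 5L)

  # exactly 1.0% is NOT collapsed (strict <)
  r3 <- mk_residues(c(rep("HAIRPIN", 990), rep("JUNCTION", 10)))
  sse3 <- tabulate_survey(r3)$distributions$PSU$sse
  expect_true("JUNCTION" %in% sse3$category)

  # one residue = one 100% category
  r4 <- mk_residues("HAIRPIN")
  sse4 <- tabulate_survey(r4)$distributions$PSU$sse
  expect_equal(sse4$percent, 100)

  # empty dataset gives an empty report, not an error
  empty <- tabulate_survey(NULL)
  expect_null(empty$structures)
})

test_that("the pipeline survey agrees with the generator manifest", {
  toy <- get_toy_survey()
  mf <- toy$manifest; res <- toy$result
  # conservation: every input structure is kept or excluded with a reason
  expect_equal(unname(res$counts["structures_in"]),
               unname(res$counts["kept"] + res$counts["excluded"]))
  excl <- res$curation_log[res$curation_log$outcome == "excluded", ]
  expect_true(all(nzchar(excl$reason)))
  expect_true(all(excl$reason %in% c("RESOLUTION", "MISSING_ATOMS",
                                     "PROCESSING", "INCOMPLETE_SSE",
                                     "CLIP_FAIL")))
  # planted exclusions come back with the planted reason
  planted <- mf$entries[mf$entries$expected != "kept" &
                        mf$entries$role == "modified", ]
  for (i in seq_len(nrow(planted))) {
    got <- excl$reason[excl$entry_id == planted$entry_id[i]]
    expect_equal(got, planted$expected[i])
  }
  # per-modification structure and residue totals equal the manifest
  want <- mf$residues
  st <- res$report$structures
  for (cc in unique(want$comp_id)) {
    w <- want[want$comp_id == cc, ]
    s <- st[st$comp_id == cc, ]
    expect_equal(s$total_residues, nrow(w))
    expect_equal(s$xray, length(unique(w$entry_id[w$method == "XRAY"])))
    expect_equal(s$em, length(unique(w$entry_id[w$method == "EM"])))
    expect_equal(s$nmr, length(unique(w$entry_id[w$method == "NMR"])))
  }
  # report percentages sum to 100 within every panel
  for (dist in res$report$distributions) {
    for (panel in dist) {
      expect_equal(sum(panel$percent), 100, tolerance = 0.1)
    }
  }
})

test_that("per-residue SSE, pucker, chi and RNA-type calls match the
          manifest exactly", {
  toy <- get_toy_survey()
  got <- toy$result$residues
  want <- toy$manifest$residues
  m <- merge(got, want, by = c("entry_id", "comp_id", "seq"),
             suffixes = c("", ".want"))
  expect_equal(nrow(m), nrow(want))
  expect_equal(m$sse_class, m$sse_class.want)
  expect_equal(m$pucker_class, m$pucker_class.want)
  expect_equal(m$chi_class, m$chi_class.want)
  expect_equal(m$rna_type, m$rna_type.want)
})

test_that("comparisons find one counterpart pair per modification with the
          planted similarity calls", {
  toy <- get_toy_survey()
  cmp <- toy$result$comparisons
  want <- toy$manifest$comparisons
  expect_equal(nrow(cmp), nrow(want))
  for (i in seq_len(nrow(want))) {
    row <- cmp[cmp$comp_ids == want$comp_id[i], ]
    expect_equal(nrow(row), 1)
    expect_equal(canonicalize_sequence(row$sequence), want$canonical[i])
    expect_equal(row$similar, want$expect_similar[i])
  }
  summ <- toy$result$report$comparison_summary
  expect_equal(sum(summ$n_pairs), nrow(want))
  expect_equal(summ$n_similar[summ$comp_id == "4SU"], 0L)
})

test_that("NMR entries enter the survey through their planted
          representative", {
  toy <- get_toy_survey()
  nmr <- toy$manifest$entries[toy$manifest$entries$method == "NMR" &
                              toy$manifest$entries$expected == "kept", ]
  expect_gt(nrow(nmr), 0)
  expect_true(all(nmr$representative == 3))
})

test_that("rerunning the pipeline on the same inputs is byte-identical", {
  toy <- get_toy_survey()
  res2 <- run_pipeline(toy$manifest$modified_dir,
                       toy$manifest$library_dir)
  expect_identical(res2$report, toy$result$report)
  expect_identical(res2$comparisons, toy$result$comparisons)
  expect_identical(res2$curation_log, toy$result$curation_log)
  # artifact writing is exercised and produces the expected files
  out <- withr::local_tempdir()
  run_pipeline(toy$manifest$modified_dir, toy$manifest$library_dir,
               out_dir = out)
  expect_true(all(file.exists(file.path(out, c(
    "conformation.tsv", "comparisons.tsv", "curation_log.tsv",
    "motif_index.tsv", "structure_counts.tsv")))))
})

test_that("an empty input directory yields an empty report and log", {
  dir <- withr::local_tempdir()
  res <- run_pipeline(dir)
  expect_null(res$report$structures)
  expect_equal(unname(res$counts["structures_in"]), 0L)
})
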