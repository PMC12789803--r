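# End-to-end survey pipeline and summary tables: orchestrates filtering,
# NMR representative selection, annotation, motif clipping, counterpart
# matching, SRS selection, comparison and tabulation.

#' Pipeline configuration
#'
#' All thresholds of the survey with their standard defaults: 3.0 A
#' resolution cutoff, 4.0 A contact cutoff for hydrogen bonds and stacking,
#' 1.0 A all-atom RMSD similarity threshold, the stacking geometry limits and
#' the pucker amplitude floor.
#'
#' @param max_resolution Resolution cutoff (A) for X-ray/EM entries.
#' @param contact_cutoff Hydrogen-bond / stacking distance cutoff (A).
#' @param similarity_threshold All-atom RMSD similarity threshold (A).
#' @param stack_normal_max,stack_centroid_max Stacking geometry limits.
#' @param coplanar_max,vertical_max Base-pair coplanarity limits.
#' @param amplitude_floor Minimum classifiable pucker amplitude (degrees).
#' @param misc_share SSE categories whose share is strictly below this
#'   fraction are collapsed into MISC in the report.
#' @return A named list of settings.
#' @export
pipeline_config <- function(max_resolution = 3.0, contact_cutoff = 4.0,
                            similarity_threshold = 1.0,
                            stack_normal_max = 30, stack_centroid_max = 5.5,
                            coplanar_max = 45, vertical_max = 2.5,
                            amplitude_floor = 5, misc_share = 0.01) {
  list(max_resolution = max_resolution, contact_cutoff = contact_cutoff,
       similarity_threshold = similarity_threshold,
       stack_normal_max = stack_normal_max,
       stack_centroid_max = stack_centroid_max,
       coplanar_max = coplanar_max, vertical_max = vertical_max,
       amplitude_floor = amplitude_floor, misc_share = misc_share)
}

annotate_entry_model <- function(model, config, dict) {
  hb <- detect_hbonds(model, cutoff = config$contact_cutoff, dict = dict)
  st <- detect_stacks(model, cutoff = config$contact_cutoff,
                      normal_max = config$stack_normal_max,
                      centroid_max = config$stack_centroid_max, dict = dict)
  bp <- detect_base_pairs(hb, model, coplanar_max = config$coplanar_max,
                          vertical_max = config$vertical_max, dict = dict)
  ss <- assign_sses(bp, model)
  list(hbonds = hb, stacks = st, pairs = bp, sses = ss,
       sse_class = residue_sse_class(ss, model))
}

# process one parsed entry: representative model, annotation, conformation of
# modified residues, clipped hairpins
process_entry <- function(entry, config, dict, clip_all = FALSE) {
  if (entry$method == "NMR" && length(entry$models) > 1) {
    entry <- select_nmr_representative(entry, dict)
  }
  model <- prepare_model(entry$models[[1]])
  ann <- annotate_entry_model(model, config, dict)
  mod_sel <- residue_keys(model)$comp %in% dict$comp_id
  conf <- NULL
  if (any(mod_sel)) {
    conf <- conformation_table(model, dict,
                               amplitude_floor = config$amplitude_floor,
                               only_comps = dict$comp_id)
    cls <- ann$sse_class
    key <- paste(cls$chain, cls$seq, cls$icode)
    conf$sse_class <- cls$sse_class[match(paste(conf$chain, conf$seq,
                                                conf$icode), key)]
    conf$entry_id <- entry$entry_id
    conf$method <- entry$method
    conf$rna_type <- vapply(conf$chain, function(ch)
      classify_rna_type(entry, ch), character(1))
  }
  motifs <- list(); clip_failures <- character(0)
  keys <- model_residue_index(model)
  for (s in ann$sses) {
    if (s$sse_type != "HAIRPIN") next
    span <- s$closing_pair[1]:s$closing_pair[2]
    has_mod <- any(keys$comp[span] %in% dict$comp_id)
    if (!clip_all && !has_mod) next
    m <- tryCatch(clip_motif(entry, s, dict = dict),
                  error = function(e) e)
    if (inherits(m, "error")) {
      reason <- if (inherits(m, "CLIP_FAIL")) "CLIP_FAIL"
                else if (inherits(m, "INCOMPLETE_SSE")) "INCOMPLETE_SSE"
                else "PROCESSING"
      clip_failures <- c(clip_failures, reason)
    } else {
      motifs[[length(motifs) + 1L]] <- m
    }
  }
  list(entry = entry, model = model, annotation = ann, conformation = conf,
       motifs = motifs, clip_failures = clip_failures)
}

#' Run the full uridine-modification survey
#'
#' Executes the complete workflow on a directory of modified structures and
#' a local unmodified library: parse, resolution filter, NMR representative
#' selection, annotation, conformation calls, hairpin clipping, canonical
#' counterpart matching, SRS selection, modified-vs-unmodified comparison
#' and tabulation.  Deterministic given fixed inputs; every excluded entry
#' carries a reason code (RESOLUTION, MISSING_ATOMS, PROCESSING,
#' INCOMPLETE_SSE, CLIP_FAIL).
#'
#' @param modified_dir Directory of structure files containing modified
#'   uridines (mmCIF or PDB).
#' @param library_dir Directory of candidate unmodified structures, or NULL.
#' @param config A [pipeline_config()].
#' @param dict Modification dictionary.
#' @param out_dir Optional directory for delimited-text artifacts
#'   (conformation table, motif index, comparison table, curation log,
#'   summary).
#' @return A `survey_result` list: `report` (the [tabulate_survey()]
#'   output), `residues`, `motifs`, `srs`, `comparisons`,
#'   `interaction_deltas`, `curation_log`, `counts`.
#' @export
run_pipeline <- function(modified_dir, library_dir = NULL,
                         config = pipeline_config(),
                         dict = mod_dictionary(), out_dir = NULL) {
  read_dir <- function(dir) {
    files <- sort(list.files(dir, pattern = "\\.(cif|mmcif|pdb|ent)$",
                             full.names = TRUE))
    out <- list(); log <- list()
    for (f in files) {
      e <- tryCatch(parse_structure(f), error = function(err) err)
      if (inherits(e, "error")) {
        log[[length(log) + 1L]] <- data.frame(
          entry_id = basename(f), filter = "parse", outcome = "excluded",
          reason = "PROCESSING", stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <- e
      }
    }
    list(entries = out, log = if (length(log)) do.call(rbind, log) else NULL)
  }
  rd <- read_dir(modified_dir)
  fl <- filter_entries(rd$entries, max_resolution = config$max_resolution)
  curation_log <- rbind(rd$log, fl$log)
  processed <- list(); conf_rows <- list(); motifs <- list()
  for (e in fl$kept) {
    pr <- tryCatch(process_entry(e, config, dict),
                   error = function(err) err)
    if (inherits(pr, "error")) {
      curation_log <- rbind(curation_log, data.frame(
        entry_id = e$entry_id, filter = "annotation", outcome = "excluded",
        reason = "PROCESSING", stringsAsFactors = FALSE))
      next
    }
    n_mod_res <- if (is.null(pr$conformation)) 0 else nrow(pr$conformation)
    has_mod_motif <- length(pr$motifs) > 0
    if (length(pr$clip_failures) && !has_mod_motif && n_mod_res > 0) {
      # the entry's modified hairpins could not be clipped: excluded, as in
      # a curated survey
      curation_log <- rbind(curation_log, data.frame(
        entry_id = e$entry_id, filter = "clip", outcome = "excluded",
        reason = pr$clip_failures[1], stringsAsFactors = FALSE))
      next
    }
    processed[[e$entry_id]] <- pr
    if (!is.null(pr$conformation)) {
      conf_rows[[length(conf_rows) + 1L]] <- pr$conformation
    }
    motifs <- c(motifs, pr$motifs)
  }
  residues <- if (length(conf_rows)) do.call(rbind, conf_rows) else NULL

  # unmodified library
  lib_motifs <- list(); lib_processed <- list()
  if (!is.null(library_dir)) {
    lrd <- read_dir(library_dir)
    lfl <- filter_entries(lrd$entries,
                          max_resolution = config$max_resolution)
    for (e in lfl$kept) {
      pr <- tryCatch(process_entry(e, config, dict, clip_all = TRUE),
                     error = function(err) NULL)
      if (is.null(pr)) next
      lib_processed[[e$entry_id]] <- pr
      lib_motifs <- c(lib_motifs, pr$motifs)
    }
  }

  # SRS per (sse_type, sequence) group
  group_of <- function(ms) vapply(ms, function(m)
    paste(m$sse_type, m$sequence), character(1))
  srs_records <- list()
  if (length(motifs)) {
    for (g in unique(group_of(motifs))) {
      srs_records[[g]] <- select_srs(motifs[group_of(motifs) == g])
    }
  }
  lib_srs <- list()
  if (length(lib_motifs)) {
    lib_no_mod <- Filter(function(m) !any(m$residues$comp %in% dict$comp_id),
                         lib_motifs)
    for (g in unique(group_of(lib_no_mod))) {
      lib_srs[[g]] <- select_srs(lib_no_mod[group_of(lib_no_mod) == g])
    }
  }

  # comparisons: modified SRS vs the unmodified SRS of the same canonical
  # sequence
  comparisons <- list(); deltas <- list()
  for (g in names(srs_records)) {
    srs <- srs_records[[g]]
    mot <- srs$representative
    target <- paste(mot$sse_type, canonicalize_sequence(mot$sequence, dict))
    if (!target %in% names(lib_srs)) next
    usrs <- lib_srs[[target]]
    cmp <- compare_pair(mot, usrs$representative,
                        threshold = config$similarity_threshold, dict = dict)
    comparisons[[length(comparisons) + 1L]] <- data.frame(
      modified_id = cmp$modified_id, unmodified_id = cmp$unmodified_id,
      sequence = mot$sequence, loop_size = mot$loop_size,
      comp_ids = paste(sort(unique(
        mot$residues$comp[mot$residues$comp %in% dict$comp_id])),
        collapse = ","),
      n_paired_atoms = cmp$n_paired_atoms, rmsd = cmp$rmsd,
      similar = cmp$similar, stringsAsFactors = FALSE)
    pr_m <- processed[[mot$entry_id]]
    pr_u <- lib_processed[[usrs$representative$entry_id]]
    if (!is.null(pr_m) && !is.null(pr_u)) {
      im <- motif_interactions(pr_m$annotation, pr_m$model, mot, dict)
      iu <- motif_interactions(pr_u$annotation, pr_u$model,
                               usrs$representative, dict)
      dd <- diff_interactions(im, iu)
      if (nrow(dd)) {
        dd$modified_id <- cmp$modified_id
        dd$unmodified_id <- cmp$unmodified_id
        deltas[[length(deltas) + 1L]] <- dd
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
                 else NULL
  deltas <- if (length(deltas)) do.call(rbind, deltas) else NULL

  report <- tabulate_survey(residues, comparisons, processed,
                            misc_share = config$misc_share, dict = dict)
  n_in <- length(rd$entries) + if (is.null(rd$log)) 0 else nrow(rd$log)
  excluded <- curation_log[curation_log$outcome == "excluded", , drop = FALSE]
  result <- structure(list(
    report = report, residues = residues, motifs = motifs,
    srs = srs_records, library_srs = lib_srs, comparisons = comparisons,
    interaction_deltas = deltas, curation_log = curation_log,
    counts = c(structures_in = n_in, kept = length(processed),
               excluded = nrow(excluded))), class = "survey_result")
  if (!is.null(out_dir)) write_survey_artifacts(result, out_dir)
  result
}

#' Summary tables of the survey
#'
#' Per-modification frequency tables: structures by experimental method,
#' residue totals, and the SSE, RNA-type, sugar-pucker and glycosidic-class
#' distributions (counts and percentages, normalized per modification over
#' residues).  SSE categories whose share is strictly below `misc_share` of
#' a modification's residues are collapsed into MISC; a category at exactly
#' the threshold is kept.
#'
#' @param residues Per-residue records (entry_id, comp_id, sse_class,
#'   pucker_class, chi_class, rna_type, method).
#' @param comparisons Comparison table (or NULL).
#' @param processed Internal per-entry records (or NULL).
#' @param misc_share MISC collapse threshold (fraction).
#' @param dict Modification dictionary.
#' @return A `survey_report` list with `structures`, `residue_totals`,
#'   `distributions` (nested per modification) and `comparison_summary`.
#' @export
tabulate_survey <- function(residues, comparisons = NULL, processed = NULL,
                            misc_share = 0.01, dict = mod_dictionary()) {
  empty <- structure(list(structures = NULL, residue_totals = NULL,
                          distributions = list(),
                          comparison_summary = NULL),
                     class = "survey_report")
  if (is.null(residues) || nrow(residues) == 0) return(empty)
  dist_table <- function(values, collapse_misc = FALSE) {
    tab <- table(values)
    if (collapse_misc) {
      share <- as.numeric(tab) / sum(tab)
      small <- share < misc_share & names(tab) != "MISC"
      if (any(small)) {
        misc_n <- sum(tab[small])
        tab <- tab[!small]
        tab["MISC"] <- (if ("MISC" %in% names(tab)) tab[["MISC"]] else 0) +
          misc_n
      }
    }
    data.frame(category = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / sum(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  mods <- intersect(dict$comp_id, unique(residues$comp_id))
  distributions <- lapply(stats::setNames(mods, mods), function(cc) {
    r <- residues[residues$comp_id == cc, ]
    list(sse = dist_table(r$sse_class, collapse_misc = TRUE),
         rna_type = dist_table(r$rna_type),
         pucker = dist_table(r$pucker_class),
         chi = dist_table(r$chi_class))
  })
  structures <- do.call(rbind, lapply(mods, function(cc) {
    r <- residues[residues$comp_id == cc, ]
    u <- unique(r[, c("entry_id", "method")])
    data.frame(comp_id = cc,
               xray = sum(u$method == "XRAY"), em = sum(u$method == "EM"),
               nmr = sum(u$method == "NMR"),
               total_structures = nrow(u), total_residues = nrow(r),
               stringsAsFactors = FALSE)
  }))
  comparison_summary <- NULL
  if (!is.null(comparisons) && nrow(comparisons)) {
    key <- lapply(seq_len(nrow(comparisons)), function(i)
      strsplit(comparisons$comp_ids[i], ",")[[1]])
    comparison_summary <- do.call(rbind, lapply(mods, function(cc) {
      sel <- vapply(key, function(k) cc %in% k, logical(1))
      data.frame(comp_id = cc, n_pairs = sum(sel),
                 n_similar = sum(comparisons$similar[sel]),
                 fraction_similar = if (sum(sel)) mean(
                   comparisons$similar[sel]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(structures = structures,
                 residue_totals = stats::setNames(
                   structures$total_residues, structures$comp_id),
                 distributions = distributions,
                 comparison_summary = comparison_summary),
            class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  if (is.null(x$structures)) {
    cat("survey_report: empty dataset\n")
    return(invisible(x))
  }
  cat("survey_report\n")
  print(x$structures, row.names = FALSE)
  if (!is.null(x$comparison_summary)) {
    cat("\ncomparisons:\n")
    print(x$comparison_summary, row.names = FALSE)
  }
  invisible(x)
}

write_survey_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(result$residues, "conformation.tsv")
  wt(result$comparisons, "comparisons.tsv")
  wt(result$interaction_deltas, "interaction_deltas.tsv")
  wt(result$curation_log, "curation_log.tsv")
  if (length(result$motifs)) {
    idx <- do.call(rbind, lapply(result$motifs, function(m) data.frame(
      motif_id = m$motif_id, sequence = m$sequence,
      canonical = canonicalize_sequence(m$sequence),
      sse_type = m$sse_type, loop_size = m$loop_size,
      stringsAsFactors = FALSE)))
    wt(idx, "motif_index.tsv")
  }
  if (!is.null(result$report$structures)) {
    wt(result$report$structures, "structure_counts.tsv")
  }
  invisible(out_dir)
}
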