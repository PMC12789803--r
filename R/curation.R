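# Dataset curation: resolution filtering, NMR-ensemble representative
# selection, motif clipping, sequence canonicalization, local-library
# counterpart matching, and RNA-type classification from metadata.

#' Construct a motif instance
#'
#' A clipped hairpin: the loop plus its first closing base pair, with a
#' provenance identifier of the form `ENTRYID_sequence_chain_startSeqNum`
#' built from author chain and residue numbering.
#'
#' @param entry_id,chain_id,start_seq_num Provenance fields.
#' @param sequence Display-character sequence (modified residues shown by
#'   their dictionary display character).
#' @param residues Screened atom table of the clipped residues, in order.
#' @param sse_type SSE type (HAIRPIN for clipped hairpins).
#' @param loop_size Number of unpaired loop residues (= length(sequence) - 2).
#' @return An object of class `motif_instance`.
#' @export
motif_instance <- function(entry_id, chain_id, start_seq_num, sequence,
                           residues, sse_type = "HAIRPIN",
                           loop_size = nchar(sequence) - 2L) {
  structure(list(
    motif_id = paste(entry_id, sequence, chain_id, start_seq_num, sep = "_"),
    entry_id = entry_id, chain_id = chain_id,
    start_seq_num = as.integer(start_seq_num), sequence = sequence,
    residues = residues, sse_type = sse_type,
    loop_size = as.integer(loop_size)), class = "motif_instance")
}

#' @export
print.motif_instance <- function(x, ...) {
  cat(sprintf("motif %s (%s, loop %d, %d atoms)\n", x$motif_id, x$sse_type,
              x$loop_size, nrow(x$residues)))
  invisible(x)
}

#' Parse a motif identifier
#'
#' @param motif_id Identifier of the form `ENTRYID_sequence_chain_start`.
#' @return List with `entry_id`, `sequence`, `chain_id`, `start_seq_num`.
#' @export
parse_motif_id <- function(motif_id) {
  parts <- strsplit(motif_id, "_", fixed = TRUE)[[1]]
  if (length(parts) < 4) stop("malformed motif_id: ", motif_id)
  n <- length(parts)
  list(entry_id = parts[1],
       sequence = paste(parts[2:(n - 2)], collapse = "_"),
       chain_id = parts[n - 1],
       start_seq_num = as.integer(parts[n]))
}

#' Resolution filter
#'
#' X-ray and cryo-EM entries are kept iff their resolution is at or below
#' `max_resolution` (boundary inclusive); entries with absent resolution are
#' excluded.  NMR entries always pass this filter (their redundancy is
#' handled by representative selection instead).
#'
#' @param entries List of `structure_entry` objects.
#' @param max_resolution Cutoff in Angstrom (default 3.0).
#' @return List with `kept` (entries) and `log` (data.frame entry_id, filter,
#'   outcome, reason).
#' @export
filter_entries <- function(entries, max_resolution = 3.0) {
  keep <- logical(length(entries))
  logs <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    if (e$method %in% c("XRAY", "EM")) {
      ok <- !is.na(e$resolution) && e$resolution <= max_resolution
      keep[i] <<- ok
      data.frame(entry_id = e$entry_id, filter = "resolution",
                 outcome = if (ok) "kept" else "excluded",
                 reason = if (ok) "" else "RESOLUTION",
                 stringsAsFactors = FALSE)
    } else {
      keep[i] <<- TRUE
      data.frame(entry_id = e$entry_id, filter = "resolution",
                 outcome = "kept", reason = "", stringsAsFactors = FALSE)
    }
  })
  list(kept = entries[keep], log = do.call(rbind, logs))
}

entry_model_coordset <- function(model, labels_from = NULL) {
  labs <- paste(model$chain, model$seq, model$icode, model$atom, sep = "|")
  coordinate_set(cbind(model$x, model$y, model$z), labs)
}

#' Select the representative model of an NMR ensemble
#'
#' Computes the iterative mean structure over all models (on shared screened
#' heavy atoms) and restricts the entry to the model with the lowest all-atom
#' RMSD to that mean; ties go to the earliest model.
#'
#' @param entry A `structure_entry` with method "NMR" (single-model entries
#'   are returned unchanged).
#' @param dict Modification dictionary.
#' @return The entry restricted to the representative model, with attributes
#'   `representative_index` and `rmsd_to_mean` (per-model vector).
#' @export
select_nmr_representative <- function(entry, dict = mod_dictionary()) {
  if (length(entry$models) == 1) {
    attr(entry, "representative_index") <- 1L
    attr(entry, "rmsd_to_mean") <- 0
    return(entry)
  }
  screened <- lapply(entry$models, function(m) screen_model(m, dict)$model)
  sets <- lapply(screened, entry_model_coordset)
  shared <- Reduce(intersect, lapply(sets, `[[`, "labels"))
  if (length(shared) < length(sets[[1]]$labels)) {
    warning(entry$entry_id, ": models differ in atom content; ",
            "using ", length(shared), " shared atoms")
  }
  sets <- lapply(sets, function(s) {
    idx <- match(shared, s$labels)
    coordinate_set(s$coords[idx, , drop = FALSE], shared)
  })
  rep <- representative_to_mean(sets)
  out <- entry
  out$models <- entry$models[rep$index]
  attr(out, "representative_index") <- rep$index
  attr(out, "rmsd_to_mean") <- rep$rmsd
  out
}

#' Revert a display sequence to its canonical alphabet
#'
#' Each modification display character is replaced by the canonical letter of
#' its component (all six shipped uridine modifications revert to U);
#' canonical letters pass through unchanged.  Idempotent and
#' length-preserving.
#'
#' @param sequence Display string (e.g. "GGuAAGC").
#' @param dict Modification dictionary.
#' @return Canonical string over A/C/G/U (e.g. "GGUAAGC").
#' @export
#' @examples
#' canonicalize_sequence("UGPPCAAAG")  # "UGUUCAAAG"
canonicalize_sequence <- function(sequence, dict = mod_dictionary()) {
  chars <- strsplit(sequence, "")[[1]]
  out <- vapply(chars, function(ch) {
    if (ch %in% c("A", "C", "G", "U")) return(ch)
    i <- match(ch, dict$display_char)
    if (is.na(i)) stop("UNKNOWN_COMPONENT: display character '", ch, "'")
    dict$canonical[i]
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = "")
}

#' Clip a hairpin motif from an entry
#'
#' Returns the loop residues plus the flanking (first) closing-pair residues
#' as a `motif_instance`; every residue must pass the quality screen.
#'
#' @param entry A single-model `structure_entry` (or an atom table).
#' @param sse A HAIRPIN SSE record from [assign_sses()] (needs
#'   `closing_pair` global indices).
#' @param dict Modification dictionary.
#' @param phosphate Passed to [screen_residue()].
#' @return A `motif_instance`, or an error condition with class
#'   "INCOMPLETE_SSE" (chain break in the span) / "CLIP_FAIL" (screen
#'   failure).
#' @export
clip_motif <- function(entry, sse, dict = mod_dictionary(),
                       phosphate = TRUE) {
  model <- if (inherits(entry, "structure_entry")) entry$models[[1]] else entry
  entry_id <- if (inherits(entry, "structure_entry")) entry$entry_id
              else "UNKNOWN"
  if (!identical(sse$sse_type, "HAIRPIN")) {
    stop("clip_motif requires a HAIRPIN SSE")
  }
  keys <- model_residue_index(model)
  gidx <- sse$closing_pair[1]:sse$closing_pair[2]
  sub <- keys[gidx, ]
  if (length(unique(sub$chain)) != 1) {
    stop(structure(class = c("INCOMPLETE_SSE", "error", "condition"),
                   list(message = "hairpin span crosses chains",
                        call = sys.call())))
  }
  steps <- diff(sub$seq)
  if (any(steps > 1 | steps < 0)) {
    stop(structure(class = c("INCOMPLETE_SSE", "error", "condition"),
                   list(message = "chain break inside hairpin span",
                        call = sys.call())))
  }
  all_gidx <- residue_gidx(model)
  screened <- lapply(gidx, function(g) {
    res <- model[all_gidx == g, ]
    s <- screen_residue(res, dict = dict, phosphate = phosphate)
    if (!s$ok) {
      stop(structure(class = c("CLIP_FAIL", "error", "condition"),
                     list(message = sprintf("residue %s/%d (%s): %s",
                                            res$chain[1], res$seq[1],
                                            res$comp[1], s$reason),
                          call = sys.call())))
    }
    s$residue
  })
  seq_chars <- display_char(sub$comp, dict)
  motif_instance(entry_id = entry_id, chain_id = sub$chain[1],
                 start_seq_num = sub$seq[1],
                 sequence = paste(seq_chars, collapse = ""),
                 residues = do.call(rbind, screened),
                 sse_type = "HAIRPIN", loop_size = length(gidx) - 2L)
}

#' Find unmodified counterparts of a motif in a local library
#'
#' Returns the library motifs whose SSE type and loop size match and whose
#' sequence equals the canonicalized sequence of the query, and which contain
#' no modified residues at any position (a local, exact-sequence stand-in for
#' a motif-database search; matching includes the closing pair).
#'
#' @param motif Query `motif_instance` (typically containing modifications).
#' @param library List of candidate `motif_instance`s (e.g. all hairpins
#'   clipped from an unmodified library).
#' @param dict Modification dictionary.
#' @return List of matching `motif_instance`s (possibly empty).
#' @export
match_unmodified <- function(motif, library, dict = mod_dictionary()) {
  target <- canonicalize_sequence(motif$sequence, dict)
  Filter(function(m) {
    m$sse_type == motif$sse_type &&
      m$loop_size == motif$loop_size &&
      identical(m$sequence, target) &&
      !any(m$residues$comp %in% dict$comp_id)
  }, library)
}

#' Classify the RNA type of a chain from its molecule description
#'
#' Case-insensitive keyword rules on the deposited free-text description:
#' ribosomal/16S/18S/23S/28S/5S -> rRNA; transfer/tRNA -> tRNA;
#' messenger/mRNA -> mRNA; snRNA/spliceosom -> snRNA;
#' synthetic/construct/aptamer -> synthetic; anything else (or a missing
#' description) -> other.
#'
#' @param entry A `structure_entry`.
#' @param chain Author chain identifier.
#' @return One of "tRNA", "rRNA", "mRNA", "snRNA", "synthetic", "other".
#' @export
classify_rna_type <- function(entry, chain) {
  mol <- entry$molecule_descriptions
  if (is.null(mol) || !chain %in% names(mol)) return("other")
  d <- tolower(mol[[chain]])
  if (grepl("ribosomal|16s|18s|23s|28s|5s", d)) "rRNA"
  else if (grepl("transfer|trna", d)) "tRNA"
  else if (grepl("messenger|mrna", d)) "mRNA"
  else if (grepl("snrna|spliceosom", d)) "snRNA"
  else if (grepl("synthetic|construct|aptamer|5'-r\\(", d)) "synthetic"
  else "other"
}

#' Clip a motif directly from its identifier
#'
#' Extracts the residues named by a motif identifier
#' (`ENTRYID_sequence_chain_start`): `length(sequence)` consecutive residues
#' of the author chain starting at the author residue number.  Each residue
#' must pass the quality screen; the residues' display sequence must match
#' the identifier's sequence.
#'
#' @param entry A `structure_entry`.
#' @param motif_id Motif identifier.
#' @param dict Modification dictionary.
#' @param phosphate Passed to [screen_residue()].
#' @return A `motif_instance`.
#' @export
clip_by_motif_id <- function(entry, motif_id, dict = mod_dictionary(),
                             phosphate = TRUE) {
  info <- parse_motif_id(motif_id)
  n <- nchar(info$sequence)
  model <- prepare_model(entry$models[[1]])
  keys <- model_residue_index(model)
  start_row <- which(keys$chain == info$chain_id &
                     keys$seq == info$start_seq_num)[1]
  if (is.na(start_row)) {
    stop("motif start ", info$chain_id, "/", info$start_seq_num,
         " not found in ", entry$entry_id)
  }
  gidx <- start_row:(start_row + n - 1L)
  if (max(gidx) > nrow(keys) ||
      length(unique(keys$chain[gidx])) != 1) {
    stop(structure(class = c("INCOMPLETE_SSE", "error", "condition"),
                   list(message = "motif span leaves the chain",
                        call = sys.call())))
  }
  all_gidx <- residue_gidx(model)
  screened <- lapply(gidx, function(g) {
    res <- model[all_gidx == g, ]
    s <- screen_residue(res, dict = dict, phosphate = phosphate)
    if (!s$ok) {
      stop(structure(class = c("CLIP_FAIL", "error", "condition"),
                     list(message = sprintf("residue %s/%d (%s): %s",
                                            res$chain[1], res$seq[1],
                                            res$comp[1], s$reason),
                          call = sys.call())))
    }
    s$residue
  })
  got <- paste(display_char(keys$comp[gidx], dict), collapse = "")
  if (!identical(got, info$sequence)) {
    warning("clipped sequence ", got, " differs from motif id ",
            info$sequence)
  }
  motif_instance(entry_id = info$entry_id, chain_id = info$chain_id,
                 start_seq_num = info$start_seq_num, sequence = got,
                 residues = do.call(rbind, screened),
                 sse_type = "HAIRPIN", loop_size = n - 2L)
}
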