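# Sequence-representative structures (SRS) and modified-vs-unmodified
# comparison: atom correspondence across chemistry differences, all-atom
# RMSD with the <= 1.0 A similarity call, and interaction differencing.

motif_coordset <- function(motif, select = NULL) {
  res <- motif$residues
  pos <- residue_gidx(res)
  labs <- paste(pos, res$atom, sep = "|")
  cs <- coordinate_set(cbind(res$x, res$y, res$z), labs)
  if (!is.null(select)) {
    idx <- match(select, cs$labels)
    if (anyNA(idx)) stop("CORRESPONDENCE_ERROR: label missing from motif")
    cs <- coordinate_set(cs$coords[idx, , drop = FALSE], select)
  }
  cs
}

#' Select the sequence-representative structure of a motif group
#'
#' All members of a group (same SSE type and sequence) are superposed and
#' averaged over their shared heavy atoms; the member with the lowest
#' all-atom RMSD to the mean structure is the representative.  Ties go to
#' the earliest member.
#'
#' @param group List of `motif_instance`s sharing sequence and topology.
#' @return List (`srs_record`): `group_key`, `member_ids`,
#'   `representative_id`, `representative` (the motif), `rmsd_to_mean`
#'   (named per-member vector).
#' @export
select_srs <- function(group) {
  stopifnot(length(group) >= 1)
  ids <- vapply(group, `[[`, character(1), "motif_id")
  if (length(group) == 1) {
    return(structure(list(
      group_key = c(group[[1]]$sse_type, group[[1]]$sequence),
      member_ids = ids, representative_id = ids[1],
      representative = group[[1]],
      rmsd_to_mean = stats::setNames(0, ids[1])), class = "srs_record"))
  }
  sets <- lapply(group, motif_coordset)
  shared <- Reduce(intersect, lapply(sets, `[[`, "labels"))
  if (length(shared) < 3) stop("TOO_FEW_ATOMS: group shares < 3 atoms")
  sets <- lapply(group, motif_coordset, select = shared)
  rep <- representative_to_mean(sets)
  structure(list(
    group_key = c(group[[1]]$sse_type, group[[1]]$sequence),
    member_ids = ids, representative_id = ids[rep$index],
    representative = group[[rep$index]],
    rmsd_to_mean = stats::setNames(rep$rmsd, ids)), class = "srs_record")
}

#' Position-by-position atom correspondence between two motifs
#'
#' Pairs atoms by name at each aligned position; atoms absent from the
#' counterpart residue (e.g. the 5MU methyl carbon, the OMU 2'-O-methyl) are
#' dropped and reported per side.  Pseudouridine pairs all base atoms with
#' uridine by name (same heavy-atom name set despite the rewired glycosidic
#' bond).
#'
#' @param modified,unmodified `motif_instance`s with equal residue counts and
#'   equal canonicalized sequences.
#' @param dict Modification dictionary.
#' @return List with `pairs` (data.frame position/atom), `dropped_modified`
#'   and `dropped_unmodified` (data.frames position/atom).
#' @export
atom_correspondence <- function(modified, unmodified,
                                dict = mod_dictionary()) {
  rm_ <- residue_split(modified$residues)
  ru <- residue_split(unmodified$residues)
  if (length(rm_) != length(ru)) {
    stop("CORRESPONDENCE_ERROR: unequal residue counts")
  }
  if (!identical(canonicalize_sequence(modified$sequence, dict),
                 canonicalize_sequence(unmodified$sequence, dict))) {
    stop("CORRESPONDENCE_ERROR: canonical sequences differ")
  }
  pairs <- list(); drop_m <- list(); drop_u <- list()
  for (p in seq_along(rm_)) {
    am <- rm_[[p]]$atom; au <- ru[[p]]$atom
    shared <- intersect(am, au)
    if (length(shared)) {
      pairs[[p]] <- data.frame(position = p, atom = shared,
                               stringsAsFactors = FALSE)
    }
    if (length(setdiff(am, au))) {
      drop_m[[p]] <- data.frame(position = p, atom = setdiff(am, au),
                                stringsAsFactors = FALSE)
    }
    if (length(setdiff(au, am))) {
      drop_u[[p]] <- data.frame(position = p, atom = setdiff(au, am),
                                stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(position = integer(0), atom = character(0))
  out <- list(pairs = if (length(pairs)) do.call(rbind, pairs) else empty,
              dropped_modified =
                if (length(drop_m)) do.call(rbind, drop_m) else empty,
              dropped_unmodified =
                if (length(drop_u)) do.call(rbind, drop_u) else empty)
  if (nrow(out$pairs) < 3) stop("CORRESPONDENCE_ERROR: fewer than 3 atoms")
  out
}

#' Compare a modified and an unmodified SRS
#'
#' Superposes the two motifs on their atom correspondence (Kabsch) and
#' reports the all-atom RMSD; pairs with RMSD at or below `threshold`
#' (default 1.0 A, boundary inclusive) are flagged similar, larger values
#' structurally distinct.
#'
#' @param modified,unmodified `motif_instance`s.
#' @param threshold Similarity threshold, Angstrom.
#' @param dict Modification dictionary.
#' @return A `comparison_result`: modified_id, unmodified_id,
#'   n_paired_atoms, rmsd, similar, dropped_atoms.
#' @export
compare_pair <- function(modified, unmodified, threshold = 1.0,
                         dict = mod_dictionary()) {
  corr <- atom_correspondence(modified, unmodified, dict)
  labs <- paste(corr$pairs$position, corr$pairs$atom, sep = "|")
  cs_m <- motif_coordset(modified, select = labs)
  cs_u <- motif_coordset(unmodified, select = labs)
  sp <- kabsch_superpose(cs_m, cs_u)
  structure(list(
    modified_id = modified$motif_id, unmodified_id = unmodified$motif_id,
    n_paired_atoms = sp$n_atoms, rmsd = sp$rmsd,
    similar = sp$rmsd <= threshold,
    dropped_atoms = list(modified = corr$dropped_modified,
                         unmodified = corr$dropped_unmodified),
    superposition = sp), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s: RMSD %.3f A over %d atoms -> %s\n",
              x$modified_id, x$unmodified_id, x$rmsd, x$n_paired_atoms,
              if (x$similar) "similar" else "distinct"))
  invisible(x)
}

#' Normalized interaction descriptors of a motif in its parent context
#'
#' For each motif position, collects hydrogen bonds, stacking contacts and
#' base pairs involving that residue from a parent-structure annotation.
#' Descriptors are normalized for cross-structure comparison: an in-motif
#' partner is identified by its motif position and canonical component, an
#' out-of-motif nucleotide partner as "<canonical>(tertiary)", and a protein
#' partner by its 3-letter residue code; distances are omitted.
#'
#' @param annotation Output of [annotate_model()] on the parent model.
#' @param model The annotated parent atom table.
#' @param motif The `motif_instance` clipped from that model.
#' @param dict Modification dictionary.
#' @param tertiary Include interactions with partners outside the motif?
#' @return data.frame with `position`, `kind` (HBOND/STACK/PAIR) and
#'   `partner` descriptor.
#' @export
motif_interactions <- function(annotation, model, motif,
                               dict = mod_dictionary(), tertiary = TRUE) {
  keys <- model_residue_index(model)
  mres <- residue_keys(motif$residues)
  midx <- match(paste(mres$chain, mres$seq, mres$icode),
                paste(keys$chain, keys$seq, keys$icode))
  if (anyNA(midx)) stop("motif residues not found in model")
  partner_desc <- function(g) {
    p <- match(g, midx)
    cc <- keys$comp[g]
    if (!is.na(p)) {
      return(sprintf("pos%d:%s", p, canonical_parent(cc, dict)))
    }
    if (cc %in% known_components(dict)) {
      sprintf("%s(tertiary)", canonical_parent(cc, dict))
    } else {
      sprintf("%s(protein)", cc)
    }
  }
  rows <- list()
  add <- function(position, kind, partner_gidx) {
    if (is.na(match(partner_gidx, midx)) && !tertiary) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      position = position, kind = kind,
      partner = partner_desc(partner_gidx), stringsAsFactors = FALSE)
  }
  hb <- annotation$hbonds
  for (r in seq_len(nrow(hb))) {
    pd <- match(hb$donor_gidx[r], midx); pa <- match(hb$acceptor_gidx[r], midx)
    if (!is.na(pd)) add(pd, "HBOND", hb$acceptor_gidx[r])
    if (!is.na(pa)) add(pa, "HBOND", hb$donor_gidx[r])
  }
  st <- annotation$stacks
  for (r in seq_len(nrow(st))) {
    p1 <- match(st$gidx_a[r], midx); p2 <- match(st$gidx_b[r], midx)
    if (!is.na(p1)) add(p1, "STACK", st$gidx_b[r])
    if (!is.na(p2)) add(p2, "STACK", st$gidx_a[r])
  }
  bp <- annotation$pairs
  for (r in seq_len(nrow(bp))) {
    p1 <- match(bp$gidx_a[r], midx); p2 <- match(bp$gidx_b[r], midx)
    if (!is.na(p1)) add(p1, "PAIR", bp$gidx_b[r])
    if (!is.na(p2)) add(p2, "PAIR", bp$gidx_a[r])
  }
  if (!length(rows)) {
    return(data.frame(position = integer(0), kind = character(0),
                      partner = character(0)))
  }
  unique(do.call(rbind, rows))
}

#' Interaction differences between two motifs
#'
#' Per-position set difference of normalized interaction descriptors
#' (see [motif_interactions()]): interactions present only in the modified
#' motif are gained, only in the unmodified lost, in both shared.
#'
#' @param modified_interactions,unmodified_interactions Outputs of
#'   [motif_interactions()] for the two motifs.
#' @return data.frame with `position`, `kind`, `partner`, `status`
#'   (gained/lost/shared).
#' @export
diff_interactions <- function(modified_interactions,
                              unmodified_interactions) {
  key <- function(d) paste(d$position, d$kind, d$partner, sep = "\r")
  km <- key(modified_interactions); ku <- key(unmodified_interactions)
  all_rows <- rbind(modified_interactions, unmodified_interactions)
  all_rows <- all_rows[!duplicated(key(all_rows)), , drop = FALSE]
  ka <- key(all_rows)
  status <- ifelse(ka %in% km & ka %in% ku, "shared",
                   ifelse(ka %in% km, "gained", "lost"))
  out <- cbind(all_rows, data.frame(status = status,
                                    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$position, out$kind, out$partner), ]
}

#' Accession-backed spot checks of the comparison machinery
#'
#' Re-runs four published modified-vs-unmodified hairpin comparisons on
#' locally supplied mmCIF files (downloaded from the PDB into `dir`, named
#' `<ENTRYID>.cif`): the UR3 pentaloop pair 7F5S/6Y6X, the two 4SU pairs
#' 5WDT/7MT2 and 6SKF/4V4N, and the H2U pair 3JCS/7QIW.  Each motif is
#' clipped by its identifier, screened, and compared by all-atom RMSD.
#'
#' @param dir Directory containing the eight entry files.
#' @param threshold Similarity threshold, Angstrom.
#' @param dict Modification dictionary.
#' @return data.frame with the pair identifiers, the computed RMSD and the
#'   similarity call.
#' @export
spot_check_accessions <- function(dir, threshold = 1.0,
                                  dict = mod_dictionary()) {
  checks <- list(
    list(mod = "7F5S_GGuAAGC_L5_1864", unmod = "6Y6X_GGUAAGC_L5_1865",
         label = "UR3_pentaloop"),
    list(mod = "5WDT_uGGAGCAG_w_8", unmod = "7MT2_UGGAGCAG_A_2767",
         label = "4SU_hexaloop"),
    list(mod = "6SKF_AGCCCAuAU_BA_2575", unmod = "4V4N_AGCCCAUAU_A1_2587",
         label = "4SU_heptaloop"),
    list(mod = "3JCS_CGuGAG_2_1402", unmod = "7QIW_CGUGAG_2_2968",
         label = "H2U_tetraloop")
  )
  rows <- lapply(checks, function(ck) {
    ids <- c(parse_motif_id(ck$mod)$entry_id,
             parse_motif_id(ck$unmod)$entry_id)
    paths <- file.path(dir, paste0(ids, ".cif"))
    if (!all(file.exists(paths))) {
      stop("missing structure files for ", ck$label, ": ",
           paste(paths[!file.exists(paths)], collapse = ", "))
    }
    e_mod <- parse_structure(paths[1])
    e_unmod <- parse_structure(paths[2])
    if (e_mod$method == "NMR") e_mod <- select_nmr_representative(e_mod)
    if (e_unmod$method == "NMR") e_unmod <- select_nmr_representative(e_unmod)
    m_mod <- clip_by_motif_id(e_mod, ck$mod, dict, phosphate = FALSE)
    m_unmod <- clip_by_motif_id(e_unmod, ck$unmod, dict, phosphate = FALSE)
    cmp <- compare_pair(m_mod, m_unmod, threshold = threshold, dict = dict)
    data.frame(label = ck$label, modified_id = ck$mod,
               unmodified_id = ck$unmod, rmsd = cmp$rmsd,
               similar = cmp$similar, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
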