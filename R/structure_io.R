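# Structure input/output: a uniform atom-table coordinate model, PDBx/mmCIF
# and PDB readers and writers, and the residue-quality screen (all heavy atoms
# present, single coordinate per atom, hydrogens removed).
#
# An atom table (one model) is a data.frame with columns
#   chain, seq, icode, comp, atom, element, alt, occ, x, y, z
# using author chain identifiers and author residue numbers throughout, since
# motif identifiers (ENTRYID_sequence_chain_start) are built from author
# numbering.

ATOM_TABLE_COLS <- c("chain", "seq", "icode", "comp", "atom", "element",
                     "alt", "occ", "x", "y", "z")

#' Construct a structure entry
#'
#' @param entry_id 4-character entry identifier.
#' @param method One of "XRAY", "EM", "NMR", "OTHER".
#' @param resolution Resolution in Angstrom, or NA (NMR/OTHER).
#' @param models List of atom tables with identical residue topology.
#' @param molecule_descriptions Named character vector (by chain) of free-text
#'   molecule descriptions, or NULL.
#' @param organism Free-text organism, or NA.
#' @return An object of class `structure_entry`.
#' @export
structure_entry <- function(entry_id, method, resolution, models,
                            molecule_descriptions = NULL,
                            organism = NA_character_) {
  method <- match.arg(method, c("XRAY", "EM", "NMR", "OTHER"))
  if (length(models) < 1) stop("empty-structure error: no models")
  models <- lapply(models, function(m) {
    missing_cols <- setdiff(ATOM_TABLE_COLS, names(m))
    if (length(missing_cols)) {
      stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
    }
    m[, ATOM_TABLE_COLS]
  })
  if (method %in% c("NMR", "OTHER")) resolution <- NA_real_
  structure(list(entry_id = entry_id, method = method,
                 resolution = as.numeric(resolution), models = models,
                 molecule_descriptions = molecule_descriptions,
                 organism = organism),
            class = "structure_entry")
}

#' @export
print.structure_entry <- function(x, ...) {
  cat(sprintf("structure_entry %s: %s%s, %d model(s), %d atoms (model 1)\n",
              x$entry_id, x$method,
              if (is.na(x$resolution)) "" else sprintf(" %.2f A", x$resolution),
              length(x$models), nrow(x$models[[1]])))
  invisible(x)
}

residue_keys <- function(model) {
  unique(model[, c("chain", "seq", "icode", "comp")])
}

get_residue <- function(model, chain, seq, icode = "") {
  model[model$chain == chain & model$seq == seq & model$icode == icode, ]
}

residue_split <- function(model) {
  key <- paste(model$chain, model$seq, model$icode, sep = "\r")
  split(model, factor(key, levels = unique(key)))
}

# ---------------------------------------------------------------------------
# mmCIF reading

cif_tokens <- function(text) {
  # Tokenize one logical chunk of mmCIF data values, honouring single and
  # double quotes.
  m <- gregexpr("('[^']*')|(\"[^\"]*\")|(\\S+)", text)
  toks <- regmatches(text, m)[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

read_cif_categories <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  items <- list()    # tag -> value (non-loop)
  loops <- list()    # category -> data.frame
  i <- 1L
  read_semicolon_block <- function(i) {
    val <- sub("^;", "", lines[i])
    i <- i + 1L
    while (i <= n && !startsWith(lines[i], ";")) {
      val <- paste(val, lines[i]); i <- i + 1L
    }
    list(value = trimws(val), next_i = i + 1L)
  }
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "data_")) {
      i <- i + 1L; next
    }
    if (ln == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1L
      }
      vals <- character(0)
      while (i <= n) {
        ln2 <- lines[i]
        t2 <- trimws(ln2)
        if (t2 == "" || startsWith(t2, "_") || startsWith(t2, "loop_") ||
            startsWith(t2, "data_") || startsWith(t2, "#")) break
        if (startsWith(ln2, ";")) {
          blk <- read_semicolon_block(i)
          vals <- c(vals, blk$value); i <- blk$next_i
        } else {
          vals <- c(vals, cif_tokens(ln2)); i <- i + 1L
        }
      }
      if (length(tags) && length(vals)) {
        ncol <- length(tags)
        if (length(vals) %% ncol != 0) {
          stop("parse error in mmCIF loop near line ", i, " (category ",
               sub("\\..*$", "", tags[1]), "): ragged value count")
        }
        mat <- matrix(vals, ncol = ncol, byrow = TRUE)
        df <- as.data.frame(mat, stringsAsFactors = FALSE)
        names(df) <- sub("^_", "", tags)
        cat_name <- sub("\\..*$", "", names(df)[1])
        loops[[cat_name]] <- df
      }
      next
    }
    if (startsWith(ln, "_")) {
      toks <- cif_tokens(ln)
      tag <- toks[1]
      if (length(toks) >= 2) {
        items[[sub("^_", "", tag)]] <- paste(toks[-1], collapse = " ")
        i <- i + 1L
      } else {
        i <- i + 1L
        if (i <= n && startsWith(lines[i], ";")) {
          blk <- read_semicolon_block(i)
          items[[sub("^_", "", tag)]] <- blk$value
          i <- blk$next_i
        } else {
          items[[sub("^_", "", tag)]] <- trimws(gsub("^['\"]|['\"]$", "",
                                                     trimws(lines[i])))
          i <- i + 1L
        }
      }
      next
    }
    i <- i + 1L
  }
  list(items = items, loops = loops)
}

cif_col <- function(df, name, default = NA_character_) {
  if (name %in% names(df)) df[[name]] else rep(default, nrow(df))
}

map_method_string <- function(s) {
  if (is.null(s) || is.na(s)) return("OTHER")
  s <- toupper(s)
  if (grepl("X-RAY|XRAY", s)) "XRAY"
  else if (grepl("ELECTRON MICROSCOPY|CRYO", s)) "EM"
  else if (grepl("NMR", s)) "NMR"
  else "OTHER"
}

parse_mmcif <- function(path) {
  cats <- read_cif_categories(path)
  as_df <- cats$loops[["atom_site"]]
  if (is.null(as_df)) {
    # single-row atom_site written without loop_ is not supported; a missing
    # category means no coordinates at all
    stop("empty-structure error: no _atom_site records in ", path)
  }
  dot_na <- function(x) ifelse(x %in% c(".", "?"), "", x)
  chain <- cif_col(as_df, "atom_site.auth_asym_id")
  if (all(is.na(chain))) chain <- cif_col(as_df, "atom_site.label_asym_id")
  seq <- cif_col(as_df, "atom_site.auth_seq_id")
  if (all(is.na(seq))) seq <- cif_col(as_df, "atom_site.label_seq_id")
  comp <- cif_col(as_df, "atom_site.label_comp_id")
  if (all(is.na(comp))) comp <- cif_col(as_df, "atom_site.auth_comp_id")
  atom <- cif_col(as_df, "atom_site.label_atom_id")
  if (all(is.na(atom))) atom <- cif_col(as_df, "atom_site.auth_atom_id")
  occ <- suppressWarnings(as.numeric(cif_col(as_df, "atom_site.occupancy")))
  occ[is.na(occ)] <- 1.0
  model_num <- cif_col(as_df, "atom_site.pdbx_PDB_model_num", "1")
  model_num[model_num %in% c(".", "?", NA)] <- "1"
  tab <- data.frame(
    chain = dot_na(chain),
    seq = as.integer(seq),
    icode = dot_na(cif_col(as_df, "atom_site.pdbx_PDB_ins_code", "")),
    comp = toupper(comp),
    atom = atom,
    element = dot_na(cif_col(as_df, "atom_site.type_symbol", "")),
    alt = dot_na(cif_col(as_df, "atom_site.label_alt_id", "")),
    occ = occ,
    x = as.numeric(cif_col(as_df, "atom_site.Cartn_x")),
    y = as.numeric(cif_col(as_df, "atom_site.Cartn_y")),
    z = as.numeric(cif_col(as_df, "atom_site.Cartn_z")),
    model = as.integer(model_num),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(tab$x) | !is.finite(tab$y) | !is.finite(tab$z))) {
    stop("parse error: non-finite coordinates in _atom_site of ", path)
  }
  models <- lapply(split(tab, tab$model), function(m) {
    rownames(m) <- NULL
    m[, ATOM_TABLE_COLS]
  })
  names(models) <- NULL

  items <- cats$items
  entry_id <- items[["entry.id"]]
  if (is.null(entry_id)) {
    entry_id <- toupper(sub("\\.(cif|mmcif)$", "", basename(path)))
  }
  method_str <- items[["exptl.method"]]
  if (is.null(method_str) && !is.null(cats$loops[["exptl"]])) {
    method_str <- cats$loops[["exptl"]][["exptl.method"]][1]
  }
  method <- map_method_string(method_str)
  res <- NA_real_
  for (tag in c("refine.ls_d_res_high", "em_3d_reconstruction.resolution",
                "reflns.d_resolution_high")) {
    v <- items[[tag]]
    if (is.null(v) && !is.null(cats$loops[[sub("\\..*", "", tag)]])) {
      v <- cats$loops[[sub("\\..*", "", tag)]][[tag]][1]
    }
    if (!is.null(v) && !v %in% c(".", "?")) {
      res <- suppressWarnings(as.numeric(v))
      if (!is.na(res)) break
    }
  }

  # molecule descriptions: entity description joined to author chains through
  # the atom_site label_entity_id column
  mol <- NULL
  ent <- cats$loops[["entity"]]
  if (is.null(ent) && !is.null(items[["entity.pdbx_description"]])) {
    ent <- data.frame(entity.id = items[["entity.id"]] %||% "1",
                      entity.pdbx_description =
                        items[["entity.pdbx_description"]],
                      stringsAsFactors = FALSE)
  }
  ent_col <- cif_col(as_df, "atom_site.label_entity_id")
  if (!is.null(ent) && "entity.pdbx_description" %in% names(ent) &&
      !all(is.na(ent_col))) {
    first_rows <- !duplicated(chain)
    desc <- ent[["entity.pdbx_description"]][
      match(ent_col[first_rows], ent[["entity.id"]])]
    mol <- stats::setNames(desc, dot_na(chain)[first_rows])
  }
  organism <- NA_character_
  for (tag in c("entity_src_nat.pdbx_organism_scientific",
                "entity_src_gen.pdbx_gene_src_scientific_name")) {
    if (!is.null(items[[tag]])) { organism <- items[[tag]]; break }
    ctg <- cats$loops[[sub("\\..*", "", tag)]]
    if (!is.null(ctg) && tag %in% names(ctg)) { organism <- ctg[[tag]][1]; break }
  }

  structure_entry(entry_id, method, res, models,
                  molecule_descriptions = mol, organism = organism)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# PDB reading (via bio3d) and header metadata

parse_pdb <- function(path) {
  hdr <- readLines(path, warn = FALSE)
  method <- "OTHER"; res <- NA_real_
  expdta <- grep("^EXPDTA", hdr, value = TRUE)
  if (length(expdta)) method <- map_method_string(expdta[1])
  remark2 <- grep("^REMARK   2 RESOLUTION", hdr, value = TRUE)
  if (length(remark2)) {
    v <- regmatches(remark2[1], regexpr("[0-9]+\\.[0-9]+", remark2[1]))
    if (length(v)) res <- as.numeric(v)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  base <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    seq = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    comp = toupper(at$resid),
    atom = at$elety,
    element = ifelse(is.na(at$elesy), "", trimws(at$elesy)),
    alt = ifelse(is.na(at$alt), "", at$alt),
    occ = ifelse(is.na(at$o), 1.0, at$o),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  nmodel <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  models <- lapply(seq_len(nmodel), function(k) {
    m <- base
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[k, ] else pdb$xyz
    m$x <- xyz[seq(1, length(xyz), 3)]
    m$y <- xyz[seq(2, length(xyz), 3)]
    m$z <- xyz[seq(3, length(xyz), 3)]
    m
  })
  remap <- grep("^REMARK 250 CHAIN-REMAP", hdr, value = TRUE)
  if (length(remap)) {
    # undo the deterministic chain remapping recorded by write_motif
    map <- do.call(rbind, strsplit(sub("^REMARK 250 CHAIN-REMAP ", "", remap),
                                   " -> "))
    for (k in seq_along(models)) {
      idx <- match(models[[k]]$chain, map[, 2])
      models[[k]]$chain <- ifelse(is.na(idx), models[[k]]$chain, map[idx, 1])
    }
  }
  entry_id <- toupper(sub("\\.(pdb|ent)$", "", basename(path)))
  hd <- grep("^HEADER", hdr, value = TRUE)
  if (length(hd) && nchar(hd[1]) >= 66) {
    id <- trimws(substr(hd[1], 63, 66))
    if (nzchar(id)) entry_id <- id
  }
  structure_entry(entry_id, method, res, models)
}

#' Read a macromolecular structure file
#'
#' Reads PDBx/mmCIF (preferred) or PDB format into a [structure_entry()]:
#' all models, author chain and residue numbering, occupancies, alternate
#' location tags, experimental method and resolution.  Residue order follows
#' file order; coordinates are in Angstrom.
#'
#' @param path File path.
#' @param format "mmcif", "pdb" or "auto" (by file extension).
#' @return A `structure_entry`.
#' @export
parse_structure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif"
              else "pdb"
  }
  entry <- switch(format, mmcif = parse_mmcif(path), pdb = parse_pdb(path))
  topo <- lapply(entry$models, function(m) paste(m$chain, m$seq, m$icode,
                                                 m$comp, m$atom))
  if (length(unique(vapply(topo, paste, character(1), collapse = "\n"))) > 1) {
    warning("models of ", entry$entry_id, " differ in atom topology")
  }
  entry
}

# ---------------------------------------------------------------------------
# Residue-quality screen

is_hydrogen_row <- function(atom, element) {
  el <- toupper(trimws(element))
  known_h <- el %in% c("H", "D")
  # fall back to the name pattern (leading H after any digits) when the
  # element field is blank
  name_h <- !nzchar(el) & grepl("^[0-9]*H", atom)
  known_h | name_h
}

#' Residue-quality screen
#'
#' Removes hydrogens, resolves alternate locations to a single coordinate per
#' atom (highest occupancy wins; ties break on the alphabetically first
#' alternate identifier), and rejects the residue if any reference heavy atom
#' is missing.
#'
#' @param residue Atom table rows of one residue.
#' @param reference_atoms Expected heavy-atom name set; defaults to
#'   [component_atoms()] of the residue's component.
#' @param dict Modification dictionary (for reference-atom lookup).
#' @param phosphate Require the 5'-phosphate group (see [component_atoms()]).
#' @return List with `ok` (logical); on success `residue` (the screened atom
#'   table); on rejection `reason`, one of "UNKNOWN_COMPONENT",
#'   "MISSING_ATOMS", "MULTI_COORD_UNRESOLVED", plus `detail`.
#' @export
screen_residue <- function(residue, reference_atoms = NULL,
                           dict = mod_dictionary(), phosphate = TRUE) {
  comp <- residue$comp[1]
  if (is.null(reference_atoms)) {
    if (!comp %in% known_components(dict)) {
      return(list(ok = FALSE, reason = "UNKNOWN_COMPONENT", detail = comp))
    }
    reference_atoms <- component_atoms(comp, phosphate = phosphate)
  }
  res <- residue[!is_hydrogen_row(residue$atom, residue$element), ,
                 drop = FALSE]
  # resolve alternate locations: per atom name keep max occupancy, ties by
  # alphabetical alt id
  if (anyDuplicated(res$atom)) {
    keep <- unlist(lapply(split(seq_len(nrow(res)), res$atom), function(ix) {
      if (length(ix) == 1) return(ix)
      sub <- res[ix, ]
      if (all(!nzchar(sub$alt))) return(NA_integer_)  # duplicates, no alt ids
      ord <- order(-sub$occ, sub$alt)
      ix[ord[1]]
    }))
    if (anyNA(keep)) {
      return(list(ok = FALSE, reason = "MULTI_COORD_UNRESOLVED",
                  detail = comp))
    }
    res <- res[sort(keep), , drop = FALSE]
  }
  res$alt <- ""
  missing <- setdiff(reference_atoms, res$atom)
  if (length(missing)) {
    return(list(ok = FALSE, reason = "MISSING_ATOMS",
                detail = paste(missing, collapse = ",")))
  }
  rownames(res) <- NULL
  list(ok = TRUE, residue = res)
}

#' Prepare a model for annotation
#'
#' Light version of the screen used before geometric annotation: strips
#' hydrogens and resolves alternate locations, but keeps residues with
#' missing atoms or unknown components (completeness is enforced later, at
#' motif clipping).
#'
#' @param model An atom table.
#' @return The prepared atom table.
#' @export
prepare_model <- function(model) {
  res <- model[!is_hydrogen_row(model$atom, model$element), , drop = FALSE]
  gidx <- residue_gidx(res)
  dup_key <- paste(gidx, res$atom, sep = "\r")
  if (anyDuplicated(dup_key)) {
    keep <- unlist(lapply(split(seq_len(nrow(res)), dup_key), function(ix) {
      if (length(ix) == 1) return(ix)
      sub <- res[ix, ]
      ix[order(-sub$occ, sub$alt)[1]]
    }))
    res <- res[sort(keep), , drop = FALSE]
  }
  res$alt <- ""
  rownames(res) <- NULL
  res
}

#' Screen every residue of a model
#'
#' @param model An atom table.
#' @inheritParams screen_residue
#' @return List with `model` (atom table of all passing, screened residues)
#'   and `rejections` (data.frame chain/seq/icode/comp/reason).
#' @export
screen_model <- function(model, dict = mod_dictionary(), phosphate = TRUE) {
  pieces <- residue_split(model)
  rej <- list(); keep <- list()
  for (p in pieces) {
    s <- screen_residue(p, dict = dict, phosphate = phosphate)
    if (s$ok) keep[[length(keep) + 1L]] <- s$residue
    else rej[[length(rej) + 1L]] <- data.frame(
      chain = p$chain[1], seq = p$seq[1], icode = p$icode[1],
      comp = p$comp[1], reason = s$reason, stringsAsFactors = FALSE)
  }
  list(model = if (length(keep)) do.call(rbind, keep) else model[0, ],
       rejections = if (length(rej)) do.call(rbind, rej) else
         data.frame(chain = character(0), seq = integer(0),
                    icode = character(0), comp = character(0),
                    reason = character(0)))
}

# ---------------------------------------------------------------------------
# Writing

cif_quote <- function(x) {
  ifelse(grepl("['\" ]", x) | !nzchar(x),
         paste0('"', ifelse(nzchar(x), x, "."), '"'), x)
}

method_to_cif <- function(method) {
  switch(method, XRAY = "X-RAY DIFFRACTION", EM = "ELECTRON MICROSCOPY",
         NMR = "SOLUTION NMR", "OTHER")
}

#' Write a structure entry as PDBx/mmCIF
#'
#' Emits entry id, experimental method, resolution, per-chain entity
#' descriptions and a complete multi-model `_atom_site` loop (coordinates to
#' 3 decimals).
#'
#' @param entry A `structure_entry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(entry, path) {
  out <- c(sprintf("data_%s", entry$entry_id), "#",
           sprintf("_entry.id %s", entry$entry_id),
           sprintf("_exptl.method '%s'", method_to_cif(entry$method)))
  if (!is.na(entry$resolution)) {
    tag <- if (entry$method == "EM") "_em_3d_reconstruction.resolution"
           else "_refine.ls_d_res_high"
    out <- c(out, sprintf("%s %.2f", tag, entry$resolution))
  }
  if (!is.na(entry$organism)) {
    out <- c(out, sprintf("_entity_src_nat.pdbx_organism_scientific '%s'",
                          entry$organism))
  }
  chains <- unique(entry$models[[1]]$chain)
  mol <- entry$molecule_descriptions
  ent_of_chain <- stats::setNames(seq_along(chains), chains)
  if (!is.null(mol)) {
    out <- c(out, "#", "loop_", "_entity.id", "_entity.pdbx_description",
             vapply(chains, function(ch) {
               d <- if (ch %in% names(mol)) mol[[ch]] else "RNA"
               sprintf("%d '%s'", ent_of_chain[[ch]], d)
             }, character(1)))
  }
  hdr <- c("loop_", "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.auth_seq_id", "_atom_site.auth_asym_id",
           "_atom_site.pdbx_PDB_model_num")
  out <- c(out, "#", hdr)
  id <- 0L
  for (k in seq_along(entry$models)) {
    m <- entry$models[[k]]
    ids <- id + seq_len(nrow(m))
    id <- id + nrow(m)
    out <- c(out, sprintf(
      "ATOM %d %s %s %s %s %s %d %d %s %.3f %.3f %.3f %.2f %.2f %d %s %d",
      ids,
      ifelse(nzchar(m$element), m$element, "X"),
      cif_quote(m$atom),
      ifelse(nzchar(m$alt), m$alt, "."),
      m$comp,
      cif_quote(m$chain),
      unname(ent_of_chain[m$chain]),
      m$seq,
      ifelse(nzchar(m$icode), m$icode, "?"),
      m$x, m$y, m$z, m$occ, 0,
      m$seq, cif_quote(m$chain), k))
  }
  writeLines(c(out, "#"), path)
  invisible(path)
}

#' Write a clipped motif to disk
#'
#' Writes the motif's residues as a single-model structure.  In PDB format,
#' author chain identifiers longer than one character are deterministically
#' remapped (in order of appearance, to A, B, ...) and the mapping is
#' recorded in `REMARK 250 CHAIN-REMAP` header lines, which the PDB reader
#' undoes on re-parse.
#'
#' @param motif A `motif_instance` (see [clip_motif()]).
#' @param path Output path.
#' @param format "mmcif" or "pdb".
#' @return The chain-remap table (PDB) or NULL (mmCIF), invisibly.
#' @export
write_motif <- function(motif, path, format = c("mmcif", "pdb")) {
  format <- match.arg(format)
  if (is.null(motif$residues) || nrow(motif$residues) == 0) {
    stop("empty motif")
  }
  entry <- structure_entry(motif$entry_id, "OTHER", NA_real_,
                           list(motif$residues))
  if (format == "mmcif") {
    write_structure_cif(entry, path)
    return(invisible(NULL))
  }
  m <- motif$residues
  chains <- unique(m$chain)
  long <- nchar(chains) > 1
  remap <- NULL
  if (any(long)) {
    pool <- setdiff(c(LETTERS, letters, as.character(0:9)), chains[!long])
    remap <- data.frame(from = chains[long],
                        to = pool[seq_len(sum(long))],
                        stringsAsFactors = FALSE)
    idx <- match(m$chain, remap$from)
    m$chain <- ifelse(is.na(idx), m$chain, remap$to[idx])
  }
  lines <- c(sprintf("HEADER    RNA MOTIF %s", motif$motif_id))
  if (!is.null(remap)) {
    lines <- c(lines, sprintf("REMARK 250 CHAIN-REMAP %s -> %s",
                              remap$from, remap$to))
  }
  name_fmt <- function(a) {
    # column alignment rule: element symbol in columns 13-14
    ifelse(nchar(a) >= 4, substr(a, 1, 4), sprintf(" %-3s", a))
  }
  lines <- c(lines, sprintf(
    "ATOM  %5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(m)), name_fmt(m$atom),
    ifelse(nzchar(m$alt), m$alt, " "),
    m$comp, m$chain, m$seq,
    ifelse(nzchar(m$icode), m$icode, " "),
    m$x, m$y, m$z, m$occ, 0,
    ifelse(nzchar(m$element), m$element, "")))
  writeLines(c(lines, "END"), path)
  invisible(remap)
}
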