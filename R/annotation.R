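# Geometric annotation: hydrogen bonds, base stacking, base pairs, and
# secondary-structure elements (hairpins, helices, internal loops, bulges,
# junctions).  Distance-only hydrogen-bond detection at a 4.0 A heavy-atom
# cutoff; the quality screen has already removed hydrogens.

model_residue_index <- function(model) {
  keys <- residue_keys(model)
  keys$gidx <- seq_len(nrow(keys))
  keys
}

residue_gidx <- function(model) {
  key <- paste(model$chain, model$seq, model$icode, sep = "\r")
  match(key, unique(key))
}

# donors/acceptors for non-nucleotide components (amino acids, ions, ...)
# classified by atom-name pattern
generic_donors <- function(atoms) {
  atoms[grepl("^N", atoms) | atoms %in% c("OG", "OG1", "OH", "SG", "OW")]
}
generic_acceptors <- function(atoms) {
  atoms[grepl("^(O|S)", atoms)]
}

#' Detect hydrogen bonds in a model
#'
#' All donor/acceptor heavy-atom pairs between different residues with a
#' distance at or below `cutoff` (boundary inclusive).  Donor and acceptor
#' atom lists come from the shipped per-component chemistry tables
#' ([donor_atoms()], [acceptor_atoms()]); atoms of non-nucleotide components
#' are classified by name pattern so contacts to protein residues are
#' reported too.
#'
#' @param model Screened atom table.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @param dict Modification dictionary.
#' @return data.frame with donor and acceptor residue references, atom names,
#'   distance, and a `base_base` flag (both atoms on nucleobases).
#' @export
detect_hbonds <- function(model, cutoff = 4.0, dict = mod_dictionary()) {
  gidx <- residue_gidx(model)
  nuc <- known_components(dict)
  don_rows <- acc_rows <- logical(nrow(model))
  base_row <- logical(nrow(model))
  for (cc in unique(model$comp)) {
    sel <- model$comp == cc
    if (cc %in% nuc) {
      don_rows[sel] <- model$atom[sel] %in% donor_atoms(cc)
      acc_rows[sel] <- model$atom[sel] %in% acceptor_atoms(cc)
      base_row[sel] <- model$atom[sel] %in% base_atoms(cc)
    } else {
      don_rows[sel] <- model$atom[sel] %in% generic_donors(model$atom[sel])
      acc_rows[sel] <- model$atom[sel] %in% generic_acceptors(model$atom[sel])
    }
  }
  empty <- data.frame(donor_chain = character(0), donor_seq = integer(0),
                      donor_icode = character(0), donor_comp = character(0),
                      donor_atom = character(0),
                      acceptor_chain = character(0), acceptor_seq = integer(0),
                      acceptor_icode = character(0),
                      acceptor_comp = character(0),
                      acceptor_atom = character(0), distance = numeric(0),
                      donor_gidx = integer(0), acceptor_gidx = integer(0),
                      base_base = logical(0))
  if (!any(don_rows) || !any(acc_rows)) return(empty)
  D <- which(don_rows); A <- which(acc_rows)
  dx <- outer(model$x[D], model$x[A], "-")
  dy <- outer(model$y[D], model$y[A], "-")
  dz <- outer(model$z[D], model$z[A], "-")
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  same_res <- outer(gidx[D], gidx[A], "==")
  hit <- which(dist <= cutoff & !same_res, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  di <- D[hit[, 1]]; ai <- A[hit[, 2]]
  out <- data.frame(
    donor_chain = model$chain[di], donor_seq = model$seq[di],
    donor_icode = model$icode[di], donor_comp = model$comp[di],
    donor_atom = model$atom[di],
    acceptor_chain = model$chain[ai], acceptor_seq = model$seq[ai],
    acceptor_icode = model$icode[ai], acceptor_comp = model$comp[ai],
    acceptor_atom = model$atom[ai],
    distance = dist[hit],
    donor_gidx = gidx[di], acceptor_gidx = gidx[ai],
    base_base = base_row[di] & base_row[ai],
    stringsAsFactors = FALSE
  )
  out[order(out$donor_gidx, out$acceptor_gidx, out$donor_atom), ]
}

ring_geometry <- function(model, dict = mod_dictionary()) {
  keys <- model_residue_index(model)
  gidx <- residue_gidx(model)
  geo <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    cc <- keys$comp[i]
    rn <- ring_atoms(cc)
    if (is.null(rn)) next
    res <- model[gidx == i, ]
    sel <- match(rn, res$atom)
    if (anyNA(sel)) next
    xyz <- cbind(res$x[sel], res$y[sel], res$z[sel])
    centroid <- colMeans(xyz)
    centered <- sweep(xyz, 2, centroid)
    normal <- svd(centered, nu = 0, nv = 3)$v[, 3]
    geo[[i]] <- list(xyz = xyz, centroid = centroid, normal = normal,
                     saturated = identical(cc, "H2U"))
  }
  list(keys = keys, geo = geo)
}

plane_angle <- function(n1, n2) {
  a <- acos(pmin(1, abs(sum(n1 * n2)))) * 180 / pi
  a
}

#' Detect base-stacking contacts
#'
#' Two bases are reported as stacked when the minimum inter-ring heavy-atom
#' distance is at or below `cutoff`, the angle between base-plane normals is
#' at most `normal_max`, and the ring-centroid separation is at most
#' `centroid_max`.  The saturated H2U base ring is still treated as a ring
#' for this geometry and flagged.
#'
#' @param model Screened atom table.
#' @param cutoff Minimum inter-ring atom distance cutoff, Angstrom.
#' @param normal_max Maximum angle between base-plane normals, degrees.
#' @param centroid_max Maximum centroid-centroid distance, Angstrom.
#' @param dict Modification dictionary.
#' @return data.frame of contacts with geometry fields and residue
#'   references.
#' @export
detect_stacks <- function(model, cutoff = 4.0, normal_max = 30,
                          centroid_max = 5.5, dict = mod_dictionary()) {
  rg <- ring_geometry(model, dict)
  keys <- rg$keys; geo <- rg$geo
  have <- which(!vapply(geo, is.null, logical(1)))
  out <- list()
  if (length(have) >= 2) {
    for (a in seq_along(have)) {
      for (b in seq_len(a - 1L)) {
        i <- have[a]; j <- have[b]
        gi <- geo[[i]]; gj <- geo[[j]]
        cd <- sqrt(sum((gi$centroid - gj$centroid)^2))
        if (cd > centroid_max) next
        na <- plane_angle(gi$normal, gj$normal)
        if (na > normal_max) next
        dmat <- outer(rowSums(gi$xyz^2), rowSums(gj$xyz^2), "+") -
          2 * gi$xyz %*% t(gj$xyz)
        mind <- sqrt(max(0, min(dmat)))
        if (mind > cutoff) next
        out[[length(out) + 1L]] <- data.frame(
          chain_a = keys$chain[j], seq_a = keys$seq[j],
          icode_a = keys$icode[j], comp_a = keys$comp[j],
          chain_b = keys$chain[i], seq_b = keys$seq[i],
          icode_b = keys$icode[i], comp_b = keys$comp[i],
          gidx_a = j, gidx_b = i,
          min_ring_dist = mind, centroid_dist = cd, normal_angle = na,
          saturated = gi$saturated || gj$saturated,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chain_a = character(0), seq_a = integer(0),
                      icode_a = character(0), comp_a = character(0),
                      chain_b = character(0), seq_b = integer(0),
                      icode_b = character(0), comp_b = character(0),
                      gidx_a = integer(0), gidx_b = integer(0),
                      min_ring_dist = numeric(0), centroid_dist = numeric(0),
                      normal_angle = numeric(0), saturated = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$gidx_a, res$gidx_b), ]
}

classify_pair_type <- function(comp_a, comp_b, atoms_a, atoms_b,
                               dict = mod_dictionary()) {
  if ("N7" %in% c(atoms_a, atoms_b)) return("HOOGSTEEN")
  ea <- wcf_edge_atoms(comp_a); eb <- wcf_edge_atoms(comp_b)
  on_wcf <- !is.null(ea) && !is.null(eb) &&
    all(atoms_a %in% ea) && all(atoms_b %in% eb)
  if (!on_wcf) return("OTHER")
  ca <- canonical_parent(comp_a, dict); cb <- canonical_parent(comp_b, dict)
  pair <- paste(sort(c(ca, cb)), collapse = "")
  if (pair %in% c("AU", "CG")) "WCF"
  else if (pair == "GU") "WOBBLE"
  else "OTHER"
}

#' Detect base pairs
#'
#' Residue pairs joined by at least two base-base hydrogen bonds with
#' near-coplanar base planes (inter-plane angle at most `coplanar_max`).
#' Pairs are classified WCF (canonical A:U / G:C donor-acceptor patterns on
#' the Watson-Crick-Franklin edges of both bases), WOBBLE (G:U on the WCF
#' edges), HOOGSTEEN (any bond through the purine N7 edge), or OTHER.
#'
#' @param hbonds Output of [detect_hbonds()].
#' @param model The screened atom table the bonds were computed on.
#' @param coplanar_max Maximum inter-base-plane angle, degrees.
#' @param vertical_max Maximum offset of one base centroid from the other
#'   base's plane, Angstrom; stacked bases (offset near the 3.3-A rise) are
#'   near-coplanar in angle but fail this test, true pairs sit in a common
#'   plane.
#' @param dict Modification dictionary.
#' @return data.frame with residue references (a before b in file order),
#'   `n_hbonds` and `pair_type`.
#' @export
detect_base_pairs <- function(hbonds, model, coplanar_max = 45,
                              vertical_max = 2.5, dict = mod_dictionary()) {
  empty <- data.frame(chain_a = character(0), seq_a = integer(0),
                      icode_a = character(0), comp_a = character(0),
                      chain_b = character(0), seq_b = integer(0),
                      icode_b = character(0), comp_b = character(0),
                      gidx_a = integer(0), gidx_b = integer(0),
                      n_hbonds = integer(0), pair_type = character(0))
  bb <- hbonds[hbonds$base_base, , drop = FALSE]
  if (nrow(bb) == 0) return(empty)
  rg <- ring_geometry(model, dict)
  keys <- rg$keys; geo <- rg$geo
  lo <- pmin(bb$donor_gidx, bb$acceptor_gidx)
  hi <- pmax(bb$donor_gidx, bb$acceptor_gidx)
  pk <- paste(lo, hi)
  out <- list()
  for (key in unique(pk)) {
    sel <- pk == key
    if (sum(sel) < 2) next
    i <- lo[sel][1]; j <- hi[sel][1]
    if (is.null(geo[[i]]) || is.null(geo[[j]])) next
    if (plane_angle(geo[[i]]$normal, geo[[j]]$normal) > coplanar_max) next
    dvec <- geo[[j]]$centroid - geo[[i]]$centroid
    vert <- max(abs(sum(dvec * geo[[i]]$normal)),
                abs(sum(dvec * geo[[j]]$normal)))
    if (vert > vertical_max) next
    atoms_i <- unique(c(bb$donor_atom[sel & bb$donor_gidx == i],
                        bb$acceptor_atom[sel & bb$acceptor_gidx == i]))
    atoms_j <- unique(c(bb$donor_atom[sel & bb$donor_gidx == j],
                        bb$acceptor_atom[sel & bb$acceptor_gidx == j]))
    out[[length(out) + 1L]] <- data.frame(
      chain_a = keys$chain[i], seq_a = keys$seq[i], icode_a = keys$icode[i],
      comp_a = keys$comp[i],
      chain_b = keys$chain[j], seq_b = keys$seq[j], icode_b = keys$icode[j],
      comp_b = keys$comp[j],
      gidx_a = i, gidx_b = j, n_hbonds = sum(sel),
      pair_type = classify_pair_type(keys$comp[i], keys$comp[j],
                                     atoms_i, atoms_j, dict),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$gidx_a, res$gidx_b), ]
}

#' Assign secondary-structure elements
#'
#' Builds helices from runs of two or more consecutive WCF/WOBBLE pairs,
#' resolves pseudoknots by keeping a maximal nested subset of helices (greedy
#' by helix length, ties by 5' position), and labels the enclosed topologies:
#' a maximal unpaired run enclosed by the closing pair of one helix with both
#' strands on one chain is a HAIRPIN (with `loop_size` unpaired residues and
#' that closing pair); regions between two stacked helices are INTERNAL
#' (unpaired residues on both strands) or BULGE (one strand); a helix
#' enclosing two or more child helices is a JUNCTION.  Residues in none of
#' these are left for the MISC bin.
#'
#' @param pairs Output of [detect_base_pairs()].
#' @param model Screened atom table.
#' @return List of SSE records: `sse_type`, `residues` (data.frame of
#'   references), `loop_size`, `closing_pair` (for hairpins), `gidx`.
#' @export
assign_sses <- function(pairs, model) {
  keys <- model_residue_index(model)
  n <- nrow(keys)
  nest <- pairs[pairs$pair_type %in% c("WCF", "WOBBLE"), , drop = FALSE]
  # one partner per residue: keep the pair with most h-bonds
  if (nrow(nest) > 1) {
    nest <- nest[order(-nest$n_hbonds, nest$gidx_a), ]
    used <- logical(n); keep <- logical(nrow(nest))
    for (r in seq_len(nrow(nest))) {
      i <- nest$gidx_a[r]; j <- nest$gidx_b[r]
      if (!used[i] && !used[j]) { keep[r] <- TRUE; used[i] <- used[j] <- TRUE }
    }
    nest <- nest[keep, , drop = FALSE]
    nest <- nest[order(nest$gidx_a), , drop = FALSE]
  }
  # helices: maximal runs of consecutive pairs (i,j),(i+1,j-1),...
  helices <- list()
  if (nrow(nest)) {
    pr <- nest[order(nest$gidx_a), c("gidx_a", "gidx_b")]
    taken <- logical(nrow(pr))
    for (r in seq_len(nrow(pr))) {
      if (taken[r]) next
      run <- r
      repeat {
        last <- run[length(run)]
        nxt <- which(pr$gidx_a == pr$gidx_a[last] + 1 &
                     pr$gidx_b == pr$gidx_b[last] - 1 & !taken)
        if (length(nxt) == 0) break
        run <- c(run, nxt[1]); taken[nxt[1]] <- TRUE
      }
      taken[run] <- TRUE
      if (length(run) >= 2) {
        helices[[length(helices) + 1L]] <- pr[run, , drop = FALSE]
      }
    }
  }
  # pseudoknot resolution: maximal nested subset, greedy by helix length then
  # 5' position
  if (length(helices) > 1) {
    ord <- order(-vapply(helices, nrow, integer(1)),
                 vapply(helices, function(h) min(h$gidx_a), numeric(1)))
    accepted <- list()
    crosses <- function(h1, h2) {
      i <- min(h1$gidx_a); j <- max(h1$gidx_b)
      k <- min(h2$gidx_a); l <- max(h2$gidx_b)
      (i < k && k < j && j < l) || (k < i && i < l && l < j)
    }
    for (h in helices[ord]) {
      if (!any(vapply(accepted, crosses, logical(1), h2 = h))) {
        accepted[[length(accepted) + 1L]] <- h
      }
    }
    helices <- accepted
  }
  paired <- logical(n)
  for (h in helices) paired[c(h$gidx_a, h$gidx_b)] <- TRUE

  sses <- list()
  add_sse <- function(type, gidx, loop_size = NA_integer_,
                      closing_pair = NULL) {
    sses[[length(sses) + 1L]] <<- list(
      sse_type = type,
      residues = keys[gidx, c("chain", "seq", "icode", "comp")],
      gidx = gidx, loop_size = loop_size, closing_pair = closing_pair)
  }
  for (h in helices) add_sse("HELIX", sort(unique(c(h$gidx_a, h$gidx_b))))

  # hairpins: innermost pair of a helix enclosing only unpaired residues on a
  # single chain
  for (h in helices) {
    i <- max(h$gidx_a); j <- min(h$gidx_b)
    if (j - i < 2) next
    span <- (i + 1):(j - 1)
    if (any(paired[span])) next
    if (length(unique(keys$chain[c(i, span, j)])) != 1) next
    add_sse("HAIRPIN", span, loop_size = length(span), closing_pair = c(i, j))
  }

  # regions between stacked helices: internal loops, bulges, junctions
  if (length(helices)) {
    outer_i <- vapply(helices, function(h) min(h$gidx_a), numeric(1))
    outer_j <- vapply(helices, function(h) max(h$gidx_b), numeric(1))
    inner_i <- vapply(helices, function(h) max(h$gidx_a), numeric(1))
    inner_j <- vapply(helices, function(h) min(h$gidx_b), numeric(1))
    for (hx in seq_along(helices)) {
      i <- inner_i[hx]; j <- inner_j[hx]
      children <- setdiff(which(outer_i > i & outer_j < j), hx)
      # direct children only (not nested inside another child)
      if (length(children) > 1) {
        direct <- children[vapply(children, function(c1) {
          !any(outer_i[setdiff(children, c1)] < outer_i[c1] &
               outer_j[setdiff(children, c1)] > outer_j[c1])
        }, logical(1))]
        children <- direct
      }
      if (length(children) == 0) next
      span <- setdiff((i + 1):(j - 1), unlist(lapply(children, function(cx) {
        outer_i[cx]:outer_j[cx]
      })))
      span <- span[!paired[span]]
      if (length(children) >= 2) {
        add_sse("JUNCTION", span)
      } else {
        cx <- children[1]
        left <- span[span < outer_i[cx]]
        right <- span[span > outer_j[cx]]
        if (length(left) && length(right)) add_sse("INTERNAL", span)
        else if (length(left) || length(right)) add_sse("BULGE", span)
      }
    }
  }
  sses
}

#' Per-residue SSE class
#'
#' Maps every residue of a model to the class of the SSE containing it
#' (hairpin-loop membership wins over helix for closing-pair bookkeeping;
#' residues in no SSE are MISC).
#'
#' @param sses Output of [assign_sses()].
#' @param model Screened atom table.
#' @return data.frame chain/seq/icode/comp/sse_class.
#' @export
residue_sse_class <- function(sses, model) {
  keys <- model_residue_index(model)
  cls <- rep("MISC", nrow(keys))
  prec <- c(HELIX = 1, JUNCTION = 2, INTERNAL = 2, BULGE = 2, HAIRPIN = 3)
  rank <- rep(0, nrow(keys))
  for (s in sses) {
    p <- prec[[s$sse_type]] %||% 1
    upd <- s$gidx[rank[s$gidx] < p]
    cls[upd] <- s$sse_type
    rank[upd] <- p
  }
  cbind(keys[, c("chain", "seq", "icode", "comp")],
        data.frame(sse_class = cls, stringsAsFactors = FALSE))
}

#' Annotate a model in one call
#'
#' Runs hydrogen-bond, stacking, base-pair and SSE detection with shared
#' settings.
#'
#' @param model Screened atom table.
#' @param contact_cutoff Distance cutoff for bonds and stacking, Angstrom.
#' @param stack_normal_max,stack_centroid_max Stacking geometry limits.
#' @param coplanar_max Base-pair coplanarity limit, degrees.
#' @param vertical_max Base-pair vertical-offset limit, Angstrom.
#' @param dict Modification dictionary.
#' @return List with `hbonds`, `stacks`, `pairs`, `sses`, `sse_class`.
#' @export
annotate_model <- function(model, contact_cutoff = 4.0,
                           stack_normal_max = 30, stack_centroid_max = 5.5,
                           coplanar_max = 45, vertical_max = 2.5,
                           dict = mod_dictionary()) {
  hb <- detect_hbonds(model, cutoff = contact_cutoff, dict = dict)
  st <- detect_stacks(model, cutoff = contact_cutoff,
                      normal_max = stack_normal_max,
                      centroid_max = stack_centroid_max, dict = dict)
  bp <- detect_base_pairs(hb, model, coplanar_max = coplanar_max,
                          vertical_max = vertical_max, dict = dict)
  ss <- assign_sses(bp, model)
  list(hbonds = hb, stacks = st, pairs = bp, sses = ss,
       sse_class = residue_sse_class(ss, model))
}

#' Read an external annotation report (DSSR-style JSON)
#'
#' Optional cross-check interface: reads the base-pair and hydrogen-bond
#' records of an externally produced JSON annotation (one object with
#' `pairs` and/or `hbonds` arrays, each element carrying `nt1`/`nt2` (or
#' `atom1_id`/`atom2_id`) and a `name`/`distance` field) into data.frames
#' comparable with this package's output.  Never required by the pipeline.
#'
#' @param path Path to the JSON report.
#' @return List with `pairs` and `hbonds` data.frames (either may be empty).
#' @export
read_external_annotation <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("reading external annotation requires the jsonlite package")
  }
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  pairs <- doc[["pairs"]]
  hbonds <- doc[["hbonds"]]
  norm_df <- function(df, cols) {
    if (is.null(df) || !NROW(df)) {
      return(stats::setNames(as.data.frame(replicate(length(cols),
                                                     character(0),
                                                     simplify = FALSE)),
                             cols))
    }
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
    df[, cols]
  }
  list(pairs = norm_df(pairs, c("nt1", "nt2", "name")),
       hbonds = norm_df(hbonds, c("atom1_id", "atom2_id", "distance")))
}
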