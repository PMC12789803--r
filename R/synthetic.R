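# Synthetic structure generator: idealized A-form hairpins with known ground
# truth (pairing, loop size, per-residue pucker and chi, planted
# modifications, NMR-like ensembles, labeled datasets).  All tests and the
# end-to-end survey compare against the manifests produced here, so the
# templates only need to be geometrically self-consistent, not
# crystallographically exact.

unitv <- function(x) x / sqrt(sum(x^2))

rot_z <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# Rodrigues rotation about a unit axis
rot_axis <- function(axis, theta_deg) {
  a <- unitv(axis); t <- theta_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

rotation_between <- function(from, to) {
  f <- unitv(from); t <- unitv(to)
  v <- cross3(f, t); c_ <- sum(f * t)
  if (sqrt(sum(v^2)) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular axis
    p <- if (abs(f[1]) < 0.9) cross3(f, c(1, 0, 0)) else cross3(f, c(0, 1, 0))
    return(rot_axis(p, 180))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * (1 / (1 + c_))
}

element_of <- function(name) {
  core <- gsub("[0-9']", "", name)
  if (core == "") return("X")
  substr(core, 1, 1)
}

# ---------------------------------------------------------------------------
# Planar base templates (z = 0), hexagon side 1.38 A

.hexagon <- function() {
  s <- 1.38
  centre <- c(s, 0, 0)
  ang <- (180 - 60 * (0:5)) * pi / 180
  xyz <- t(vapply(ang, function(a) centre + s * c(cos(a), sin(a), 0),
                  numeric(3)))
  list(xyz = xyz, centre = centre)
}

base_template <- function(comp) {
  hx <- .hexagon()
  centre <- hx$centre
  exo <- function(at, len = 1.23) at + len * unitv(at - centre)
  if (comp %in% c("U", "C")) {
    xyz <- hx$xyz
    rownames(xyz) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    extra <- rbind(O2 = exo(xyz["C2", ]))
    extra <- rbind(extra,
                   if (comp == "U") rbind(O4 = exo(xyz["C4", ], 1.23))
                   else rbind(N4 = exo(xyz["C4", ], 1.34)))
    return(rbind(xyz, extra))
  }
  if (comp %in% c("A", "G")) {
    xyz <- hx$xyz
    rownames(xyz) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    # fuse the five-membered ring on the C4-C5 edge, opposite the hexagon
    # centre
    mid <- (xyz["C4", ] + xyz["C5", ]) / 2
    u <- unitv(mid - centre)
    r5 <- 1.38 / (2 * sin(36 * pi / 180))
    p5 <- mid + r5 * cos(36 * pi / 180) * u
    phi4 <- atan2(xyz["C4", 2] - p5[2], xyz["C4", 1] - p5[1])
    phi5 <- atan2(xyz["C5", 2] - p5[2], xyz["C5", 1] - p5[1])
    step <- phi5 - phi4
    while (step > pi) step <- step - 2 * pi
    while (step < -pi) step <- step + 2 * pi
    at_phi <- function(phi) p5 + r5 * c(cos(phi), sin(phi), 0)
    five <- rbind(N7 = at_phi(phi5 + step), C8 = at_phi(phi5 + 2 * step),
                  N9 = at_phi(phi5 + 3 * step))
    xyz <- rbind(xyz, five)
    extra <- if (comp == "A") rbind(N6 = exo(xyz["C6", ], 1.34))
             else rbind(O6 = exo(xyz["C6", ], 1.23),
                        N2 = exo(xyz["C2", ], 1.34))
    return(rbind(xyz, extra))
  }
  stop("no base template for component ", comp)
}

base_ring_centre <- function(comp, xyz) {
  if (is_purine_comp(comp)) colMeans(xyz[c("N1","C2","N3","C4","C5","C6"), ])
  else colMeans(xyz[c("N1","C2","N3","C4","C5","C6"), ])
}

# unit vector at the glycosidic attach atom pointing away from the base
# (towards where C1' sits)
base_exterior_dir <- function(comp, xyz, attach = NULL) {
  if (is.null(attach)) attach <- if (is_purine_comp(comp)) "N9" else "N1"
  nb <- switch(attach,
               N1 = c("C2", "C6"), N9 = c("C4", "C8"), C5 = c("C4", "C6"))
  a <- xyz[attach, ]
  unitv(-(unitv(xyz[nb[1], ] - a) + unitv(xyz[nb[2], ] - a)))
}

base_normal <- function(xyz) {
  ring <- xyz[intersect(rownames(xyz), c(PYRIMIDINE_RING, PURINE_RING)), ]
  centred <- sweep(ring, 2, colMeans(ring))
  svd(centred, nu = 0, nv = 3)$v[, 3]
}

# ---------------------------------------------------------------------------
# WCF / wobble pair frames, optimized once and cached

.pair_targets <- list(
  AU = list(c("N1", "N3", 2.82), c("N6", "O4", 2.95)),
  UA = list(c("N3", "N1", 2.82), c("O4", "N6", 2.95)),
  GC = list(c("O6", "N4", 2.91), c("N1", "N3", 2.95), c("N2", "O2", 2.86)),
  CG = list(c("N4", "O6", 2.91), c("N3", "N1", 2.95), c("O2", "N2", 2.86)),
  GU = list(c("O6", "N3", 2.83), c("N1", "O2", 2.78)),
  UG = list(c("N3", "O6", 2.83), c("O2", "N1", 2.78))
)

.pair_cache <- new.env(parent = emptyenv())

#' Idealized coplanar base-pair geometry
#'
#' Places the two base templates in a common plane with the pair's canonical
#' hydrogen-bond donor-acceptor distances optimized to standard values
#' (2.8-3.0 A); used as the building block of synthetic A-form stems.
#'
#' @param comp1,comp2 Component codes of the 5' and 3' strand bases; must
#'   form a WCF or wobble pair (A:U, G:C, G:U in either order).
#' @param stretch Additional separation (A) added to every bond target; a
#'   stretched pair is a convenient fixture whose secondary cross-distances
#'   exceed the contact cutoff.
#' @return List with `xyz1`, `xyz2` (named coordinate matrices, z = 0) and
#'   `anchor1`, `anchor2` (the C1' positions implied by the glycosidic
#'   geometry).
#' @export
pair_geometry <- function(comp1, comp2, stretch = 0) {
  key <- paste(comp1, comp2, stretch, sep = "|")
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  tkey <- paste0(canonical_parent(comp1), canonical_parent(comp2))
  targets <- .pair_targets[[tkey]]
  if (is.null(targets)) stop("GENERATION_ERROR: unsupported pair ", tkey)
  b1 <- base_template(comp1)
  b2 <- base_template(comp2)
  at1 <- if (is_purine_comp(comp1)) "N9" else "N1"
  at2 <- if (is_purine_comp(comp2)) "N9" else "N1"
  obj <- function(p, full = TRUE) {
    R <- rot_z(p[1]); t <- c(p[2], p[3], 0)
    b2t <- sweep(b2 %*% t(R), 2, t, "+")
    rownames(b2t) <- rownames(b2)
    v <- sum(vapply(targets, function(tg) {
      d <- sqrt(sum((b1[tg[1], ] - b2t[tg[2], ])^2))
      (d - (as.numeric(tg[3]) + stretch))^2
    }, numeric(1)))
    if (!full) return(v)
    # keep every non-bonded cross-base contact at or beyond van der Waals
    # range so only the intended hydrogen bonds come close
    dd <- sqrt(pmax(outer(rowSums(b1^2), rowSums(b2t^2), "+") -
                      2 * b1 %*% t(b2t), 0))
    dimnames(dd) <- list(rownames(b1), rownames(b2t))
    for (tg in targets) dd[tg[1], tg[2]] <- Inf
    v <- v + 5 * sum(pmax(3.1 - dd, 0)^2)
    # in stretched (fixture) pairs, secondary donor-acceptor contacts are
    # pushed past the detection cutoff so only the intended bonds register
    da_floor <- min(4.1, 3.1 + 1.2 * stretch)
    if (da_floor > 3.1) {
      da12 <- dd[intersect(donor_atoms(comp1), rownames(dd)),
                 intersect(acceptor_atoms(comp2), colnames(dd)),
                 drop = FALSE]
      da21 <- dd[intersect(acceptor_atoms(comp1), rownames(dd)),
                 intersect(donor_atoms(comp2), colnames(dd)),
                 drop = FALSE]
      v <- v + 5 * (sum(pmax(da_floor - da12, 0)^2) +
                    sum(pmax(da_floor - da21, 0)^2))
    }
    v
  }
  best <- NULL
  starts <- expand.grid(th = seq(0, 330, by = 30),
                        tx = c(-12, -9, -6, -3), ty = c(-5, 0, 5))
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[s, ]), obj,
                        control = list(maxit = 1500, reltol = 1e-13))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-8) break
  }
  # accept hydrogen-bond lengths within ~0.08 A of target in the clash-free
  # arrangement
  if (obj(best$par, full = FALSE) > 0.02) {
    stop("GENERATION_ERROR: pair optimization failed for ", tkey)
  }
  R <- rot_z(best$par[1]); t <- c(best$par[2], best$par[3], 0)
  xyz2 <- sweep(b2 %*% t(R), 2, t, "+")
  rownames(xyz2) <- rownames(b2)
  e1 <- base_exterior_dir(comp1, b1)
  e2 <- base_exterior_dir(comp2, xyz2)
  at1 <- if (is_purine_comp(comp1)) "N9" else "N1"
  at2 <- if (is_purine_comp(comp2)) "N9" else "N1"
  q1 <- b1[at1, ] + 1.48 * e1
  q2 <- xyz2[at2, ] + 1.48 * e2
  # normalize the frame: C1' anchors on the x axis, centred at the origin
  mid <- (q1 + q2) / 2
  xax <- unitv(q1 - q2)
  ang <- atan2(xax[2], xax[1]) * 180 / pi
  Rn <- rot_z(-ang)
  xyz1 <- sweep(b1, 2, mid) %*% t(Rn)
  xyz2 <- sweep(xyz2, 2, mid) %*% t(Rn)
  rownames(xyz1) <- rownames(b1)
  out <- list(xyz1 = xyz1, xyz2 = xyz2,
              anchor1 = as.numeric((q1 - mid) %*% t(Rn)),
              anchor2 = as.numeric((q2 - mid) %*% t(Rn)))
  .pair_cache[[key]] <- out
  out
}

#' Two-residue base-only fixture of an idealized pair
#'
#' @inheritParams pair_geometry
#' @param chain Chain identifier.
#' @return An atom table with the two bases (base atoms only).
#' @export
ideal_pair_model <- function(comp1, comp2, stretch = 0, chain = "A") {
  pg <- pair_geometry(comp1, comp2, stretch)
  mk <- function(xyz, comp, seqno) {
    data.frame(chain = chain, seq = seqno, icode = "", comp = comp,
               atom = rownames(xyz),
               element = vapply(rownames(xyz), element_of, character(1)),
               alt = "", occ = 1, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(mk(pg$xyz1, comp1, 1L), mk(pg$xyz2, comp2, 2L))
}

# ---------------------------------------------------------------------------
# Sugar ring with exact pseudorotation state

.sugar_cache <- new.env(parent = emptyenv())

ring_from_pucker <- function(P, nu_max) {
  key <- sprintf("%.6f|%.6f", P, nu_max)
  if (!is.null(.sugar_cache[[key]])) return(.sugar_cache[[key]])
  r <- 1.22
  build <- function(phase, amp) {
    k <- 0:4
    ang <- (90 - 72 * k) * pi / 180
    xyz <- cbind(r * cos(ang), r * sin(ang),
                 amp * cos((phase + 144 * k) * pi / 180))
    rownames(xyz) <- RING5_ATOMS
    xyz
  }
  measure <- function(phase, amp) {
    xyz <- build(phase, amp)
    res <- data.frame(atom = rownames(xyz), x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
    ps <- pseudorotation(sugar_torsions(res))
    ps
  }
  wrap180 <- function(a) ((a + 180) %% 360) - 180
  amp <- max(nu_max, 5) / 90  # rough initial scale (radians-ish)
  # locate the phase giving the requested P on a coarse grid, then polish
  grid <- seq(0, 359, by = 15)
  errs <- vapply(grid, function(g) abs(wrap180(measure(g, amp)$P - P)),
                 numeric(1))
  phase <- grid[which.min(errs)]
  for (it in 1:60) {
    m <- measure(phase, amp)
    dP <- wrap180(P - m$P)
    damp <- if (m$nu_max > 1e-9) nu_max / m$nu_max else 1
    slope <- wrap180(measure(phase + 1, amp)$P - m$P)
    if (abs(slope) < 1e-3) slope <- sign(slope + 1e-9)
    phase <- phase + dP / slope
    amp <- amp * damp
    if (abs(dP) < 1e-9 && abs(damp - 1) < 1e-9) break
  }
  out <- build(phase, amp)
  .sugar_cache[[key]] <- out
  out
}

# full sugar + backbone fragment in local coordinates, C1' at the origin;
# attribute "base_dir" is the unit vector from C1' towards the base
sugar_template <- function(P = 18, nu_max = 38) {
  ring <- ring_from_pucker(P, nu_max)
  ring <- sweep(ring, 2, ring["C1'", ])
  centred <- sweep(ring, 2, colMeans(ring))
  n <- svd(centred, nu = 0, nv = 3)$v[, 3]
  if (n[3] < 0) n <- -n
  exo_dir <- function(at, up, alpha = 55) {
    nb <- RING5_ATOMS[(match(at, RING5_ATOMS) + c(-2, 0)) %% 5 + 1]
    a <- ring[at, ]
    e0 <- -(unitv(ring[nb[1], ] - a) + unitv(ring[nb[2], ] - a))
    e_in <- e0 - sum(e0 * n) * n
    if (sqrt(sum(e_in^2)) < 1e-9) e_in <- e0
    e_in <- unitv(e_in)
    unitv(cos(alpha * pi / 180) * e_in +
          (if (up) 1 else -1) * sin(alpha * pi / 180) * n)
  }
  base_dir <- exo_dir("C1'", up = TRUE)
  o2p <- ring["C2'", ] + 1.41 * exo_dir("C2'", up = FALSE)
  o3p <- ring["C3'", ] + 1.42 * exo_dir("C3'", up = FALSE)
  c5p <- ring["C4'", ] + 1.51 * exo_dir("C4'", up = TRUE)
  d1 <- unitv(c5p - ring["C4'", ])
  o5p <- c5p + 1.42 * unitv(d1 + 0.9 * n)
  p <- o5p + 1.60 * unitv(o5p - c5p + 0.6 * n)
  axis <- unitv(p - o5p)
  u <- unitv(cross3(axis, if (abs(axis[1]) < 0.9) c(1, 0, 0)
                          else c(0, 1, 0)))
  v <- cross3(axis, u)
  op1 <- p + 1.48 * unitv(0.35 * axis + 0.94 * u)
  op2 <- p + 1.48 * unitv(0.35 * axis - 0.47 * u + 0.81 * v)
  xyz <- rbind(ring, `O2'` = o2p, `O3'` = o3p, `C5'` = c5p, `O5'` = o5p,
               P = p, OP1 = op1, OP2 = op2)
  attr(xyz, "base_dir") <- base_dir
  xyz
}

# place a full nucleotide: the base is already in global coordinates, the
# sugar/backbone is attached through the glycosidic bond with the requested
# pucker and chi
place_nucleotide <- function(comp, base_xyz, P = 18, nu_max = 38,
                             chi = -158, attach = NULL,
                             dict = mod_dictionary()) {
  if (is.null(attach)) attach <- if (is_purine_comp(comp)) "N9" else "N1"
  ext <- base_exterior_dir(comp, base_xyz, attach)
  A <- base_xyz[attach, ]
  c1_target <- A + 1.48 * ext
  sug <- sugar_template(P, nu_max)
  R0 <- rotation_between(attr(sug, "base_dir"), -ext)
  xyz <- sweep(sug %*% t(R0), 2, c1_target, "+")
  rownames(xyz) <- rownames(sug)
  chi_atoms_v <- chi_atoms(comp, dict)
  res_df <- function(sxyz) {
    all <- rbind(sxyz, base_xyz)
    data.frame(atom = rownames(all), x = all[, 1], y = all[, 2],
               z = all[, 3], stringsAsFactors = FALSE)
  }
  cur <- torsion_angle(xyz["O4'", ], xyz["C1'", ],
                       base_xyz[chi_atoms_v[3], ], base_xyz[chi_atoms_v[4], ])
  axis <- unitv(A - c1_target)
  # empirical rotation sense: probe a one-degree turn of the sugar
  probe <- sweep(sweep(xyz, 2, c1_target) %*% t(rot_axis(axis, 1)), 2,
                 c1_target, "+")
  rownames(probe) <- rownames(xyz)
  cur2 <- torsion_angle(probe["O4'", ], probe["C1'", ],
                        base_xyz[chi_atoms_v[3], ],
                        base_xyz[chi_atoms_v[4], ])
  wrap180 <- function(a) ((a + 180) %% 360) - 180
  slope <- wrap180(cur2 - cur)
  delta <- wrap180(chi - cur) / slope
  xyz <- sweep(sweep(xyz, 2, c1_target) %*% t(rot_axis(axis, delta)), 2,
               c1_target, "+")
  rownames(xyz) <- rownames(sug)
  all <- rbind(xyz, base_xyz)
  data.frame(atom = rownames(all),
             element = vapply(rownames(all), element_of, character(1)),
             x = all[, 1], y = all[, 2], z = all[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---------------------------------------------------------------------------
# Hairpin construction

revcomp_rna <- function(s) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

#' Generator specification for one synthetic hairpin
#'
#' @param stem_seq 5' strand of the stem (>= 2 nt); the 3' strand is its
#'   reverse complement.
#' @param loop_seq Loop sequence, 4-10 nt.
#' @param modifications data.frame with columns `position` (1-based in the
#'   full sequence) and `comp_id` (dictionary code); targets must be U.
#' @param pucker Optional data.frame `position`, `P`, `nu_max` overriding the
#'   default C3'-endo (P = 18, nu_max = 38) at those positions.
#' @param chi Optional data.frame `position`, `chi` overriding the default
#'   anti (-158).
#' @param entry_id,chain,start_seq_num Identifiers for the emitted entry.
#' @param method,resolution,molecule_description,organism Entry metadata.
#' @param n_models,noise_sigma,seed Ensemble settings: `n_models` Gaussian
#'   perturbed copies at `noise_sigma` (A); the planted representative (see
#'   [make_ensemble()]) gets sigma/10.
#' @param loop_tilt_deg Tilt of the loop-arc plane away from the helix axis;
#'   a conformational dial used to plant structurally distinct counterparts.
#' @param rise,twist A-form helical rise (A) and twist (degrees) of the stem.
#' @param spacing Loop C1'-C1' spacing along the arc (A).
#' @return A `hairpin_spec` list.
#' @export
hairpin_spec <- function(stem_seq = "GG", loop_seq = "UUCAAAG",
                         modifications = NULL, pucker = NULL, chi = NULL,
                         entry_id = "SYN1", chain = "A", start_seq_num = 1L,
                         method = "XRAY", resolution = 2.0,
                         molecule_description = "synthetic RNA hairpin",
                         organism = NA_character_,
                         n_models = 1L, noise_sigma = 0, seed = 1L,
                         loop_tilt_deg = 0, rise = 2.81, twist = 32.7,
                         spacing = 5.9) {
  spec <- list(stem_seq = stem_seq, loop_seq = loop_seq,
               modifications = modifications, pucker = pucker, chi = chi,
               entry_id = entry_id, chain = chain,
               start_seq_num = as.integer(start_seq_num), method = method,
               resolution = resolution,
               molecule_description = molecule_description,
               organism = organism, n_models = as.integer(n_models),
               noise_sigma = noise_sigma, seed = as.integer(seed),
               loop_tilt_deg = loop_tilt_deg, rise = rise, twist = twist,
               spacing = spacing)
  class(spec) <- "hairpin_spec"
  spec
}

#' Build a synthetic hairpin with known ground truth
#'
#' Constructs an idealized hairpin: an A-form stem of WCF pairs (standard
#' hydrogen-bond distances, C3'-endo sugars, anti bases) and a loop laid out
#' on a smooth arc with outward-pointing bases, then applies the requested
#' modifications, per-position pucker/chi overrides, coordinate noise and
#' ensemble expansion.  The manifest records the ground truth (pairing, loop
#' size, per-residue conformational classes, modifications, planted ensemble
#' representative); conformational classes are measured on the coordinates
#' as emitted (after noise, on the planted representative model, at the
#' serialized 3-decimal precision), so the manifest is exact for the files
#' a pipeline run will read.
#'
#' @param spec A [hairpin_spec()].
#' @param dict Modification dictionary.
#' @return List with `entry` (a `structure_entry`) and `manifest`.
#' @export
build_hairpin <- function(spec, dict = mod_dictionary()) {
  S <- nchar(spec$stem_seq); L <- nchar(spec$loop_seq)
  if (S < 2) stop("GENERATION_ERROR: stem must have >= 2 pairs")
  if (L < 2) stop("GENERATION_ERROR: loop too short to close a hairpin")
  full_seq <- paste0(spec$stem_seq, spec$loop_seq, revcomp_rna(spec$stem_seq))
  ch <- strsplit(full_seq, "")[[1]]
  N <- length(ch)
  get_pucker <- function(pos) {
    if (!is.null(spec$pucker)) {
      i <- match(pos, spec$pucker$position)
      if (!is.na(i)) return(c(spec$pucker$P[i], spec$pucker$nu_max[i]))
    }
    c(18, 38)
  }
  get_chi <- function(pos) {
    if (!is.null(spec$chi)) {
      i <- match(pos, spec$chi$position)
      if (!is.na(i)) return(spec$chi$chi[i])
    }
    -158
  }
  bases <- vector("list", N)
  for (i in seq_len(S)) {
    j <- N + 1 - i
    pg <- pair_geometry(ch[i], ch[j])
    R <- rot_z(spec$twist * (i - 1))
    shift <- c(0, 0, spec$rise * (i - 1))
    bases[[i]] <- sweep(pg$xyz1 %*% t(R), 2, shift, "+")
    bases[[j]] <- sweep(pg$xyz2 %*% t(R), 2, shift, "+")
    rownames(bases[[i]]) <- rownames(pg$xyz1)
    rownames(bases[[j]]) <- rownames(pg$xyz2)
  }
  # C1' anchors of the innermost pair, from the glycosidic geometry
  anchor_of <- function(pos) {
    comp <- ch[pos]
    at <- if (is_purine_comp(comp)) "N9" else "N1"
    bases[[pos]][at, ] + 1.48 * base_exterior_dir(comp, bases[[pos]], at)
  }
  a1 <- anchor_of(S); a2 <- anchor_of(S + L + 1)
  chord <- sqrt(sum((a2 - a1)^2))
  ratio <- chord / ((L + 1) * spec$spacing)
  if (ratio >= 1) stop("GENERATION_ERROR: loop too short for stem separation")
  half <- stats::uniroot(function(x) sin(x) / x - ratio,
                         c(1e-6, pi - 1e-6))$root
  alpha <- 2 * half
  Rarc <- chord / (2 * sin(half))
  u <- unitv(a2 - a1)
  zax <- c(0, 0, 1)
  up <- unitv(zax - sum(zax * u) * u)
  if (spec$loop_tilt_deg != 0) {
    up <- as.numeric(rot_axis(u, spec$loop_tilt_deg) %*% up)
  }
  centre <- (a1 + a2) / 2 - Rarc * cos(half) * up
  beta1 <- atan2(sum((a1 - centre) * up), sum((a1 - centre) * u))
  beta2 <- atan2(sum((a2 - centre) * up), sum((a2 - centre) * u))
  sweep_ang <- beta2 - beta1
  # traverse the arc over the top (through the +up direction)
  mid_ang <- pi / 2
  contains_top <- function(b1, d) {
    tt <- (mid_ang - b1) / d
    tt > 0 && tt < 1
  }
  if (!contains_top(beta1, sweep_ang)) {
    sweep_ang <- sweep_ang - sign(sweep_ang) * 2 * pi
  }
  for (k in seq_len(L)) {
    pos <- S + k
    phi <- beta1 + sweep_ang * k / (L + 1)
    v <- centre + Rarc * (cos(phi) * u + sin(phi) * up)
    w <- unitv(Rarc * (cos(phi) * u + sin(phi) * up))
    tang <- unitv(-sin(phi) * u + cos(phi) * up) * sign(sweep_ang)
    comp <- ch[pos]
    tmpl <- base_template(comp)
    at <- if (is_purine_comp(comp)) "N9" else "N1"
    e_t <- base_exterior_dir(comp, tmpl, at)
    # map (template exterior, template normal) -> (-w, tangent)
    b1v <- e_t; b2v <- c(0, 0, 1); b3v <- cross3(b1v, b2v)
    t1v <- -w; t2v <- tang; t3v <- cross3(t1v, t2v)
    B <- cbind(b1v, b2v, b3v); Tm <- cbind(t1v, t2v, t3v)
    R <- Tm %*% solve(B)
    xyz <- tmpl %*% t(R)
    rownames(xyz) <- rownames(tmpl)
    A_target <- v + 1.48 * w
    xyz <- sweep(xyz, 2, A_target - xyz[at, ], "+")
    bases[[pos]] <- xyz
  }
  rows <- vector("list", N)
  for (pos in seq_len(N)) {
    pk <- get_pucker(pos)
    res <- place_nucleotide(ch[pos], bases[[pos]], P = pk[1], nu_max = pk[2],
                            chi = get_chi(pos), dict = dict)
    rows[[pos]] <- cbind(data.frame(chain = spec$chain,
                                    seq = spec$start_seq_num + pos - 1L,
                                    icode = "", comp = ch[pos],
                                    stringsAsFactors = FALSE),
                         res[, c("atom", "element")],
                         data.frame(alt = "", occ = 1),
                         res[, c("x", "y", "z")])
  }
  model <- do.call(rbind, rows)
  rownames(model) <- NULL
  mods <- spec$modifications
  if (!is.null(mods) && nrow(mods)) {
    for (r in seq_len(nrow(mods))) {
      model <- apply_modification_model(model, mods$position[r],
                                        mods$comp_id[r], dict)
    }
  }
  conf <- NULL  # filled in from the emitted coordinates below
  pairing <- data.frame(pos_a = seq_len(S), pos_b = N - seq_len(S) + 1L)
  fill_conformation <- function(m) {
    cf <- conformation_table(m, dict)
    cf$position <- seq_len(N)
    cf[, c("position", "chain", "seq", "comp_id", "P", "nu_max",
           "pucker_class", "chi", "chi_class")]
  }
  manifest <- list(
    entry_id = spec$entry_id, chain = spec$chain,
    sequence = paste(display_char(model_comp_sequence(model), dict),
                     collapse = ""),
    start_seq_num = spec$start_seq_num,
    stem_bp = S, loop_size = L, n_residues = N,
    hairpin_span = c(S, N - S + 1L),
    clip_length = L + 2L,
    pairing = pairing,
    conformation = conf,
    modifications = if (is.null(mods)) {
      data.frame(position = integer(0), comp_id = character(0))
    } else mods,
    method = spec$method, resolution = spec$resolution,
    noise_sigma = spec$noise_sigma, n_models = spec$n_models,
    representative = NA_integer_
  )
  res_na <- if (spec$method %in% c("NMR", "OTHER")) NA_real_
            else spec$resolution
  entry <- structure_entry(spec$entry_id, spec$method, res_na, list(model),
                           molecule_descriptions = stats::setNames(
                             spec$molecule_description, spec$chain),
                           organism = spec$organism)
  if (spec$n_models > 1) {
    planted <- max(1L, min(spec$n_models, 3L))
    entry <- make_ensemble(entry, spec$n_models, spec$noise_sigma,
                           seed = spec$seed, planted_representative = planted)
    manifest$representative <- planted
  } else if (spec$noise_sigma > 0) {
    entry$models[[1]] <- perturb_model(entry$models[[1]], spec$noise_sigma,
                                       spec$seed)
  }
  # ground truth is stated for the emitted coordinates: the (possibly
  # perturbed) single model, or the planted representative of an ensemble
  truth_model <- if (spec$n_models > 1) {
    entry$models[[manifest$representative]]
  } else {
    entry$models[[1]]
  }
  # state the truth for the coordinates as serialized (3 decimals)
  truth_model$x <- round(truth_model$x, 3)
  truth_model$y <- round(truth_model$y, 3)
  truth_model$z <- round(truth_model$z, 3)
  manifest$conformation <- fill_conformation(truth_model)
  list(entry = entry, manifest = manifest)
}

model_comp_sequence <- function(model) {
  residue_keys(model)$comp
}

perturb_model <- function(model, sigma, seed) {
  set.seed(seed)
  n <- nrow(model)
  model$x <- model$x + stats::rnorm(n, 0, sigma)
  model$y <- model$y + stats::rnorm(n, 0, sigma)
  model$z <- model$z + stats::rnorm(n, 0, sigma)
  model
}

apply_modification_model <- function(model, position, comp_id,
                                     dict = mod_dictionary()) {
  gidx <- residue_gidx(model)
  sel <- gidx == position
  if (!any(sel)) stop("no residue at position ", position)
  res <- model[sel, ]
  if (res$comp[1] != "U") {
    stop("modification target at position ", position, " is ", res$comp[1],
         ", not U")
  }
  xyz <- as.matrix(res[, c("x", "y", "z")])
  rownames(xyz) <- res$atom
  ring6 <- xyz[PYRIMIDINE_RING, ]
  centre <- colMeans(ring6)
  nrm <- {
    cc <- sweep(ring6, 2, centre)
    svd(cc, nu = 0, nv = 3)$v[, 3]
  }
  add_atom <- function(res, name, pos, element) {
    newrow <- res[1, ]
    newrow$atom <- name; newrow$element <- element
    newrow$x <- pos[1]; newrow$y <- pos[2]; newrow$z <- pos[3]
    rbind(res, newrow)
  }
  if (comp_id == "PSU") {
    # isomerization: rotate the base 180 degrees about the N3-C6 axis so C5
    # takes up the old glycosidic position; atom names travel with the atoms
    axis <- unitv(xyz["C6", ] - xyz["N3", ])
    Rm <- rot_axis(axis, 180)
    origin <- xyz["N3", ]
    bsel <- res$atom %in% base_atoms("U")
    b <- as.matrix(res[bsel, c("x", "y", "z")])
    b <- sweep(sweep(b, 2, origin) %*% t(Rm), 2, origin, "+")
    res[bsel, c("x", "y", "z")] <- b
  } else if (comp_id == "5MU") {
    res <- add_atom(res, "C5M", xyz["C5", ] + 1.50 * unitv(xyz["C5", ] -
                                                           centre), "C")
  } else if (comp_id == "UR3") {
    res <- add_atom(res, "C3U", xyz["N3", ] + 1.47 * unitv(xyz["N3", ] -
                                                           centre), "C")
  } else if (comp_id == "OMU") {
    res <- add_atom(res, "CM2", xyz["O2'", ] + 1.43 * unitv(xyz["O2'", ] -
                                                            xyz["C2'", ]),
                    "C")
  } else if (comp_id == "4SU") {
    i <- which(res$atom == "O4")
    pos <- xyz["C4", ] + 1.68 * unitv(xyz["O4", ] - xyz["C4", ])
    res$atom[i] <- "S4"; res$element[i] <- "S"
    res$x[i] <- pos[1]; res$y[i] <- pos[2]; res$z[i] <- pos[3]
  } else if (comp_id == "H2U") {
    # saturate C5=C6: pucker the two carbons out of the base plane
    for (nm in c("C5", "C6")) {
      i <- which(res$atom == nm)
      d <- if (nm == "C5") 0.25 else -0.25
      res$x[i] <- res$x[i] + d * nrm[1]
      res$y[i] <- res$y[i] + d * nrm[2]
      res$z[i] <- res$z[i] + d * nrm[3]
    }
  } else {
    stop("unknown modification ", comp_id)
  }
  res$comp <- comp_id
  out <- rbind(model[gidx < position, ], res, model[gidx > position, ])
  rownames(out) <- NULL
  out
}

#' Apply a uridine modification to a built structure
#'
#' Edits residue `position` (1-based residue index) of every model:
#' pseudouridine rotates the base 180 degrees about the N3-C6 axis
#' (re-attaching it through C1'-C5 with atom names preserved); 5MU/UR3/OMU
#' add their methyl carbon (C5M on C5, C3U on N3, CM2 on O2'); 4SU replaces
#' O4 by S4 at a 1.68 A C=S bond; H2U puckers C5/C6 out of the base plane.
#'
#' @param entry A `structure_entry` (or a bare atom table).
#' @param position 1-based residue index.
#' @param comp_id Modification code.
#' @param dict Modification dictionary.
#' @return The modified entry (or atom table).
#' @export
apply_modification <- function(entry, position, comp_id,
                               dict = mod_dictionary()) {
  if (!inherits(entry, "structure_entry")) {
    return(apply_modification_model(entry, position, comp_id, dict))
  }
  entry$models <- lapply(entry$models, apply_modification_model,
                         position = position, comp_id = comp_id, dict = dict)
  entry
}

#' Expand an entry into an NMR-like ensemble
#'
#' Each model is the base coordinates plus i.i.d. Gaussian noise of standard
#' deviation `noise_sigma`; the planted representative receives sigma/10 so
#' that representative recovery is unambiguous.
#'
#' @param entry A single-model `structure_entry`.
#' @param n_models Number of models.
#' @param noise_sigma Noise level, Angstrom.
#' @param seed RNG seed.
#' @param planted_representative Index of the low-noise model.
#' @return An NMR `structure_entry` with `n_models` models and attribute
#'   `planted_representative`.
#' @export
make_ensemble <- function(entry, n_models, noise_sigma, seed = 1L,
                          planted_representative = 1L) {
  base <- entry$models[[1]]
  set.seed(seed)
  models <- lapply(seq_len(n_models), function(k) {
    s <- if (k == planted_representative) noise_sigma / 10 else noise_sigma
    m <- base
    n <- nrow(m)
    m$x <- m$x + stats::rnorm(n, 0, s)
    m$y <- m$y + stats::rnorm(n, 0, s)
    m$z <- m$z + stats::rnorm(n, 0, s)
    m
  })
  out <- structure_entry(entry$entry_id, "NMR", NA_real_, models,
                         molecule_descriptions = entry$molecule_descriptions,
                         organism = entry$organism)
  attr(out, "planted_representative") <- planted_representative
  out
}

# ---------------------------------------------------------------------------
# Labeled toy corpora

#' Default synthetic study specification
#'
#' Describes a toy survey corpus covering all six uridine modifications:
#' per modification, three X-ray entries sharing one hairpin sequence (an
#' SRS group), one cryo-EM and one NMR-ensemble entry of a second sequence,
#' one entry deliberately failing the 3.0 A resolution filter and one with a
#' deliberately incomplete residue (clip failure); pseudouridine and
#' 5-methyluridine additionally contribute an entry with the modification on
#' a paired stem uridine.  The library side carries two unmodified
#' counterpart conformers for each first-sequence family (for 4-thiouridine
#' in a deliberately shifted loop conformation, planting a structurally
#' distinct pair) plus unrelated decoys.
#'
#' @return List of data.frames `modified` and `library` consumed by
#'   [generate_dataset()].
#' @export
default_study_spec <- function() {
  mods <- c("PSU", "5MU", "UR3", "OMU", "4SU", "H2U")
  prefix <- c(PSU = "P", `5MU` = "T", UR3 = "R", OMU = "O", `4SU` = "S",
              H2U = "H")
  loop_a <- c(PSU = "AUCAAGA", `5MU` = "GUUCAAG", UR3 = "GUAAC",
              OMU = "AAUCC", `4SU` = "CAUAGA", H2U = "AGUGGAAC")
  loop_b <- c(PSU = "AUCAAGAA", `5MU` = "GUUCAAGA", UR3 = "GUAAAC",
              OMU = "AAUACC", `4SU` = "CAUAGAA", H2U = "AGUGGAACA")
  loop_pos <- c(PSU = 2, `5MU` = 3, UR3 = 2, OMU = 3, `4SU` = 3, H2U = 3)
  rna_desc <- c(PSU = "transfer RNA", `5MU` = "23S ribosomal RNA",
                UR3 = "16S ribosomal RNA", OMU = "messenger RNA",
                `4SU` = "transfer RNA", H2U = "transfer RNA")
  rows <- list(); lib <- list()
  for (m in mods) {
    px <- prefix[[m]]
    # conformational plants at the modified residue
    p_target <- if (m %in% c("UR3", "H2U")) 162 else 18  # C2'-endo vs C3'-endo
    mk <- function(id, loop, method, resolution, n_models = 1,
                   noise = 0.05, defect = "", chi = -158, pucker = p_target,
                   desc = rna_desc[[m]], stem = "GG", stem_mod = FALSE) {
      data.frame(entry_id = paste0(px, id), comp_id = m, stem_seq = stem,
                 loop_seq = loop,
                 mod_position = if (stem_mod) 2L
                                else nchar(stem) + loop_pos[[m]],
                 method = method, resolution = resolution,
                 n_models = n_models, noise_sigma = noise,
                 defect = defect, chi = chi, pucker_P = pucker,
                 molecule_description = desc, loop_tilt = 0,
                 stringsAsFactors = FALSE)
    }
    rows[[m]] <- rbind(
      mk("A01", loop_a[[m]], "XRAY", 2.0),
      mk("A02", loop_a[[m]], "XRAY", 2.5,
         chi = if (m == "PSU") 55 else -158),
      mk("A03", loop_a[[m]], "XRAY", 2.9,
         pucker = if (m == "5MU") 126 else p_target),
      mk("B01", loop_b[[m]], "EM", 2.8,
         desc = if (m == "OMU") "synthetic construct" else rna_desc[[m]]),
      mk("B02", loop_b[[m]], "NMR", NA_real_, n_models = 5, noise = 0.3,
         chi = if (m == "H2U") 50 else -158),
      mk("X01", loop_a[[m]], "XRAY", 3.5, defect = "RESOLUTION"),
      mk("D01", loop_a[[m]], "XRAY", 2.2, defect = "MISSING_ATOM")
    )
    if (m %in% c("PSU", "5MU")) {
      rows[[m]] <- rbind(rows[[m]],
                         mk("C01", "GAAA", "XRAY", 2.4, stem = "GUG",
                            stem_mod = TRUE, pucker = 18))
    }
    lib[[m]] <- data.frame(
      entry_id = paste0("L", px, c("01", "02")),
      stem_seq = "GG", loop_seq = loop_a[[m]],
      resolution = c(1.9, 2.1),
      loop_tilt = if (m == "4SU") 25 else 0,
      stringsAsFactors = FALSE)
  }
  lib$decoy <- data.frame(entry_id = c("LZ01", "LZ02"), stem_seq = "GG",
                          loop_seq = c("GCGAAA", "ACCGAAU"),
                          resolution = c(2.0, 2.3), loop_tilt = 0,
                          stringsAsFactors = FALSE)
  list(modified = do.call(rbind, rows), library = do.call(rbind, lib))
}

#' Generate a labeled synthetic corpus on disk
#'
#' Emits the study specification as mmCIF files under `dir/modified` and
#' `dir/library`, with per-entry method/resolution metadata, planted filter
#' failures and defects, and returns a ground-truth manifest: per-entry
#' expectations (kept or exclusion reason), per-modified-residue
#' conformational classes and SSE membership, and the expected comparison
#' outcomes.
#'
#' @param dir Output directory (created).
#' @param seed Master seed; per-entry seeds are derived from it.
#' @param spec A [default_study_spec()]-shaped specification.
#' @param dict Modification dictionary.
#' @return The manifest: list with `entries`, `residues`, `comparisons`.
#' @export
generate_dataset <- function(dir, seed = 1L, spec = default_study_spec(),
                             dict = mod_dictionary()) {
  mod_dir <- file.path(dir, "modified")
  lib_dir <- file.path(dir, "library")
  dir.create(mod_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(lib_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list(); residues <- list()
  for (i in seq_len(nrow(spec$modified))) {
    e <- spec$modified[i, ]
    S <- nchar(e$stem_seq)
    hs <- hairpin_spec(
      stem_seq = e$stem_seq, loop_seq = e$loop_seq,
      modifications = data.frame(position = e$mod_position,
                                 comp_id = e$comp_id,
                                 stringsAsFactors = FALSE),
      pucker = data.frame(position = e$mod_position, P = e$pucker_P,
                          nu_max = 38),
      chi = data.frame(position = e$mod_position, chi = e$chi),
      entry_id = e$entry_id, method = e$method, resolution = e$resolution,
      molecule_description = e$molecule_description,
      n_models = e$n_models, noise_sigma = e$noise_sigma,
      seed = (seed * 1000L + i) %% .Machine$integer.max)
    bh <- build_hairpin(hs, dict)
    entry <- bh$entry; mf <- bh$manifest
    if (identical(e$defect, "MISSING_ATOM")) {
      # drop O2' from the first (unmodified) loop residue in every model
      drop_seq <- S + 1L
      entry$models <- lapply(entry$models, function(mm) {
        mm[!(mm$seq == drop_seq & mm$atom == "O2'"), ]
      })
    }
    path <- file.path(mod_dir, paste0(e$entry_id, ".cif"))
    write_structure_cif(entry, path)
    expected <- if (identical(e$defect, "RESOLUTION")) "RESOLUTION"
                else if (identical(e$defect, "MISSING_ATOM")) "CLIP_FAIL"
                else "kept"
    in_loop <- e$mod_position > S &&
      e$mod_position <= S + nchar(e$loop_seq)
    cf <- mf$conformation[mf$conformation$position == e$mod_position, ]
    entries[[length(entries) + 1L]] <- data.frame(
      entry_id = e$entry_id, role = "modified", comp_id = e$comp_id,
      file = path, method = e$method, resolution = e$resolution,
      n_models = e$n_models, representative = mf$representative,
      sequence = mf$sequence, loop_size = mf$loop_size,
      expected = expected, stringsAsFactors = FALSE)
    if (expected == "kept") {
      residues[[length(residues) + 1L]] <- data.frame(
        entry_id = e$entry_id, comp_id = e$comp_id,
        seq = e$mod_position, method = e$method,
        sse_class = if (in_loop) "HAIRPIN" else "HELIX",
        pucker_class = cf$pucker_class, chi_class = cf$chi_class,
        rna_type = if (grepl("ribosomal", e$molecule_description)) "rRNA"
                   else if (grepl("transfer", e$molecule_description)) "tRNA"
                   else if (grepl("messenger", e$molecule_description)) "mRNA"
                   else if (grepl("synthetic", e$molecule_description))
                     "synthetic"
                   else "other",
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(spec$library))) {
    e <- spec$library[i, ]
    # a non-zero loop tilt marks a deliberately shifted conformer; the tilt
    # is combined with syn flips of two mid-loop bases so the planted
    # conformational difference clearly exceeds the similarity threshold
    distort_chi <- NULL
    if (e$loop_tilt != 0) {
      S <- nchar(e$stem_seq)
      distort_chi <- data.frame(position = S + c(2L, 3L), chi = c(30, 30))
    }
    hs <- hairpin_spec(
      stem_seq = e$stem_seq, loop_seq = e$loop_seq,
      entry_id = e$entry_id, method = "XRAY", resolution = e$resolution,
      molecule_description = "ribosomal RNA", noise_sigma = 0.05,
      loop_tilt_deg = e$loop_tilt, chi = distort_chi,
      seed = (seed * 1000L + 500L + i) %% .Machine$integer.max)
    bh <- build_hairpin(hs, dict)
    path <- file.path(lib_dir, paste0(e$entry_id, ".cif"))
    write_structure_cif(bh$entry, path)
    entries[[length(entries) + 1L]] <- data.frame(
      entry_id = e$entry_id, role = "library", comp_id = "",
      file = path, method = "XRAY", resolution = e$resolution,
      n_models = 1L, representative = NA_integer_,
      sequence = bh$manifest$sequence, loop_size = bh$manifest$loop_size,
      expected = "kept", stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, entries)
  residues <- do.call(rbind, residues)
  # expected comparison outcomes: one pair per modification's first-sequence
  # family (its canonical sequence has library counterparts); the planted
  # loop tilt of the 4SU library makes that single pair distinct
  mods <- unique(spec$modified$comp_id)
  comparisons <- do.call(rbind, lapply(mods, function(m) {
    first <- spec$modified[spec$modified$comp_id == m, ][1, ]
    S <- nchar(first$stem_seq)
    closer <- substr(first$stem_seq, S, S)
    data.frame(comp_id = m,
               canonical = paste0(closer, first$loop_seq,
                                  revcomp_rna(closer)),
               expect_similar = !identical(m, "4SU"),
               stringsAsFactors = FALSE)
  }))
  list(entries = entries, residues = residues, comparisons = comparisons,
       modified_dir = mod_dir, library_dir = lib_dir)
}
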