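# Sugar-pucker pseudorotation analysis and glycosidic-angle classification.

#' Canonical pseudorotation pucker classes
#'
#' Ten envelope/twist classes at 36-degree intervals of the pseudorotation
#' phase, starting at C3'-endo (ideal phase 18 degrees).  Class boundaries lie
#' halfway between ideal phases, i.e. each class owns a 36-degree-wide bin.
#' @export
PUCKER_CLASSES <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                    "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

.SIN36_72 <- sin(36 * pi / 180) + sin(72 * pi / 180)

#' Pseudorotation phase and amplitude from ring torsions
#'
#' Altona-Sundaralingam analysis of the five ribose ring torsions
#' nu0 (C4'-O4'-C1'-C2') through nu4 (C3'-C4'-O4'-C1').  For torsions of the
#' exact closed form nu_j = nu_max * cos(P + 144 * (j - 2)) the phase and
#' amplitude are recovered exactly.
#'
#' @param nu Numeric length-5 vector of ring torsions in degrees (nu0..nu4).
#' @return List with `P` (degrees in [0, 360)) and `nu_max` (degrees, >= 0).
#' @export
#' @examples
#' nu <- pseudorotation_torsions(18, 40)
#' pseudorotation(nu)  # P = 18, nu_max = 40
pseudorotation <- function(nu) {
  stopifnot(length(nu) == 5)
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * .SIN36_72
  if (abs(num) < 1e-12 && abs(den) < 1e-12) {
    return(list(P = 0, nu_max = 0))
  }
  P <- atan2(num, den) * 180 / pi
  if (P < 0) P <- P + 360
  nu_max <- sqrt(nu[3]^2 + (num / (2 * .SIN36_72))^2)
  list(P = P, nu_max = nu_max)
}

#' @rdname pseudorotation
#' @param P Pseudorotation phase in degrees.
#' @param nu_max Puckering amplitude in degrees.
#' @return For `pseudorotation_torsions`: the five torsions of the closed
#'   form, nu_j = nu_max * cos(P + 144 * (j - 2)).
#' @export
pseudorotation_torsions <- function(P, nu_max) {
  j <- 0:4
  nu_max * cos((P + 144 * (j - 2)) * pi / 180)
}

#' Pucker class from phase and amplitude
#'
#' Nearest-ideal-phase assignment over the ten canonical classes (36-degree
#' bins); amplitudes below `amplitude_floor` (essentially planar rings) are
#' reported as "UNSPECIFIED".
#'
#' @param P Phase in degrees.
#' @param nu_max Amplitude in degrees.
#' @param amplitude_floor Minimum classifiable amplitude, degrees.
#' @return A pucker class string.
#' @export
pucker_class_of <- function(P, nu_max, amplitude_floor = 5) {
  if (is.na(P) || is.na(nu_max) || nu_max < amplitude_floor) {
    return("UNSPECIFIED")
  }
  P <- P %% 360
  PUCKER_CLASSES[(floor(P / 36) %% 10) + 1]
}

#' syn/anti classification rule for a glycosidic angle
#'
#' syn for chi in [-90, +90] (boundary inclusive on both sides), anti
#' outside, "unspecified" for NA.
#'
#' @param chi Glycosidic angle in degrees, or NA.
#' @return "syn", "anti" or "unspecified".
#' @export
chi_class_of <- function(chi) {
  if (is.na(chi)) return("unspecified")
  if (abs(chi) <= 90) "syn" else "anti"
}

residue_atom_xyz <- function(residue, name) {
  i <- match(name, residue$atom)
  if (is.na(i)) return(NULL)
  as.numeric(c(residue$x[i], residue$y[i], residue$z[i]))
}

#' Ribose ring torsions of a residue
#'
#' @param residue A residue atom table (rows of one residue) with columns
#'   `atom`, `x`, `y`, `z`.
#' @return Numeric length-5 vector nu0..nu4 (degrees).
#' @export
sugar_torsions <- function(residue) {
  ring <- lapply(RING5_ATOMS, residue_atom_xyz, residue = residue)
  if (any(vapply(ring, is.null, logical(1)))) {
    stop("MISSING_ATOMS: ribose ring incomplete")
  }
  names(ring) <- RING5_ATOMS
  # nu_j is the torsion about the bond ring[j+1]-ring[j+2] (cyclic)
  idx <- rbind(c(5, 1, 2, 3),   # nu0: C4'-O4'-C1'-C2'
               c(1, 2, 3, 4),   # nu1: O4'-C1'-C2'-C3'
               c(2, 3, 4, 5),   # nu2: C1'-C2'-C3'-C4'
               c(3, 4, 5, 1),   # nu3: C2'-C3'-C4'-O4'
               c(4, 5, 1, 2))   # nu4: C3'-C4'-O4'-C1'
  vapply(seq_len(5), function(j) {
    torsion_angle(ring[[idx[j, 1]]], ring[[idx[j, 2]]],
                  ring[[idx[j, 3]]], ring[[idx[j, 4]]])
  }, numeric(1))
}

#' Sugar-pucker call for a residue
#'
#' @inheritParams sugar_torsions
#' @param amplitude_floor Minimum amplitude (degrees) for a classifiable
#'   pucker; planar or near-planar rings are "UNSPECIFIED".
#' @return List with `P`, `nu_max`, `pucker_class`.
#' @export
pseudorotation_pucker <- function(residue, amplitude_floor = 5) {
  nu <- sugar_torsions(residue)
  ps <- pseudorotation(nu)
  list(P = ps$P, nu_max = ps$nu_max,
       pucker_class = pucker_class_of(ps$P, ps$nu_max, amplitude_floor))
}

#' Glycosidic angle chi and syn/anti class
#'
#' chi is the torsion over O4'-C1' and the component's glycosidic bond
#' (N1-C2 for pyrimidines, N9-C4 for purines, C5-C4 for the pseudouridine
#' C-glycoside).  syn conformations have chi between -90 and +90 degrees
#' (boundary inclusive); anti conformations fall outside that range.  When a
#' chi atom is missing the angle is NA and the class "unspecified".
#'
#' @param residue Residue atom table with a `comp` column (or pass `comp_id`).
#' @param comp_id Component code; defaults to the residue's `comp` value.
#' @param dict Modification dictionary.
#' @return List with `chi` (degrees or NA), `chi_class`
#'   ("syn"/"anti"/"unspecified") and `chi_atoms` used.
#' @export
chi_angle <- function(residue, comp_id = NULL, dict = mod_dictionary()) {
  if (is.null(comp_id)) comp_id <- residue$comp[1]
  atoms <- chi_atoms(comp_id, dict)
  if (is.null(atoms)) {
    return(list(chi = NA_real_, chi_class = "unspecified", chi_atoms = NULL))
  }
  pts <- lapply(atoms, residue_atom_xyz, residue = residue)
  if (any(vapply(pts, is.null, logical(1)))) {
    return(list(chi = NA_real_, chi_class = "unspecified", chi_atoms = atoms))
  }
  chi <- torsion_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  list(chi = chi, chi_class = chi_class_of(chi), chi_atoms = atoms)
}

#' Full conformational call for one residue
#'
#' Combines [pseudorotation_pucker()] and [chi_angle()].
#'
#' @inheritParams chi_angle
#' @param amplitude_floor Passed to [pseudorotation_pucker()].
#' @return One-row data.frame: comp_id, P, nu_max, pucker_class, chi,
#'   chi_class.
#' @export
conformation_call <- function(residue, comp_id = NULL,
                              dict = mod_dictionary(), amplitude_floor = 5) {
  if (is.null(comp_id)) comp_id <- residue$comp[1]
  pk <- tryCatch(pseudorotation_pucker(residue, amplitude_floor),
                 error = function(e) list(P = NA_real_, nu_max = NA_real_,
                                          pucker_class = "UNSPECIFIED"))
  ch <- chi_angle(residue, comp_id, dict)
  data.frame(comp_id = comp_id, P = pk$P, nu_max = pk$nu_max,
             pucker_class = pk$pucker_class, chi = ch$chi,
             chi_class = ch$chi_class, stringsAsFactors = FALSE)
}

#' Per-residue conformation table for a model
#'
#' @param model An atom table (one model) with columns `chain`, `seq`,
#'   `icode`, `comp`, `atom`, `x`, `y`, `z`.
#' @param dict Modification dictionary.
#' @param amplitude_floor Passed to [pseudorotation_pucker()].
#' @param only_comps Optional component filter (e.g. dictionary codes only).
#' @return data.frame with one row per residue: chain, seq, comp_id, P,
#'   nu_max, pucker_class, chi, chi_class.
#' @export
conformation_table <- function(model, dict = mod_dictionary(),
                               amplitude_floor = 5, only_comps = NULL) {
  keys <- unique(model[, c("chain", "seq", "icode", "comp")])
  if (!is.null(only_comps)) keys <- keys[keys$comp %in% only_comps, ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    res <- model[model$chain == k$chain & model$seq == k$seq &
                 model$icode == k$icode, ]
    cc <- conformation_call(res, k$comp, dict, amplitude_floor)
    cbind(data.frame(chain = k$chain, seq = k$seq, icode = k$icode,
                     stringsAsFactors = FALSE), cc)
  })
  do.call(rbind, rows)
}
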