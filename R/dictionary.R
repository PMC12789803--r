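# Component dictionary: heavy-atom content, donor/acceptor chemistry and
# glycosidic-bond topology for the four canonical ribonucleotides and the six
# uridine modifications surveyed by the package.

SUGAR_BACKBONE_ATOMS <- c(
  "P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
  "C3'", "O3'", "C2'", "O2'", "C1'"
)

RING5_ATOMS <- c("O4'", "C1'", "C2'", "C3'", "C4'")

PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")
PURINE_RING <- c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6")

.BASE_ATOMS <- list(
  A   = c(PURINE_RING, "N6"),
  G   = c(PURINE_RING, "N2", "O6"),
  C   = c(PYRIMIDINE_RING, "O2", "N4"),
  U   = c(PYRIMIDINE_RING, "O2", "O4"),
  PSU = c(PYRIMIDINE_RING, "O2", "O4"),
  `5MU` = c(PYRIMIDINE_RING, "O2", "O4", "C5M"),
  UR3 = c(PYRIMIDINE_RING, "O2", "O4", "C3U"),
  OMU = c(PYRIMIDINE_RING, "O2", "O4"),
  `4SU` = c("N1", "C2", "N3", "C4", "C5", "C6", "O2", "S4"),
  H2U = c(PYRIMIDINE_RING, "O2", "O4")
)

# OMU carries the 2'-O-methyl carbon on the sugar side.
.EXTRA_SUGAR_ATOMS <- list(OMU = "CM2")

# Base-side hydrogen-bond donors (heavy atoms bearing a polar H) and
# acceptors.  N3 of UR3 is methylated and so not a donor; the free N1 of
# pseudouridine is its hallmark extra donor.
.BASE_DONORS <- list(
  A = "N6", G = c("N1", "N2"), C = "N4", U = "N3",
  PSU = c("N1", "N3"), `5MU` = "N3", UR3 = character(0),
  OMU = "N3", `4SU` = "N3", H2U = "N3"
)
.BASE_ACCEPTORS <- list(
  A = c("N1", "N3", "N7"), G = c("N3", "O6", "N7"),
  C = c("O2", "N3"), U = c("O2", "O4"),
  PSU = c("O2", "O4"), `5MU` = c("O2", "O4"), UR3 = c("O2", "O4"),
  OMU = c("O2", "O4"), `4SU` = c("O2", "S4"), H2U = c("O2", "O4")
)

# Watson-Crick-Franklin edge atoms, used to classify detected base pairs.
.WCF_EDGE <- list(
  A = c("N1", "N6"), G = c("N1", "N2", "O6"), C = c("N3", "O2", "N4"),
  U = c("N3", "O2", "O4"), PSU = c("N3", "O2", "O4"),
  `5MU` = c("N3", "O2", "O4"), UR3 = c("O2", "O4"),
  OMU = c("N3", "O2", "O4"), `4SU` = c("N3", "O2", "S4"),
  H2U = c("N3", "O2", "O4")
)

#' Modification dictionary
#'
#' The six uridine modifications surveyed by the package, keyed by their
#' 3-character chemical-component codes, together with their canonical parent,
#' the single display character used in motif sequences, the modification
#' class, and the two base-side atoms that close the glycosidic torsion chi.
#' Pseudouridine is a C-glycoside (C1'-C5 bond), so its chi is measured over
#' O4'-C1'-C5-C4; all other uridine modifications keep the pyrimidine
#' N1-glycosidic linkage.
#'
#' @param path Optional path to an editable tab-separated dictionary with
#'   columns \code{comp_id}, \code{canonical}, \code{display_char},
#'   \code{mod_class}, \code{gly_atom1}, \code{gly_atom2}.  When \code{NULL}
#'   the built-in table is returned.
#' @return A data.frame with one row per modified component.
#' @export
#' @examples
#' mod_dictionary()
mod_dictionary <- function(path = NULL) {
  if (!is.null(path)) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
    need <- c("comp_id", "canonical", "display_char", "mod_class",
              "gly_atom1", "gly_atom2")
    if (!all(need %in% names(d))) {
      stop("dictionary file must have columns: ", paste(need, collapse = ", "))
    }
    return(d[, need])
  }
  data.frame(
    comp_id      = c("PSU", "5MU", "UR3", "OMU", "4SU", "H2U"),
    canonical    = "U",
    display_char = c("P", "t", "u", "u", "u", "u"),
    mod_class    = c("BASE", "BASE", "BASE", "SUGAR", "BASE", "BASE"),
    gly_atom1    = c("C5", "N1", "N1", "N1", "N1", "N1"),
    gly_atom2    = c("C4", "C2", "C2", "C2", "C2", "C2"),
    stringsAsFactors = FALSE
  )
}

#' Write the modification dictionary as an editable TSV
#'
#' @param dict A dictionary data.frame as returned by [mod_dictionary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mod_dictionary <- function(dict, path) {
  utils::write.table(dict, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname mod_dictionary
#' @param comp_id A component code.
#' @param dict A modification dictionary.
#' @export
is_modified_comp <- function(comp_id, dict = mod_dictionary()) {
  comp_id %in% dict$comp_id
}

known_components <- function(dict = mod_dictionary()) {
  c("A", "C", "G", "U", dict$comp_id)
}

#' Reference heavy atoms for a component
#'
#' The complete heavy-atom name set a screened residue of the component must
#' carry (the residue-quality screen rejects residues missing any of these).
#'
#' @param comp_id Component code (canonical A/C/G/U or a dictionary code).
#' @param phosphate Include the 5'-phosphate group (P, OP1, OP2)?  Chain-first
#'   residues of deposited structures often lack it.
#' @return Character vector of atom names, or `NULL` for unknown components.
#' @export
component_atoms <- function(comp_id, phosphate = TRUE) {
  base <- .BASE_ATOMS[[comp_id]]
  if (is.null(base)) return(NULL)
  sug <- SUGAR_BACKBONE_ATOMS
  if (!phosphate) sug <- setdiff(sug, c("P", "OP1", "OP2"))
  extra <- .EXTRA_SUGAR_ATOMS[[comp_id]]
  c(sug, extra, base)
}

base_atoms <- function(comp_id) .BASE_ATOMS[[comp_id]]

#' @rdname component_atoms
#' @export
ring_atoms <- function(comp_id) {
  if (comp_id %in% c("A", "G")) PURINE_RING
  else if (comp_id %in% names(.BASE_ATOMS)) PYRIMIDINE_RING
  else NULL
}

is_purine_comp <- function(comp_id) comp_id %in% c("A", "G")

#' Hydrogen-bond donor and acceptor atoms of a component
#'
#' Donors are heavy atoms carrying a polar hydrogen (the screen removes H
#' atoms, so the distance-only bond test runs on heavy atoms).  The sugar O2'
#' is a donor except when methylated (OMU); backbone phosphate and ester
#' oxygens are acceptors.
#'
#' @param comp_id Component code.
#' @return Character vector of atom names.
#' @export
donor_atoms <- function(comp_id) {
  b <- .BASE_DONORS[[comp_id]]
  if (is.null(b)) return(character(0))
  sugar <- if (identical(comp_id, "OMU")) character(0) else "O2'"
  c(b, sugar)
}

#' @rdname donor_atoms
#' @export
acceptor_atoms <- function(comp_id) {
  b <- .BASE_ACCEPTORS[[comp_id]]
  if (is.null(b)) return(character(0))
  c(b, "O2'", "O4'", "O3'", "O5'", "OP1", "OP2")
}

wcf_edge_atoms <- function(comp_id) .WCF_EDGE[[comp_id]]

#' Glycosidic torsion atoms for a component
#'
#' Returns the four chi atoms in order O4', C1', then the two base-side atoms
#' (N1-C2 for pyrimidines, N9-C4 for purines, C5-C4 for the pseudouridine
#' C-glycoside).
#'
#' @param comp_id Component code.
#' @param dict Modification dictionary.
#' @return Character vector of four atom names, or `NULL` if unknown.
#' @export
chi_atoms <- function(comp_id, dict = mod_dictionary()) {
  if (comp_id %in% dict$comp_id) {
    r <- dict[dict$comp_id == comp_id, ]
    return(c("O4'", "C1'", r$gly_atom1, r$gly_atom2))
  }
  if (comp_id %in% c("A", "G")) return(c("O4'", "C1'", "N9", "C4"))
  if (comp_id %in% c("C", "U")) return(c("O4'", "C1'", "N1", "C2"))
  NULL
}

# The base-side atom the sugar C1' bonds to.
glycosidic_attach_atom <- function(comp_id, dict = mod_dictionary()) {
  chi_atoms(comp_id, dict)[3]
}

#' Display character for a component in motif sequences
#'
#' Canonical components map to their upper-case letter; modified components to
#' their dictionary display character (P for pseudouridine, t for
#' 5-methyluridine, u for the remaining uridine modifications).
#'
#' @param comp_id Component code(s).
#' @param dict Modification dictionary.
#' @return Character vector of single characters ("?" for unknown codes).
#' @export
display_char <- function(comp_id, dict = mod_dictionary()) {
  vapply(comp_id, function(cc) {
    if (cc %in% c("A", "C", "G", "U")) return(cc)
    i <- match(cc, dict$comp_id)
    if (is.na(i)) "?" else dict$display_char[i]
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical parent of a component
#'
#' @param comp_id Component code(s).
#' @param dict Modification dictionary.
#' @return One of "A","C","G","U" per element, or NA for unknown codes.
#' @export
canonical_parent <- function(comp_id, dict = mod_dictionary()) {
  vapply(comp_id, function(cc) {
    if (cc %in% c("A", "C", "G", "U")) return(cc)
    i <- match(cc, dict$comp_id)
    if (is.na(i)) NA_character_ else dict$canonical[i]
  }, character(1), USE.NAMES = FALSE)
}
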