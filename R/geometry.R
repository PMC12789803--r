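# Numeric kernel: torsion angles, Kabsch superposition, RMSD, iterative mean
# coordinates and representative-by-mean selection.

#' Signed torsion (dihedral) angle
#'
#' IUPAC convention: the angle is 0 for a cis (eclipsed) arrangement and
#' positive clockwise when looking from p2 towards p3.  Result lies in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @export
#' @examples
#' torsion_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))  # 0 (cis)
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("UNDEFINED_TORSION: collinear points")
  }
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2u)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Labelled coordinate set
#'
#' A thin container pairing an n x 3 coordinate matrix with unique atom
#' labels; the unit of correspondence for superposition and averaging.
#'
#' @param coords Numeric matrix, n rows x 3 columns (Angstrom).
#' @param labels Character vector of unique labels, one per row.
#' @return An object of class `coordinate_set`.
#' @export
coordinate_set <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(coords)))
  if (length(labels) != nrow(coords)) stop("labels must match coords rows")
  if (anyDuplicated(labels)) stop("labels must be unique")
  structure(list(labels = as.character(labels), coords = unname(coords)),
            class = "coordinate_set")
}

as_coordinate_set <- function(x) {
  if (inherits(x, "coordinate_set")) x else coordinate_set(x)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `reference`,
#' computed by singular value decomposition of the cross-covariance matrix
#' with the usual sign correction so that reflections are excluded
#' (det(rotation) = +1; chirality of nucleic acids is preserved).
#'
#' @param mobile,reference `coordinate_set` objects (or bare n x 3 matrices)
#'   with identical label sequences; n >= 3 non-collinear points.
#' @return A `superposition`: list with `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (Angstrom) and `n_atoms`.  The transform maps a
#'   coordinate row x to `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as_coordinate_set(mobile)
  reference <- as_coordinate_set(reference)
  if (!identical(mobile$labels, reference$labels)) {
    stop("CORRESPONDENCE_ERROR: label sequences differ")
  }
  M <- mobile$coords; R <- reference$coords
  n <- nrow(M)
  if (n < 3) stop("TOO_FEW_ATOMS: need >= 3 paired atoms")
  cm <- colMeans(M); cr <- colMeans(R)
  Mc <- sweep(M, 2, cm); Rc <- sweep(R, 2, cr)
  H <- t(Mc) %*% Rc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Mc %*% t(rot)
  rmsd <- sqrt(sum((fitted - Rc)^2) / n)
  structure(list(rotation = rot,
                 translation = as.numeric(cr - as.numeric(cm %*% t(rot))),
                 rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#'
#' @param sp A `superposition` from [kabsch_superpose()].
#' @param coords An n x 3 matrix or `coordinate_set`.
#' @return Transformed coordinates in the same form as the input.
#' @export
apply_superposition <- function(sp, coords) {
  if (inherits(coords, "coordinate_set")) {
    coords$coords <- apply_superposition(sp, coords$coords)
    return(coords)
  }
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d atoms, RMSD %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Iterative mean structure of an ensemble
#'
#' All members are superposed onto the current mean (initially member 1), the
#' per-atom arithmetic mean is recomputed, and the cycle repeats until the
#' mean moves less than `tol` (maximum per-atom displacement) or `max_iter`
#' cycles have run.
#'
#' @param members List of `coordinate_set`s sharing labels.
#' @param tol Convergence tolerance in Angstrom.
#' @param max_iter Maximum iterations.
#' @return A `coordinate_set` holding the converged mean, with attributes
#'   `converged` (logical) and `iterations`.
#' @export
mean_coordinates <- function(members, tol = 1e-4, max_iter = 20) {
  stopifnot(length(members) >= 1)
  members <- lapply(members, as_coordinate_set)
  labs <- members[[1]]$labels
  for (m in members) {
    if (!identical(m$labels, labs)) {
      stop("CORRESPONDENCE_ERROR: members do not share labels")
    }
  }
  mean_xyz <- members[[1]]$coords
  if (length(members) == 1) {
    out <- coordinate_set(mean_xyz, labs)
    attr(out, "converged") <- TRUE; attr(out, "iterations") <- 1L
    return(out)
  }
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ref <- coordinate_set(mean_xyz, labs)
    fitted <- lapply(members, function(m) {
      apply_superposition(kabsch_superpose(m, ref), m$coords)
    })
    new_mean <- Reduce(`+`, fitted) / length(fitted)
    shift <- max(sqrt(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("mean_coordinates did not converge in ", max_iter, " iterations")
  }
  out <- coordinate_set(mean_xyz, labs)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}

#' Representative member closest to the ensemble mean
#'
#' Computes the iterative mean of the ensemble, superposes every member onto
#' it, and returns the member with the lowest all-atom RMSD to the mean.
#' Ties (within 1e-9 A) go to the lowest index.
#'
#' @param members List of `coordinate_set`s sharing labels.
#' @param tol,max_iter Passed to [mean_coordinates()].
#' @return List with `index` (1-based), `rmsd` (per-member RMSD-to-mean
#'   vector) and `mean` (the mean `coordinate_set`).
#' @export
representative_to_mean <- function(members, tol = 1e-4, max_iter = 20) {
  stopifnot(length(members) >= 1)
  members <- lapply(members, as_coordinate_set)
  mn <- mean_coordinates(members, tol = tol, max_iter = max_iter)
  rmsds <- vapply(members, function(m) kabsch_superpose(m, mn)$rmsd,
                  numeric(1))
  best <- which(rmsds <= min(rmsds) + 1e-9)[1]
  list(index = best, rmsd = rmsds, mean = mn)
}
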