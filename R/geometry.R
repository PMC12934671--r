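# Torsion angles, Ramachandran regions, rotamer bins, distances and the
# virtual C-beta construction.  All angles are in degrees in (-180, 180];
# all distances in Angstroms.  Criteria are heavy-atom based throughout.

.deg <- function(x) x * 180 / pi
.rad <- function(x) x * pi / 180

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-10) stop("degenerate geometry: zero-length vector", call. = FALSE)
  v / n
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle about the p2--p3 bond with the IUPAC sign
#' convention: looking from p2 to p3, a clockwise rotation of p4 relative
#' to p1 is positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstroms).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-8 || sqrt(sum(b2^2)) < 1e-8 || sqrt(sum(b3^2)) < 1e-8)
    stop("degenerate geometry: coincident consecutive points", call. = FALSE)
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-8 || sqrt(sum(n2^2)) < 1e-8)
    stop("degenerate geometry: colinear points", call. = FALSE)
  m1 <- .cross3(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- -sum(m1 * n2)
  ang <- .deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Ramachandran region of a (phi, psi) pair
#'
#' Broad-region labels used by the active-kinase criteria:
#' \itemize{
#'   \item \code{A} (alpha): phi in (-180, 0), psi in (-100, 50]
#'   \item \code{B} (beta):  phi in (-180, 0), psi in (50, 180]
#'   \item \code{L} (left-handed): phi in (0, 180], psi in (-50, 100]
#'   \item \code{other}: any other finite pair
#'   \item \code{none}: phi or psi not available
#' }
#' The published intervals are open; to obtain a deterministic partition we
#' close A at psi = 50 (A owns the A/B boundary), close B at psi = 180 with
#' psi = -180 wrapped to 180, and close L at phi = 180 and psi = 100.
#'
#' @param phi,psi Backbone dihedrals in degrees.
#' @return One of \code{"A"}, \code{"B"}, \code{"L"}, \code{"other"},
#'   \code{"none"}.
#' @export
rama_region <- function(phi, psi) {
  if (is.null(phi) || is.null(psi) || is.na(phi) || is.na(psi)) return("none")
  if (!is.finite(phi) || !is.finite(psi)) return("none")
  # psi wraparound: -180 is the same backbone state as +180
  if (psi <= -180) psi <- psi + 360
  if (phi > -180 && phi < 0) {
    if (psi > -100 && psi <= 50) return("A")
    if (psi > 50 && psi <= 180) return("B")
    return("other")
  }
  if (phi > 0 && phi <= 180) {
    if (psi > -50 && psi <= 100) return("L")
    return("other")
  }
  # phi == -180 or phi == 0 exactly: outside every named region
  "other"
}

#' Gauche-minus test for a chi1 rotamer
#'
#' TRUE iff chi1 lies in the open interval (-120, 0).
#'
#' @param chi1 Side-chain chi1 dihedral in degrees (may be NA).
#' @return Logical, or NA when chi1 is unavailable.
#' @export
chi1_minus <- function(chi1) {
  if (is.null(chi1) || is.na(chi1)) return(NA)
  is.finite(chi1) && chi1 > -120 && chi1 < 0
}

#' Rotamer bin name for chi1
#'
#' minus = (-120, 0), plus = (0, 120), trans = remainder.
#' @param chi1 degrees; NA allowed.
#' @return "minus", "plus", "trans" or NA.
#' @export
chi1_bin <- function(chi1) {
  if (is.null(chi1) || is.na(chi1)) return(NA_character_)
  if (chi1 > -120 && chi1 < 0) return("minus")
  if (chi1 > 0 && chi1 < 120) return("plus")
  "trans"
}

#' Minimum pairwise distance between two atom sets
#'
#' @param atoms_a,atoms_b Numeric matrices with 3 columns (one atom per
#'   row).  A single 3-vector is also accepted.
#' @return The minimum Euclidean distance, or \code{NA_real_} when either
#'   set is empty (missing atoms propagate as criterion state "none").
#' @export
min_pair_distance <- function(atoms_a, atoms_b) {
  atoms_a <- .as_coord_matrix(atoms_a)
  atoms_b <- .as_coord_matrix(atoms_b)
  if (is.null(atoms_a) || is.null(atoms_b) ||
      nrow(atoms_a) == 0L || nrow(atoms_b) == 0L) return(NA_real_)
  d2 <- outer(rowSums(atoms_a^2), rowSums(atoms_b^2), "+") -
    2 * tcrossprod(atoms_a, atoms_b)
  sqrt(max(min(d2), 0))
}

.as_coord_matrix <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) return(x)
  if (is.numeric(x) && length(x) == 3L) return(matrix(x, nrow = 1L))
  if (is.data.frame(x)) return(as.matrix(x[, c("x", "y", "z")]))
  NULL
}

#' Ideal virtual C-beta position from a backbone triad
#'
#' Reconstructs the C-beta an L-amino acid would have, given backbone N,
#' CA and C.  Used when a glycine occupies a position whose criterion is
#' C-beta based (APE10/11/12).  Uses the standard tetrahedral construction
#' with a 1.53 A bond.
#'
#' @param n,ca,c Numeric 3-vectors of the backbone N, CA, C positions.
#' @return 3-vector: the virtual C-beta position.
#' @export
virtual_cbeta <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  if (sqrt(sum(b^2)) < 1e-8 || sqrt(sum(cc^2)) < 1e-8)
    stop("degenerate backbone triad", call. = FALSE)
  a <- .cross3(b, cc)
  # coefficients give the canonical pseudo-CB used for contact analysis
  ca + (-0.58273431 * a + 0.56802827 * b - 0.54067466 * cc)
}

# gamma-atom priority for chi1 (N-CA-CB-Xgamma)
.CHI1_GAMMA <- c("OG", "OG1", "CG", "CG1", "SG")

#' @keywords internal
.euclid <- function(a, b) sqrt(sum((a - b)^2))
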