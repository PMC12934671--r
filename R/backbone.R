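# Backbone and side-chain dihedrals of residues inside a StructureModel.
# Sequence neighbors only count when the peptide bond actually exists
# (C-N distance < 1.8 A), so chain breaks and satellite residues never
# produce spurious dihedrals.

.PEPTIDE_BOND_MAX <- 1.8

# neighbor residue numbers present in the chain, ordered
#' @keywords internal
.chain_resnos <- function(model, chain) {
  a <- model$atoms
  sort(unique(a$resno[a$chain == chain & !a$hetero]))
}

#' @keywords internal
.prev_resno <- function(model, chain, resno) {
  rs <- .chain_resnos(model, chain)
  rs <- rs[rs < resno]
  if (!length(rs)) return(NULL)
  max(rs)
}

#' @keywords internal
.next_resno <- function(model, chain, resno) {
  rs <- .chain_resnos(model, chain)
  rs <- rs[rs > resno]
  if (!length(rs)) return(NULL)
  min(rs)
}

#' Backbone phi/psi and side-chain chi1 of one residue
#'
#' phi needs the preceding residue's C and psi the following residue's N;
#' both are only used when bonded (C-N < 1.8 A).  chi1 is the
#' N-CA-CB-gamma torsion with the standard gamma-atom priority
#' (OG, OG1, CG, CG1, SG); Gly and Ala have no chi1.
#'
#' @param model StructureModel.
#' @param chain Chain id.
#' @param resno Residue number.
#' @return list(phi, psi, chi1) in degrees; NA where not computable.
#' @export
residue_dihedrals <- function(model, chain, resno) {
  n  <- atom_xyz(model, chain, resno, "N")
  ca <- atom_xyz(model, chain, resno, "CA")
  c_ <- atom_xyz(model, chain, resno, "C")
  phi <- psi <- chi1 <- NA_real_
  if (!is.null(n) && !is.null(ca) && !is.null(c_)) {
    pr <- .prev_resno(model, chain, resno)
    if (!is.null(pr)) {
      cp <- atom_xyz(model, chain, pr, "C")
      if (!is.null(cp) && .euclid(cp, n) < .PEPTIDE_BOND_MAX)
        phi <- dihedral(cp, n, ca, c_)
    }
    nx <- .next_resno(model, chain, resno)
    if (!is.null(nx)) {
      nn <- atom_xyz(model, chain, nx, "N")
      if (!is.null(nn) && .euclid(c_, nn) < .PEPTIDE_BOND_MAX)
        psi <- dihedral(n, ca, c_, nn)
    }
    cb <- atom_xyz(model, chain, resno, "CB")
    if (!is.null(cb)) {
      rt <- res_table(model, chain, resno)
      g <- .CHI1_GAMMA[.CHI1_GAMMA %in% rt$elety][1]
      if (!is.na(g)) {
        gx <- atom_xyz(model, chain, resno, g)
        chi1 <- dihedral(n, ca, cb, gx)
      }
    }
  }
  list(phi = phi, psi = psi, chi1 = chi1)
}

#' Ramachandran region of one residue
#' @inheritParams residue_dihedrals
#' @return Region label (see \code{\link{rama_region}}).
#' @export
residue_region <- function(model, chain, resno) {
  d <- residue_dihedrals(model, chain, resno)
  rama_region(d$phi, d$psi)
}

# C-beta of a residue, reconstructing a virtual one from the backbone
# when absent (Gly)
#' @keywords internal
.cbeta_or_virtual <- function(model, chain, resno) {
  cb <- atom_xyz(model, chain, resno, "CB")
  if (!is.null(cb)) return(cb)
  n  <- atom_xyz(model, chain, resno, "N")
  ca <- atom_xyz(model, chain, resno, "CA")
  c_ <- atom_xyz(model, chain, resno, "C")
  if (is.null(n) || is.null(ca) || is.null(c_)) return(NULL)
  virtual_cbeta(n, ca, c_)
}
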