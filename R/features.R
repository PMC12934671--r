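# The six criterion states and the 26 underlying structural features for
# one kinase chain.
#
# Criterion summary (defaults; all bounds strict):
#   spatial   DFGin: Phe anchor <= 11 A from Glu4-Ca and >= 11 A from Lys-Ca
#   dihedral  XDF regions (B, L, A) + Phe chi1 gauche-minus  ==  BLAminus
#   saltbr    min(Lys-Nz to Glu-Oe1/Oe2) < 3.6 A
#   hrd       His region A and Arg region L (skipped without alphaF-Asp)
#   actloopNT min backbone N-O distance DFG6/XHRD < 3.6 A
#   actloopCT APE7/6 (A,A) or flipped (B,L); APE8 region B; then per group:
#             nonTYR: APE8 chi1 g- when Ser/Thr; APE9-Ca/HRD-Arg-O < 6 A;
#                     APE10-Cb/DFG4-Ca < 8 A; APE11 in (8,14); APE12 in (7,14)
#             TYR:    APE9, APE10 regions B; APE9-Ca/HRD-Arg-O < 8 A

.PHE_LIKE <- c("PHE", "TYR")

# anchor atom of the DFG-Phe position: Cz for Phe/Tyr, otherwise the
# side-chain heavy atom most distal from CA
#' @keywords internal
.phe_anchor_xyz <- function(model, chain, resno) {
  nm <- res_name(model, chain, resno)
  if (is.null(nm)) return(NULL)
  if (nm %in% .PHE_LIKE) {
    cz <- atom_xyz(model, chain, resno, "CZ")
    if (!is.null(cz)) return(cz)
  }
  ca <- atom_xyz(model, chain, resno, "CA")
  sc <- sidechain_xyz(model, chain, resno, include_ca_fallback = FALSE)
  if (is.null(sc) || is.null(ca)) return(NULL)
  d <- sqrt(rowSums((sc - matrix(ca, nrow(sc), 3, byrow = TRUE))^2))
  as.numeric(sc[which.max(d), ])
}

#' All measured features for one kinase chain
#'
#' Computes every quantity the six criteria consume: the two DFG-Phe
#' anchor distances, Ramachandran regions and dihedrals of the XDFG, HRD
#' and APE6-APE10 residues, the salt-bridge and ActLoopNT hydrogen-bond
#' distances, the APE9-12 distances and the three regulatory-spine
#' distances.
#'
#' @param model StructureModel.
#' @param map KinaseMotifMap for the chain.
#' @return Named list of class \code{"FeatureVector"}; unmeasurable
#'   entries are NA.
#' @export
compute_features <- function(model, map) {
  ch <- map$chain_id
  dfg <- map$res_dfg_asp
  phe <- dfg + 1L
  anchor <- .phe_anchor_xyz(model, ch, phe)
  dist_or_na <- function(a, b) if (is.null(a) || is.null(b)) NA_real_ else .euclid(a, b)

  glu4_ca <- if (!is.na(map$res_glu4)) atom_xyz(model, ch, map$res_glu4, "CA")
  lys_ca  <- if (!is.na(map$res_saltbridge_lys))
               atom_xyz(model, ch, map$res_saltbridge_lys, "CA")

  dx  <- residue_dihedrals(model, ch, dfg - 1L)  # X of XDFG
  dd  <- residue_dihedrals(model, ch, dfg)
  dfh <- residue_dihedrals(model, ch, phe)

  # salt bridge: Lys Nz vs Glu Oe1/Oe2 (nearest terminal atoms when the
  # mapped residues are atypical; flagged)
  sb <- .saltbridge_distance(model, map)

  # ActLoopNT: DFG6 / XHRD backbone N-O
  d6 <- dfg + 5L
  nt <- NA_real_
  if (!is.na(map$res_xhrd)) {
    n6 <- atom_xyz(model, ch, d6, "N"); o6 <- atom_xyz(model, ch, d6, "O")
    nx <- atom_xyz(model, ch, map$res_xhrd, "N")
    ox <- atom_xyz(model, ch, map$res_xhrd, "O")
    cand <- c(dist_or_na(n6, ox), dist_or_na(o6, nx))
    nt <- if (all(is.na(cand))) NA_real_ else min(cand, na.rm = TRUE)
  }

  hh <- if (!is.na(map$res_hrd_his)) residue_dihedrals(model, ch, map$res_hrd_his)
        else list(phi = NA, psi = NA, chi1 = NA)
  ha <- if (!is.na(map$res_hrd_arg)) residue_dihedrals(model, ch, map$res_hrd_arg)
        else list(phi = NA, psi = NA, chi1 = NA)

  ape_d <- function(n) {
    if (map$group == "noAPE") return(list(phi = NA, psi = NA, chi1 = NA))
    residue_dihedrals(model, ch, actloop_index(map, paste0("APE", n)))
  }
  a7 <- ape_d(7); a6 <- ape_d(6); a8 <- ape_d(8); a9 <- ape_d(9); a10 <- ape_d(10)

  d_ape9 <- d_a10 <- d_a11 <- d_a12 <- NA_real_
  if (map$group != "noAPE") {
    ape9_ca <- atom_xyz(model, ch, actloop_index(map, "APE9"), "CA")
    arg_o <- if (!is.na(map$res_hrd_arg)) atom_xyz(model, ch, map$res_hrd_arg, "O")
    d_ape9 <- dist_or_na(ape9_ca, arg_o)
    dfg4_ca <- atom_xyz(model, ch, dfg + 3L, "CA")
    cbdist <- function(n) {
      cb <- .cbeta_or_virtual(model, ch, actloop_index(map, paste0("APE", n)))
      dist_or_na(cb, dfg4_ca)
    }
    d_a10 <- cbdist(10); d_a11 <- cbdist(11); d_a12 <- cbdist(12)
  }

  spine <- .spine_distances_raw(model, map)

  fv <- list(
    d_phe_glu4 = dist_or_na(anchor, glu4_ca),
    d_phe_lys = dist_or_na(anchor, lys_ca),
    xdf_regions = c(X = rama_region(dx$phi, dx$psi),
                    D = rama_region(dd$phi, dd$psi),
                    F = rama_region(dfh$phi, dfh$psi)),
    x_phi = dx$phi, x_psi = dx$psi,
    asp_phi = dd$phi, asp_psi = dd$psi,
    phe_phi = dfh$phi, phe_psi = dfh$psi,
    phe_chi1 = dfh$chi1,
    d_saltbridge = sb$distance,
    saltbridge_atypical = sb$atypical,
    d_dfg6_xhrd = nt,
    hrd_his_region = rama_region(hh$phi, hh$psi),
    hrd_arg_region = rama_region(ha$phi, ha$psi),
    ape7_region = rama_region(a7$phi, a7$psi),
    ape6_region = rama_region(a6$phi, a6$psi),
    ape8_region = rama_region(a8$phi, a8$psi),
    ape9_region = rama_region(a9$phi, a9$psi),
    ape10_region = rama_region(a10$phi, a10$psi),
    ape8_chi1 = a8$chi1,
    d_ape9ca_hrdargO = d_ape9,
    d_ape10cb_dfg4ca = d_a10,
    d_ape11cb_dfg4ca = d_a11,
    d_ape12cb_dfg4ca = d_a12,
    spine1 = spine[1], spine2 = spine[2], spine3 = spine[3]
  )
  class(fv) <- "FeatureVector"
  fv
}

#' @keywords internal
.saltbridge_distance <- function(model, map) {
  ch <- map$chain_id
  if (is.na(map$res_saltbridge_lys) || is.na(map$res_saltbridge_glu))
    return(list(distance = NA_real_, atypical = FALSE))
  lys_nm <- res_name(model, ch, map$res_saltbridge_lys)
  glu_nm <- res_name(model, ch, map$res_saltbridge_glu)
  atypical <- FALSE
  nz <- atom_xyz(model, ch, map$res_saltbridge_lys, "NZ")
  if (is.null(nz)) {
    # nearest equivalent: most distal side-chain heavy atom
    nz <- .phe_anchor_xyz(model, ch, map$res_saltbridge_lys)
    if (!identical(lys_nm, "LYS")) atypical <- TRUE
  }
  rt <- res_table(model, ch, map$res_saltbridge_glu)
  oe <- rt[rt$elety %in% c("OE1", "OE2"), c("x", "y", "z"), drop = FALSE]
  if (!nrow(oe)) {
    # terminal side-chain oxygens of whatever residue sits there (e.g. Asp)
    oe <- rt[grepl("^O[DEGH]", rt$elety), c("x", "y", "z"), drop = FALSE]
    if (!identical(glu_nm, "GLU")) atypical <- TRUE
  }
  if (is.null(nz) || !nrow(oe))
    return(list(distance = NA_real_, atypical = atypical))
  list(distance = min_pair_distance(matrix(nz, 1L), as.matrix(oe)),
       atypical = atypical)
}

#' @keywords internal
.spine_distances_raw <- function(model, map) {
  ch <- map$chain_id
  pair <- function(r1, r2) {
    if (is.na(r1) || is.na(r2)) return(NA_real_)
    min_pair_distance(sidechain_xyz(model, ch, r1), sidechain_xyz(model, ch, r2))
  }
  c(pair(map$res_hrd_his, map$res_dfg_asp + 1L),     # spine1 HRD-His / DFG-Phe
    pair(map$res_dfg_asp + 1L, map$res_glu4),        # spine2 DFG-Phe / Glu4
    pair(map$res_glu4, map$res_hpn7))                # spine3 Glu4 / HPN7
}

# ---- criterion states ----------------------------------------------------

#' Spatial DFG label
#'
#' Classifies the DFG-Phe position as DFGin (near the C-helix Glu4-Ca, far
#' from the beta3 Lys-Ca), DFGout (the converse) or DFGinter, from the
#' distances of the Phe Cz anchor to the two Ca atoms.
#'
#' @param model StructureModel.
#' @param map KinaseMotifMap.
#' @param config \code{\link{active_config}}.
#' @return One of "DFGin", "DFGout", "DFGinter", "None".
#' @export
spatial_dfg_label <- function(model, map, config = active_config()) {
  fv <- compute_features(model, map)
  .spatial_from_features(fv, config)
}

#' @keywords internal
.spatial_from_features <- function(fv, config) {
  d4 <- fv$d_phe_glu4; dk <- fv$d_phe_lys
  if (is.na(d4) || is.na(dk)) return("None")
  if (d4 <= config$spatial_glu4_in_max && dk >= config$spatial_lys_in_min)
    return("DFGin")
  if (d4 > config$spatial_glu4_out_min && dk <= config$spatial_lys_out_max)
    return("DFGout")
  "DFGinter"
}

#' Dihedral label of the XDFG motif
#'
#' Concatenates the Ramachandran region letters of the X, Asp and Phe
#' residues of the XDFG motif with the chi1 rotamer word of the
#' Phe-position side chain (minus / plus / trans).  BLAminus is the
#' catalytically competent state.
#'
#' @inheritParams spatial_dfg_label
#' @return Label string ("BLAminus", "ABAminus", ...), "other" when any
#'   region is outside A/B/L, or "None" when a dihedral is missing.
#' @export
dihedral_xdf_label <- function(model, map, config = active_config()) {
  fv <- compute_features(model, map)
  .xdf_from_features(fv)
}

#' @keywords internal
.xdf_from_features <- function(fv) {
  reg <- fv$xdf_regions
  if (any(reg == "none")) return("None")
  rot <- chi1_bin(fv$phe_chi1)
  if (is.na(rot)) return("None")
  if (any(reg == "other")) return("other")
  paste0(paste(reg, collapse = ""), rot)
}

.state <- function(ok) if (is.na(ok)) "none" else if (ok) "in" else "out"

#' Salt-bridge criterion state
#'
#' @inheritParams spatial_dfg_label
#' @return list(state = "in"/"out"/"none"/"skipped", distance).
#' @export
saltbridge_state <- function(model, map, config = active_config()) {
  if (map$skip_saltbridge)
    return(list(state = "skipped", distance = NA_real_))
  fv <- compute_features(model, map)
  list(state = .state(if (is.na(fv$d_saltbridge)) NA
                      else fv$d_saltbridge < config$saltbridge_max),
       distance = fv$d_saltbridge, atypical = fv$saltbridge_atypical)
}

#' ActLoopNT criterion state
#'
#' Backbone-backbone hydrogen bond between DFG6 and the residue before the
#' HRD motif; in when the minimum of the N-O and O-N distances is below
#' the cutoff.
#'
#' @inheritParams spatial_dfg_label
#' @return list(state, distance).
#' @export
actloopNT_state <- function(model, map, config = active_config()) {
  fv <- compute_features(model, map)
  list(state = .state(if (is.na(fv$d_dfg6_xhrd)) NA
                      else fv$d_dfg6_xhrd < config$hbond_max),
       distance = fv$d_dfg6_xhrd)
}

#' HRD criterion state
#'
#' His backbone in region A and Arg backbone in region L; skipped for
#' kinases lacking the alphaF-helix Asp that braces the HRD loop.
#'
#' @inheritParams spatial_dfg_label
#' @return One of "in", "out", "none", "skipped".
#' @export
hrd_state <- function(model, map, config = active_config()) {
  if (map$skip_hrd) return("skipped")
  fv <- compute_features(model, map)
  .hrd_from_features(fv)
}

#' @keywords internal
.hrd_from_features <- function(fv) {
  h <- fv$hrd_his_region; a <- fv$hrd_arg_region
  if (h == "none" || a == "none") return("none")
  if (h == "A" && a == "L") "in" else "out"
}

#' ActLoopCT criterion state
#'
#' The C-terminal activation-loop segment must be positioned for substrate
#' binding.  Sub-features: APE7/APE6 regions (A,A) or the type-II-turn
#' flip (B,L); APE8 region B; then for non-TYR kinases the APE8 chi1
#' gauche-minus requirement (Ser/Thr only) and the APE9-12 distance
#' bounds; for TYR kinases, region B at APE9 and APE10 and the wider APE9
#' distance bound.
#'
#' @inheritParams spatial_dfg_label
#' @return list(state, detail = named per-sub-feature states).
#' @export
actloopCT_state <- function(model, map, config = active_config()) {
  if (map$group == "noAPE")
    return(list(state = "skipped", detail = character()))
  fv <- compute_features(model, map)
  .ct_from_features(fv, model, map, config)
}

#' @keywords internal
.ct_from_features <- function(fv, model, map, config) {
  det <- character()
  sub <- function(name, ok) det[name] <<- .state(ok)

  r7 <- fv$ape7_region; r6 <- fv$ape6_region
  sub("APE7_6", if (r7 == "none" || r6 == "none") NA
                else (r7 == "A" && r6 == "A") || (r7 == "B" && r6 == "L"))
  sub("APE8", if (fv$ape8_region == "none") NA else fv$ape8_region == "B")

  if (map$group == "TYR") {
    sub("APE9_dihe", if (fv$ape9_region == "none") NA else fv$ape9_region == "B")
    sub("APE10_dihe", if (fv$ape10_region == "none") NA else fv$ape10_region == "B")
    sub("APE9_dist", if (is.na(fv$d_ape9ca_hrdargO)) NA
                     else fv$d_ape9ca_hrdargO < config$ape9_max_tyr)
  } else {
    # chi1 g- required only when APE8 is Ser or Thr
    ape8_nm <- res_name(model, map$chain_id, actloop_index(map, "APE8"))
    if (!is.null(ape8_nm) && ape8_nm %in% c("SER", "THR"))
      sub("APE8_chi1", chi1_minus(fv$ape8_chi1))
    sub("APE9_dist", if (is.na(fv$d_ape9ca_hrdargO)) NA
                     else fv$d_ape9ca_hrdargO < config$ape9_max_nontyr)
    sub("APE10_dist", if (is.na(fv$d_ape10cb_dfg4ca)) NA
                      else fv$d_ape10cb_dfg4ca < config$ape10_max)
    sub("APE11_dist", if (is.na(fv$d_ape11cb_dfg4ca)) NA
                      else fv$d_ape11cb_dfg4ca > config$ape11_bounds[1] &&
                           fv$d_ape11cb_dfg4ca < config$ape11_bounds[2])
    sub("APE12_dist", if (is.na(fv$d_ape12cb_dfg4ca)) NA
                      else fv$d_ape12cb_dfg4ca > config$ape12_bounds[1] &&
                           fv$d_ape12cb_dfg4ca < config$ape12_bounds[2])
  }
  state <- if (any(det == "out")) "out"
           else if (any(det == "none")) "none"
           else "in"
  list(state = state, detail = det)
}

#' Regulatory-spine distances
#'
#' Minimum side-chain heavy-atom distances of the three stacked pairs
#' HRD-His/DFG-Phe, DFG-Phe/Glu4 and Glu4/HPN7 (Ca stands in for Gly/Ala
#' side chains).  The spine is intact when all three are below 5 A; it is
#' reported but never used in the Active decision.
#'
#' @inheritParams spatial_dfg_label
#' @return list(spine1, spine2, spine3, intact).
#' @export
spine_distances <- function(model, map, config = active_config()) {
  s <- .spine_distances_raw(model, map)
  intact <- if (any(is.na(s))) NA else all(s < config$spine_max)
  list(spine1 = s[1], spine2 = s[2], spine3 = s[3], intact = intact)
}
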