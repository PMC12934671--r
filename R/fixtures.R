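# Synthetic kinase-like fixtures.
#
# The builder favors geometric exactness over global protein realism: the
# criteria are local, so the activation loop is built as two idealized
# peptide arms (N-terminal arm through DFG9, C-terminal arm from APE15
# into a C-terminal helix) with a disordered middle, and the conserved
# motifs outside the loop (beta3 Lys, C-helix Glu, Glu4, HPN7, the HRD
# mini-chain) are free-floating satellite residues rigid-placed to realize
# each requested pairwise distance.  Dihedral requests are exact by
# construction (natural-extension chain building); distance requests are
# realized by deterministic rigid-body optimization and verified post hoc
# with the same measurement functions the classifier uses.  These are
# test fixtures, not models of any real kinase.

# ---- deterministic uniform stream (keeps the global RNG untouched) -------
.lcg_stream <- function(seed, n) {
  x <- as.double(seed %% 2147483647)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (1103515245 * x + 12345) %% 2147483648
    out[i] <- x / 2147483648
  }
  out
}

# ---- natural extension reference frame -----------------------------------
#' @keywords internal
.nerf <- function(a, b, c, bond, angle, torsion) {
  th <- .rad(angle); ch <- .rad(torsion)
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ch), bond * sin(th) * sin(ch))
  as.numeric(c + cbind(bc, m, n) %*% d2)
}

# torsion(C, N, CA, CB) giving L-chirality with angle(N-CA-CB) = 110.5
.CB_TORSION <- -122.6

# side-chain template: for each atom, the three reference atoms, bond,
# angle and torsion (chi1 substituted where torsion is NA)
.SIDECHAINS <- list(
  ALA = list(),
  GLY = NULL,
  SER = list(c("N", "CA", "CB", "OG", 1.42, 110.5, NA)),
  CYS = list(c("N", "CA", "CB", "SG", 1.81, 113.0, NA)),
  THR = list(c("N", "CA", "CB", "OG1", 1.43, 109.5, NA),
             c("N", "CA", "CB", "CG2", 1.52, 110.5, "chi1+120")),
  VAL = list(c("N", "CA", "CB", "CG1", 1.52, 110.5, NA),
             c("N", "CA", "CB", "CG2", 1.52, 110.5, "chi1+120")),
  LEU = list(c("N", "CA", "CB", "CG", 1.53, 116.0, NA),
             c("CA", "CB", "CG", "CD1", 1.52, 110.5, "180"),
             c("CA", "CB", "CG", "CD2", 1.52, 110.5, "60")),
  ASP = list(c("N", "CA", "CB", "CG", 1.52, 112.6, NA),
             c("CA", "CB", "CG", "OD1", 1.25, 118.5, "0"),
             c("CA", "CB", "CG", "OD2", 1.25, 118.5, "180")),
  GLU = list(c("N", "CA", "CB", "CG", 1.52, 114.0, NA),
             c("CA", "CB", "CG", "CD", 1.52, 114.0, "180"),
             c("CB", "CG", "CD", "OE1", 1.25, 118.5, "0"),
             c("CB", "CG", "CD", "OE2", 1.25, 118.5, "180")),
  LYS = list(c("N", "CA", "CB", "CG", 1.52, 114.0, NA),
             c("CA", "CB", "CG", "CD", 1.52, 111.5, "180"),
             c("CB", "CG", "CD", "CE", 1.52, 111.5, "180"),
             c("CG", "CD", "CE", "NZ", 1.49, 111.5, "180")),
  ARG = list(c("N", "CA", "CB", "CG", 1.52, 114.0, NA),
             c("CA", "CB", "CG", "CD", 1.52, 111.5, "180")),
  HIS = list(c("N", "CA", "CB", "CG", 1.50, 113.8, NA)),
  PRO = list(c("N", "CA", "CB", "CG", 1.49, 104.5, NA),
             c("CA", "CB", "CG", "CD", 1.51, 105.5, "-35")),
  TYR = "ring", PHE = "ring"
)

.ring_atoms <- function(n, ca, cb, chi1, chi2 = -85, tyr = FALSE) {
  cg <- .nerf(n, ca, cb, 1.50, 113.8, chi1)
  cd1 <- .nerf(ca, cb, cg, 1.39, 120, chi2)
  cd2 <- .nerf(ca, cb, cg, 1.39, 120, chi2 + 180)
  ce1 <- .nerf(cb, cg, cd1, 1.39, 120, 180)
  ce2 <- .nerf(cb, cg, cd2, 1.39, 120, 180)
  cz <- .nerf(cg, cd1, ce1, 1.39, 120, 0)
  out <- list(CG = cg, CD1 = cd1, CD2 = cd2, CE1 = ce1, CE2 = ce2, CZ = cz)
  if (tyr) out$OH <- .nerf(cd1, ce1, cz, 1.36, 120, 180)
  out
}

# build one continuous peptide from residue specs
# rs: data.frame(resno, type, phi, psi, chi1)
#' @keywords internal
.build_peptide <- function(rs, chain = "A") {
  n <- nrow(rs)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  a0 <- c(0, 1, 0)
  C[1, ] <- .nerf(a0, N[1, ], CA[1, ], 1.525, 111.0, 55)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- .nerf(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, rs$psi[i])
    CA[i + 1L, ] <- .nerf(CA[i, ], C[i, ], N[i + 1L, ], 1.458, 121.7, 180)
    C[i + 1L, ] <- .nerf(C[i, ], N[i + 1L, ], CA[i + 1L, ], 1.525, 111.0,
                         rs$phi[i + 1L])
  }
  for (i in seq_len(n))
    O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, rs$psi[i] + 180)

  rows <- list()
  push <- function(resno, type, name, p) {
    el <- substr(name, 1, 1)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, insert = "", resid = type, elety = name,
      elesy = el, x = p[1], y = p[2], z = p[3], o = 1, b = 90,
      hetero = FALSE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    ty <- rs$type[i]
    push(rs$resno[i], ty, "N", N[i, ])
    push(rs$resno[i], ty, "CA", CA[i, ])
    push(rs$resno[i], ty, "C", C[i, ])
    push(rs$resno[i], ty, "O", O[i, ])
    if (ty == "GLY") next
    cb <- .nerf(C[i, ], N[i, ], CA[i, ], 1.53, 110.5, .CB_TORSION)
    push(rs$resno[i], ty, "CB", cb)
    chi1 <- if (is.na(rs$chi1[i])) -65 else rs$chi1[i]
    tmpl <- .SIDECHAINS[[ty]]
    if (identical(tmpl, "ring")) {
      ring <- .ring_atoms(N[i, ], CA[i, ], cb, chi1, tyr = (ty == "TYR"))
      for (nm in names(ring)) push(rs$resno[i], ty, nm, ring[[nm]])
    } else if (!is.null(tmpl) && length(tmpl)) {
      pos <- list(N = N[i, ], CA = CA[i, ], CB = cb)
      for (sp in tmpl) {
        tor <- if (is.na(sp[7])) chi1
               else if (sp[7] == "chi1+120") chi1 + 120
               else as.numeric(sp[7])
        p <- .nerf(pos[[sp[1]]], pos[[sp[2]]], pos[[sp[3]]],
                   as.numeric(sp[5]), as.numeric(sp[6]), tor)
        pos[[sp[4]]] <- p
        push(rs$resno[i], ty, sp[4], p)
      }
    }
  }
  do.call(rbind, rows)
}

# ---- rigid placement against distance constraints ------------------------

.rotvec_matrix <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  k <- r / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.transform_xyz <- function(xyz, p, c0) {
  R <- .rotvec_matrix(p[4:6])
  sweep((xyz - matrix(c0, nrow(xyz), 3, byrow = TRUE)) %*% t(R), 2,
        c0 + p[1:3], "+")
}

# constraints: list of list(measure = function(xyz) value, target, hinge)
#' @keywords internal
.place_rigid <- function(frag, constraints, init = c(0, 0, 0), seed = 1,
                         n_restarts = 30L, tol = 0.02) {
  xyz0 <- as.matrix(frag[, c("x", "y", "z")])
  c0 <- colMeans(xyz0)
  hard <- !vapply(constraints, function(cn) isTRUE(cn$hinge), TRUE)
  obj <- function(p) {
    xyz <- .transform_xyz(xyz0, p, c0)
    s <- 0
    for (cn in constraints) {
      m <- cn$measure(xyz)
      s <- s + if (isTRUE(cn$hinge)) 0.01 * max(0, m - cn$target)^2
               else (m - cn$target)^2
    }
    s
  }
  resid_max <- function(p) {
    xyz <- .transform_xyz(xyz0, p, c0)
    r <- 0
    for (cn in constraints[hard])
      r <- max(r, abs(cn$measure(xyz) - cn$target))
    r
  }
  jit <- .lcg_stream(seed * 7919 + 13, n_restarts * 6L)
  best <- NULL; bestp <- NULL
  for (k in seq_len(n_restarts)) {
    p0 <- c(init, 0, 0, 0)
    if (k > 1L) {
      j <- jit[((k - 1L) * 6L + 1L):(k * 6L)]
      p0 <- p0 + c((j[1:3] - 0.5) * 16, (j[4:6] - 0.5) * 2 * pi)
    }
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-15))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-15))
    if (is.null(best) || fit$value < best) { best <- fit$value; bestp <- fit$par }
    if (resid_max(bestp) < tol / 4) break
  }
  if (resid_max(bestp) > tol)
    stop(sprintf(paste0("build error: rigid placement did not satisfy its ",
                        "distance constraints (max residual %.3f A); the ",
                        "requested geometry may be unsatisfiable"),
                 resid_max(bestp)), call. = FALSE)
  xyz <- .transform_xyz(xyz0, bestp, c0)
  frag$x <- xyz[, 1]; frag$y <- xyz[, 2]; frag$z <- xyz[, 3]
  frag
}

# align fragment so that the unit vector from atom p1 to p2 points along u,
# then translate so p1 lands at target
.orient_and_place <- function(frag, p1, p2, u, target) {
  xyz <- as.matrix(frag[, c("x", "y", "z")])
  a <- xyz[p1, ]; b <- xyz[p2, ]
  v <- .unit(b - a); u <- .unit(u)
  ax <- .cross3(v, u)
  s <- sqrt(sum(ax^2)); cth <- sum(v * u)
  R <- if (s < 1e-12) { if (cth > 0) diag(3) else .rotvec_matrix(pi * .unit(c(v[2], -v[1], 0) + 1e-3)) }
       else .rotvec_matrix(.unit(ax) * atan2(s, cth))
  xyz <- xyz %*% t(R)
  off <- target - xyz[p1, ]
  xyz <- sweep(xyz, 2, off, "+")
  frag$x <- xyz[, 1]; frag$y <- xyz[, 2]; frag$z <- xyz[, 3]
  frag
}

# ---- toy kinase spec -----------------------------------------------------

#' Specification of a synthetic toy kinase fixture
#'
#' Defaults realize an all-criteria-passing geometry for the chosen group;
#' \code{violate} flips exactly one criterion.  A distance set to NA is
#' left unconstrained.
#'
#' @param group "nonTYR", "TYR" or "noAPE".
#' @param violate NULL or one of "spatial", "dihedral", "saltbr", "hrd",
#'   "actloopNT", "actloopCT".
#' @param loop_length Activation loop length, DFG1..APE1 inclusive
#'   (>= 24; default 26; the middle is left unmodeled, as in a disordered
#'   loop).
#' @param dihedrals Named list of (phi, psi) targets in degrees for
#'   \code{x}, \code{asp}, \code{phe}, \code{hrd_his}, \code{hrd_arg},
#'   \code{ape10}, \code{ape9}, \code{ape8}, \code{ape7}, \code{ape6};
#'   plus scalars \code{phe_chi1}, \code{ape8_chi1}.
#' @param distances Named list of targets in Angstroms: saltbridge,
#'   dfg6_xhrd, ape9_hrdargO, ape10_dfg4, ape11_dfg4, ape12_dfg4,
#'   phe_glu4, phe_lys, spine1, spine2, spine3.
#' @param cell,spacegroup Optional crystal cell (six parameters) and space
#'   group for symmetry-dependent fixtures.
#' @param ctd_length Helical residues after APE1 (>= 40 for the
#'   superposition window; default 45).
#' @param seed Integer controlling the deterministic placement restarts.
#' @param entry_id Identifier of the emitted model.
#' @return List of class \code{"ToyKinaseSpec"}.
#' @export
toy_kinase_spec <- function(group = "nonTYR", violate = NULL,
                            loop_length = 26L, dihedrals = list(),
                            distances = list(), cell = NULL,
                            spacegroup = NULL, ctd_length = 45L, seed = 1L,
                            entry_id = NULL) {
  stopifnot(group %in% c("nonTYR", "TYR", "noAPE"))
  if (loop_length < 24L) stop("loop_length must be >= 24", call. = FALSE)
  dh <- list(x = c(-120, 130), asp = c(60, 40), phe = c(-75, -30),
             phe_chi1 = -65,
             hrd_his = c(-75, -30), hrd_arg = c(60, 40),
             ape10 = c(-120, 130), ape9 = c(-120, 130), ape8 = c(-120, 130),
             ape8_chi1 = -60, ape7 = c(-75, -30), ape6 = c(-75, -30))
  ds <- list(saltbridge = 3.0, dfg6_xhrd = 2.9,
             ape9_hrdargO = if (group == "TYR") 7.0 else 3.8,
             ape10_dfg4 = 7.0, ape11_dfg4 = 10.0, ape12_dfg4 = 11.0,
             phe_glu4 = 8.0, phe_lys = 14.0,
             spine1 = 4.0, spine2 = 4.0, spine3 = 4.0)
  if (!is.null(violate)) {
    violate <- match.arg(violate, c("spatial", "dihedral", "saltbr", "hrd",
                                    "actloopNT", "actloopCT"))
    switch(violate,
      spatial = { ds$phe_glu4 <- 14; ds$phe_lys <- 9; ds$spine2 <- NA },
      dihedral = { dh$phe_chi1 <- 55 },           # g+ rotamer: BLAplus
      saltbr = { ds$saltbridge <- 4.5 },
      hrd = { dh$hrd_arg <- c(-120, 140) },       # Arg in B, not L
      actloopNT = { ds$dfg6_xhrd <- 5.0 },
      actloopCT = { ds$ape10_dfg4 <- 9.0 })
  }
  dh[names(dihedrals)] <- dihedrals
  ds[names(distances)] <- distances
  if (is.null(entry_id))
    entry_id <- paste0("toy_", group, if (is.null(violate)) "" else
                       paste0("_", violate))
  sp <- list(group = group, violate = violate, loop_length = as.integer(loop_length),
             dihedrals = dh, distances = ds, cell = cell,
             spacegroup = spacegroup, ctd_length = as.integer(ctd_length),
             seed = as.integer(seed), entry_id = entry_id)
  class(sp) <- "ToyKinaseSpec"
  sp
}

# resno layout of the fixture (chain A):
#   30 Lys (beta3), 45 C-helix Glu, 49 Glu4 (Leu), 60 HPN7 (Leu),
#   70-73 xHRD-His-Arg-Asp mini-chain,
#   99-100 context + X[XDFG], 101.. DFG1..DFG9 arm,
#   APE15..APE1 arm ending at 100+loop_length, then the C-terminal helix.
.TOY_RESNOS <- list(lys = 30L, glu = 45L, glu4 = 49L, hpn7 = 60L,
                    xhrd = 70L, dfg1 = 101L)

#' Build a synthetic toy kinase
#'
#' See \code{\link{toy_kinase_spec}}.  Deterministic given the spec seed.
#'
#' @param spec A \code{ToyKinaseSpec}.
#' @param tol Maximum accepted distance residual (Angstroms).
#' @return list(model = StructureModel, map = KinaseMotifMap, residuals =
#'   data.frame(quantity, target, achieved, residual)).
#' @export
build_toy_kinase <- function(spec = toy_kinase_spec(), tol = 0.05) {
  dh <- spec$dihedrals; ds <- spec$distances
  L <- spec$loop_length
  rn <- .TOY_RESNOS
  ape1 <- rn$dfg1 + L - 1L
  ape <- function(n) ape1 - (n - 1L)

  # --- N-terminal arm: 99 GLY, 100 X(THR), DFG1..DFG9 ---------------------
  nt_types <- c("GLY", "THR", "ASP", "PHE", "GLY", "LEU", "GLY", "VAL",
                "GLY", "ALA", "SER")
  nt <- data.frame(resno = 99:109, type = nt_types,
                   phi = c(-120, dh$x[1], dh$asp[1], dh$phe[1], 90,
                           -60, -60, -60, -60, -60, -60),
                   psi = c(130, dh$x[2], dh$asp[2], dh$phe[2], 0,
                           -45, -45, -45, -45, -45, 130),
                   chi1 = c(NA, -60, -65, dh$phe_chi1, NA, -65, NA, -65,
                            NA, NA, -65), stringsAsFactors = FALSE)
  nt_at <- .build_peptide(nt)

  # --- C-terminal arm: APE15..APE1 + helix --------------------------------
  ct_res <- ape(15):ape1
  ct_types <- c("ALA", "ALA", "ALA", "ALA", "ALA", "VAL", "GLY",
                if (spec$group == "TYR") "PRO" else "THR",
                "ALA", "ALA", "ALA", "ALA", "ALA", "PRO", "GLU")
  # APE15..APE11 alternate extended/helical so the APE10-12 C-betas are
  # not colinear (keeps the three distance constraints well conditioned);
  # no criterion constrains these dihedrals
  phi <- c(-120, -60, -120, -60, -120, dh$ape10[1], dh$ape9[1], dh$ape8[1],
           dh$ape7[1], dh$ape6[1], -120, -120, -120, -70, -120)
  psi <- c(130, -45, 130, -45, 130, dh$ape10[2], dh$ape9[2], dh$ape8[2],
           dh$ape7[2], dh$ape6[2], 130, 130, 130, 140, 130)
  chi1 <- c(rep(NA, 5), -65, NA,
            if (spec$group == "TYR") 30 else dh$ape8_chi1,
            rep(NA, 7))
  ctd <- data.frame(resno = (ape1 + 1L):(ape1 + spec$ctd_length),
                    type = "ALA", phi = -60, psi = -45, chi1 = NA,
                    stringsAsFactors = FALSE)
  ct <- rbind(data.frame(resno = ct_res, type = ct_types, phi = phi,
                         psi = psi, chi1 = chi1, stringsAsFactors = FALSE),
              ctd)
  ct_at <- .build_peptide(ct)

  gx <- function(at, resno, name) {
    r <- at[at$resno == resno & at$elety == name, c("x", "y", "z")]
    if (!nrow(r)) stop("fixture internal: missing atom ", resno, " ", name)
    as.numeric(r[1, ])
  }
  scx <- function(at, resno) {
    r <- at[at$resno == resno &
              !(at$elety %in% c("N", "CA", "C", "O")), c("x", "y", "z")]
    as.matrix(r)
  }

  dfg4_ca <- gx(nt_at, 104L, "CA")
  phe_cz <- gx(nt_at, 102L, "CZ")
  phe_sc <- scx(nt_at, 102L)

  # place the CT arm: APE10/11/12 C-beta distances to DFG4 C-alpha, with a
  # hinge keeping APE9 within reach of the HRD mini-chain placed next
  rowidx <- function(at, resno, name) which(at$resno == resno & at$elety == name)
  cons_ct <- list()
  for (nn in c(10L, 11L, 12L)) {
    tgt <- ds[[paste0("ape", nn, "_dfg4")]]
    if (is.na(tgt)) next
    i <- rowidx(ct_at, ape(nn), "CB")
    cons_ct[[length(cons_ct) + 1L]] <- local({
      i0 <- i; t0 <- tgt
      list(measure = function(xyz) sqrt(sum((xyz[i0, ] - dfg4_ca)^2)),
           target = t0, hinge = FALSE)
    })
  }
  i9 <- rowidx(ct_at, ape(9L), "CA")
  n6 <- gx(nt_at, 106L, "N")
  cons_ct[[length(cons_ct) + 1L]] <- local({
    i0 <- i9
    list(measure = function(xyz) sqrt(sum((xyz[i0, ] - n6)^2)),
         target = 12, hinge = TRUE)
  })
  init_ct <- dfg4_ca + c(8, -3, 0) - colMeans(as.matrix(ct_at[, c("x", "y", "z")]))
  ct_at <- .place_rigid(ct_at, cons_ct, init = init_ct, seed = spec$seed,
                        tol = tol / 2)

  # --- HRD mini-chain: xHRD(VAL) HIS ARG ASP ------------------------------
  hrd <- data.frame(resno = 70:73, type = c("VAL", "HIS", "ARG", "ASP"),
                    phi = c(-120, dh$hrd_his[1], dh$hrd_arg[1], -120),
                    psi = c(130, dh$hrd_his[2], dh$hrd_arg[2], 130),
                    chi1 = c(-65, -65, -65, -65), stringsAsFactors = FALSE)
  hrd_at <- .build_peptide(hrd)
  ape9_ca <- gx(ct_at, ape(9L), "CA")
  o6 <- gx(nt_at, 106L, "O")
  cons_hrd <- list()
  if (!is.na(ds$dfg6_xhrd)) {
    iN <- rowidx(hrd_at, 70L, "N"); iO <- rowidx(hrd_at, 70L, "O")
    cons_hrd[[length(cons_hrd) + 1L]] <- local({
      iN0 <- iN; iO0 <- iO; t0 <- ds$dfg6_xhrd
      list(measure = function(xyz) min(sqrt(sum((n6 - xyz[iO0, ])^2)),
                                       sqrt(sum((o6 - xyz[iN0, ])^2))),
           target = t0, hinge = FALSE)
    })
  }
  if (!is.na(ds$ape9_hrdargO)) {
    iAo <- rowidx(hrd_at, 72L, "O")
    cons_hrd[[length(cons_hrd) + 1L]] <- local({
      i0 <- iAo; t0 <- ds$ape9_hrdargO
      list(measure = function(xyz) sqrt(sum((xyz[i0, ] - ape9_ca)^2)),
           target = t0, hinge = FALSE)
    })
  }
  if (!is.na(ds$spine1)) {
    isc <- which(hrd_at$resno == 71L &
                   !(hrd_at$elety %in% c("N", "CA", "C", "O")))
    cons_hrd[[length(cons_hrd) + 1L]] <- local({
      i0 <- isc; t0 <- ds$spine1
      list(measure = function(xyz) min_pair_distance(xyz[i0, , drop = FALSE],
                                                     phe_sc),
           target = t0, hinge = FALSE)
    })
  }
  init_hrd <- (n6 + ape9_ca) / 2 + c(0, 0, -5) -
    colMeans(as.matrix(hrd_at[, c("x", "y", "z")]))
  hrd_at <- .place_rigid(hrd_at, cons_hrd, init = init_hrd,
                         seed = spec$seed + 1L, tol = tol / 2)

  # --- beta3 Lys: CA at phe_lys from Phe CZ, side chain pointing outward --
  lys_at <- .build_peptide(data.frame(resno = rn$lys, type = "LYS",
                                      phi = -120, psi = 130, chi1 = -65,
                                      stringsAsFactors = FALSE))
  u_lys <- .unit(c(-0.25, 0.85, 0.47))
  lys_at <- .orient_and_place(lys_at, rowidx(lys_at, rn$lys, "CA"),
                              rowidx(lys_at, rn$lys, "NZ"), u_lys,
                              phe_cz + ds$phe_lys * u_lys)

  # --- C-helix Glu: OE1 at saltbridge distance from Lys NZ, OE2 beyond ----
  glu_at <- .build_peptide(data.frame(resno = rn$glu, type = "GLU",
                                      phi = -60, psi = -45, chi1 = -65,
                                      stringsAsFactors = FALSE))
  nz <- gx(lys_at, rn$lys, "NZ")
  if (!is.na(ds$saltbridge)) {
    glu_at <- .orient_and_place(glu_at, rowidx(glu_at, rn$glu, "OE1"),
                                rowidx(glu_at, rn$glu, "OE2"), u_lys,
                                nz + ds$saltbridge * u_lys)
  }

  # --- Glu4 satellite (Leu): CA distance to Phe CZ plus spine2 ------------
  glu4_at <- .build_peptide(data.frame(resno = rn$glu4, type = "LEU",
                                       phi = -60, psi = -45, chi1 = -65,
                                       stringsAsFactors = FALSE))
  cons_g4 <- list()
  if (!is.na(ds$phe_glu4)) {
    iCA <- rowidx(glu4_at, rn$glu4, "CA")
    cons_g4[[length(cons_g4) + 1L]] <- local({
      i0 <- iCA; t0 <- ds$phe_glu4
      list(measure = function(xyz) sqrt(sum((xyz[i0, ] - phe_cz)^2)),
           target = t0, hinge = FALSE)
    })
  }
  if (!is.na(ds$spine2)) {
    isc <- which(glu4_at$resno == rn$glu4 &
                   !(glu4_at$elety %in% c("N", "CA", "C", "O")))
    cons_g4[[length(cons_g4) + 1L]] <- local({
      i0 <- isc; t0 <- ds$spine2
      list(measure = function(xyz) min_pair_distance(xyz[i0, , drop = FALSE],
                                                     phe_sc),
           target = t0, hinge = FALSE)
    })
  }
  u_g4 <- .unit(c(0.9, -0.3, 0.3))
  init_g4 <- phe_cz + (if (is.na(ds$phe_glu4)) 8 else ds$phe_glu4) * u_g4 -
    colMeans(as.matrix(glu4_at[, c("x", "y", "z")]))
  if (length(cons_g4))
    glu4_at <- .place_rigid(glu4_at, cons_g4, init = init_g4,
                            seed = spec$seed + 2L, tol = tol / 2)
  else {
    glu4_at$x <- glu4_at$x + init_g4[1]; glu4_at$y <- glu4_at$y + init_g4[2]
    glu4_at$z <- glu4_at$z + init_g4[3]
  }

  # --- HPN7 satellite (Leu): spine3 to Glu4 -------------------------------
  hpn_at <- .build_peptide(data.frame(resno = rn$hpn7, type = "LEU",
                                      phi = -60, psi = -45, chi1 = -65,
                                      stringsAsFactors = FALSE))
  g4_sc <- scx(glu4_at, rn$glu4)
  if (!is.na(ds$spine3)) {
    isc <- which(hpn_at$resno == rn$hpn7 &
                   !(hpn_at$elety %in% c("N", "CA", "C", "O")))
    cons_h <- list(local({
      i0 <- isc; t0 <- ds$spine3
      list(measure = function(xyz) min_pair_distance(xyz[i0, , drop = FALSE],
                                                     g4_sc),
           target = t0, hinge = FALSE)
    }))
    init_h <- colMeans(g4_sc) + c(4, 3, -3) -
      colMeans(as.matrix(hpn_at[, c("x", "y", "z")]))
    hpn_at <- .place_rigid(hpn_at, cons_h, init = init_h,
                           seed = spec$seed + 3L, tol = tol / 2)
  }

  atoms <- rbind(lys_at, glu_at, glu4_at, hpn_at, hrd_at, nt_at, ct_at)
  model <- structure_model(atoms, entry_id = spec$entry_id,
                           cell = spec$cell, spacegroup = spec$spacegroup)
  map <- motif_map(kinase_id = paste0(if (spec$group == "TYR") "TYR"
                                      else "CAMK", "_TOY1"),
                   chain_id = "A", res_dfg_asp = rn$dfg1, res_ape_glu = ape1,
                   res_hrd_his = 71L, res_saltbridge_lys = rn$lys,
                   res_saltbridge_glu = rn$glu, res_glu4 = rn$glu4,
                   res_hpn7 = rn$hpn7, group = spec$group)

  residuals <- .toy_residuals(model, map, spec)
  bad <- residuals[!is.na(residuals$residual) & residuals$residual >
                     ifelse(residuals$kind == "dihedral", 1, tol), ]
  if (nrow(bad))
    stop("build error: constraints not satisfied within tolerance: ",
         paste(sprintf("%s (residual %.3f)", bad$quantity, bad$residual),
               collapse = ", "), call. = FALSE)
  list(model = model, map = map, residuals = residuals)
}

#' @keywords internal
.toy_residuals <- function(model, map, spec) {
  dh <- spec$dihedrals; ds <- spec$distances
  fv <- compute_features(model, map)
  ang_diff <- function(a, b) {
    d <- abs(a - b) %% 360
    min(d, 360 - d)
  }
  rows <- list()
  add <- function(q, kind, target, achieved) {
    resid <- if (is.na(target) || is.na(achieved)) NA_real_
             else if (kind == "dihedral") ang_diff(target, achieved)
             else abs(target - achieved)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = q, kind = kind, target = target, achieved = achieved,
      residual = resid, stringsAsFactors = FALSE)
  }
  add("x_phi", "dihedral", dh$x[1], fv$x_phi)
  add("x_psi", "dihedral", dh$x[2], fv$x_psi)
  add("asp_phi", "dihedral", dh$asp[1], fv$asp_phi)
  add("asp_psi", "dihedral", dh$asp[2], fv$asp_psi)
  add("phe_phi", "dihedral", dh$phe[1], fv$phe_phi)
  add("phe_psi", "dihedral", dh$phe[2], fv$phe_psi)
  add("phe_chi1", "dihedral", dh$phe_chi1, fv$phe_chi1)
  hh <- residue_dihedrals(model, "A", 71L)
  ha <- residue_dihedrals(model, "A", 72L)
  add("hrd_his_phi", "dihedral", dh$hrd_his[1], hh$phi)
  add("hrd_his_psi", "dihedral", dh$hrd_his[2], hh$psi)
  add("hrd_arg_phi", "dihedral", dh$hrd_arg[1], ha$phi)
  add("hrd_arg_psi", "dihedral", dh$hrd_arg[2], ha$psi)
  if (spec$group != "noAPE") {
    for (nn in c(6L, 7L, 8L, 9L, 10L)) {
      d <- residue_dihedrals(model, "A", actloop_index(map, paste0("APE", nn)))
      add(paste0("ape", nn, "_phi"), "dihedral", dh[[paste0("ape", nn)]][1], d$phi)
      add(paste0("ape", nn, "_psi"), "dihedral", dh[[paste0("ape", nn)]][2], d$psi)
    }
    if (spec$group != "TYR")
      add("ape8_chi1", "dihedral", dh$ape8_chi1, fv$ape8_chi1)
  }
  add("saltbridge", "distance", ds$saltbridge, fv$d_saltbridge)
  add("dfg6_xhrd", "distance", ds$dfg6_xhrd, fv$d_dfg6_xhrd)
  add("ape9_hrdargO", "distance", ds$ape9_hrdargO, fv$d_ape9ca_hrdargO)
  add("ape10_dfg4", "distance", ds$ape10_dfg4, fv$d_ape10cb_dfg4ca)
  add("ape11_dfg4", "distance", ds$ape11_dfg4, fv$d_ape11cb_dfg4ca)
  add("ape12_dfg4", "distance", ds$ape12_dfg4, fv$d_ape12cb_dfg4ca)
  add("phe_glu4", "distance", ds$phe_glu4, fv$d_phe_glu4)
  add("phe_lys", "distance", ds$phe_lys, fv$d_phe_lys)
  add("spine1", "distance", ds$spine1, fv$spine1)
  add("spine2", "distance", ds$spine2, fv$spine2)
  add("spine3", "distance", ds$spine3, fv$spine3)
  do.call(rbind, rows)
}

#' Named fixture presets
#'
#' Reads the preset table shipped with the package (a JSON document of
#' named \code{\link{toy_kinase_spec}} arguments) and returns the specs.
#'
#' @param name Optional preset name; NULL returns all.
#' @return A ToyKinaseSpec, or a named list of them.
#' @export
toy_presets <- function(name = NULL) {
  path <- system.file("extdata", "toy_presets.json", package = "kinactive",
                      mustWork = TRUE)
  defs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mk <- function(d) do.call(toy_kinase_spec, d)
  if (!is.null(name)) {
    if (!name %in% names(defs)) stop("unknown preset '", name, "'", call. = FALSE)
    return(mk(defs[[name]]))
  }
  lapply(defs, mk)
}

#' Add a substrate peptide chain to a toy kinase
#'
#' Builds an 11-residue extended peptide (P-5..P+5) in chain B with a
#' hydroxyl residue at P0 and places it rigidly so the P0 hydroxyl oxygen
#' sits at the requested distance from the enzyme's HRD-Asp side-chain
#' oxygen, approaching from above (away from the enzyme APE8 site) unless
#' \code{at_ape8_site} simulates a domain-swapped pose.
#'
#' @param model,map Enzyme fixture and motif map.
#' @param d_oh_asp Hydroxyl-O to Asp-Od1 distance (Angstroms).
#' @param restype "SER", "THR" or "TYR" at P0.
#' @param p0 Residue number given to the phosphoacceptor.
#' @param at_ape8_site If TRUE, place the hydroxyl at the enzyme's APE8
#'   gamma-oxygen position instead (domain-swap signature).
#' @return The model with chain B appended.
#' @export
add_substrate_chain <- function(model, map, d_oh_asp = 3.0, restype = "SER",
                                p0 = 501L, at_ape8_site = FALSE) {
  stopifnot(restype %in% c("SER", "THR", "TYR"))
  oh_name <- unname(c(SER = "OG", THR = "OG1", TYR = "OH")[restype])
  types <- rep("GLY", 11L); types[6L] <- restype
  pep <- .build_peptide(data.frame(resno = (p0 - 5L):(p0 + 5L), type = types,
                                   phi = -120, psi = 130,
                                   chi1 = ifelse(types == restype, -65, NA),
                                   stringsAsFactors = FALSE), chain = "B")
  od1 <- atom_xyz(model, map$chain_id, map$res_hrd_asp, "OD1")
  od2 <- atom_xyz(model, map$chain_id, map$res_hrd_asp, "OD2")
  if (is.null(od1)) stop("enzyme HRD-Asp OD1 not found", call. = FALSE)
  ape8 <- actloop_index(map, "APE8")
  site <- atom_xyz(model, map$chain_id, ape8, "OG1") %||%
    atom_xyz(model, map$chain_id, ape8, "OG") %||%
    .cbeta_or_virtual(model, map$chain_id, ape8)
  # away from the APE8 side ("from above") and away from OD2, so the
  # requested distance is the minimum over both carboxylate oxygens
  u <- .unit(.unit(od1 - site) +
               if (is.null(od2)) 0 else .unit(od1 - od2))
  target <- if (at_ape8_site) site else od1 + d_oh_asp * u
  ioh <- which(pep$resno == p0 & pep$elety == oh_name)
  ica <- which(pep$resno == p0 & pep$elety == "CA")
  pep <- .orient_and_place(pep, ioh, ica, u, target)
  model$atoms <- rbind(model$atoms, pep)
  model
}

#' Synthetic AlphaFold-style confidence scores
#'
#' @param n_residues Number of residues.
#' @param loop Integer indices of the activation loop.
#' @param pae_profile "uniform" (constant \code{pae_value}), "two_block"
#'   (\code{pae_in} within the loop columns, \code{pae_out} elsewhere) or
#'   "random" (uniform in [0, pae_max], reproducible by seed).
#' @param pae_value,pae_in,pae_out,pae_max Profile parameters (Angstroms).
#' @param plddt_value Constant per-residue pLDDT (default 90); may be a
#'   full-length vector.
#' @param seed Seed for the "random" profile.
#' @return \code{\link{prediction_scores}}.
#' @export
synth_prediction_scores <- function(n_residues, loop,
                                    pae_profile = c("uniform", "two_block",
                                                    "random"),
                                    pae_value = 0, pae_in = 2, pae_out = 10,
                                    pae_max = 20, plddt_value = 90,
                                    seed = 1L) {
  pae_profile <- match.arg(pae_profile)
  loop <- as.integer(loop)
  if (any(loop < 1L | loop > n_residues))
    stop("loop is not a subset of residues", call. = FALSE)
  pae <- switch(pae_profile,
    uniform = matrix(pae_value, n_residues, n_residues),
    two_block = {
      m <- matrix(pae_out, n_residues, n_residues)
      m[, loop] <- pae_in
      m
    },
    random = matrix(.lcg_stream(seed, n_residues^2) * pae_max,
                    n_residues, n_residues))
  plddt <- if (length(plddt_value) == n_residues) plddt_value
           else rep(plddt_value[1L], n_residues)
  prediction_scores(pae, plddt)
}
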