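# Superposition on the C-terminal domain and activation-loop backbone
# RMSD, following the benchmarking conventions: fit on the CA atoms of
# the 40 residues C-terminal to the APE motif, then measure RMSD over the
# N, CA, C, O atoms of the activation-loop window without refitting.

#' Least-squares rigid superposition (Kabsch)
#'
#' @param mobile,reference n x 3 coordinate matrices of paired atoms.
#' @return list(rotation 3x3 with det +1, translation 3-vector, rmsd over
#'   the fit atoms, n).  Apply as \code{x \%*\% t(rotation) + translation}.
#' @export
kabsch <- function(mobile, reference) {
  stopifnot(nrow(mobile) == nrow(reference), ncol(mobile) == 3L)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)        # proper rotation even for mirror input
  t <- cr - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, t, "+")
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((moved - reference)^2))), n = nrow(mobile))
}

# residue pairing of the C-terminal-domain fit window: offsets 1..40
# after APE1, paired by offset
#' @keywords internal
.ctd_pairs <- function(mobile, reference, map_mobile, map_reference,
                       window = 40L) {
  am <- ar <- NULL
  for (off in seq_len(window)) {
    pm <- atom_xyz(mobile, map_mobile$chain_id, map_mobile$res_ape_glu + off, "CA")
    pr <- atom_xyz(reference, map_reference$chain_id,
                   map_reference$res_ape_glu + off, "CA")
    if (is.null(pm) || is.null(pr)) next
    am <- rbind(am, pm); ar <- rbind(ar, pr)
  }
  list(mobile = am, reference = ar)
}

#' Superpose two kinases on their C-terminal domains
#'
#' Fits the mobile structure onto the reference by least squares over the
#' paired CA atoms of the 40 residues C-terminal to the APE motif
#' (missing residues are skipped pairwise; at least 20 pairs required).
#'
#' @param mobile,reference StructureModels.
#' @param map_mobile,map_reference Motif maps addressing each chain.
#' @return Object of class \code{"SuperpositionResult"}: rotation,
#'   translation, fit_rmsd, n_fit_atoms.
#' @export
superpose_ctd <- function(mobile, reference, map_mobile, map_reference) {
  pr <- .ctd_pairs(mobile, reference, map_mobile, map_reference)
  if (is.null(pr$mobile) || nrow(pr$mobile) < 20L)
    stop(sprintf("insufficient overlap: %d shared CA in the C-terminal window (need >= 20)",
                 if (is.null(pr$mobile)) 0L else nrow(pr$mobile)), call. = FALSE)
  k <- kabsch(pr$mobile, pr$reference)
  out <- list(rotation = k$rotation, translation = k$translation,
              fit_rmsd = k$rmsd, n_fit_atoms = k$n)
  class(out) <- "SuperpositionResult"
  out
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("CTD superposition: fit RMSD %.3f A over %d CA atoms (det R = %+.0f)\n",
              x$fit_rmsd, x$n_fit_atoms, det(x$rotation)))
  invisible(x)
}

#' @keywords internal
.apply_transform <- function(model, sp) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  moved <- sweep(xyz %*% t(sp$rotation), 2, sp$translation, "+")
  model$atoms$x <- moved[, 1]; model$atoms$y <- moved[, 2]
  model$atoms$z <- moved[, 3]
  model
}

# activation-loop residue pairing by index from each end.  For unequal
# loop lengths the NT indices DFG1..DFGk and CT indices APE1..APE(m-k)
# with m = min length, k = ceiling(m/2): middle residues are truncated.
#' @keywords internal
.loop_pair_labels <- function(map_a, map_b, mode) {
  la <- map_a$res_ape_glu - map_a$res_dfg_asp + 1L
  lb <- map_b$res_ape_glu - map_b$res_dfg_asp + 1L
  if (mode == "full") {
    m <- min(la, lb)
    k <- as.integer(ceiling(m / 2))
    c(paste0("DFG", seq_len(k)), paste0("APE", rev(seq_len(m - k))))
  } else if (mode == "ntct") {
    c(paste0("DFG", seq_len(min(9L, la, lb))),
      paste0("APE", rev(seq_len(min(15L, la, lb)))))
  } else {  # nt5ct15: the template-similarity screen window
    c(paste0("DFG", seq_len(min(5L, la, lb))),
      paste0("APE", rev(seq_len(min(15L, la, lb)))))
  }
}

#' Activation-loop backbone RMSD after C-terminal-domain superposition
#'
#' Superposes on the C-terminal domains (\code{\link{superpose_ctd}}),
#' then measures RMSD over the paired backbone atoms (N, CA, C, O) of an
#' activation-loop window without refitting.  Residues are paired by
#' motif-anchored loop index (DFGn to DFGn, APEn to APEn), so loops of
#' unequal length are truncated in the middle.
#'
#' @param mobile,reference StructureModels.
#' @param map_mobile,map_reference Motif maps.
#' @param mode Window: \code{"full"} (whole DFG..APE span),
#'   \code{"ntct"} (first 9 + last 15 residues) or \code{"nt5ct15"}
#'   (first 5 + last 15; the 1.5 A template-similarity screen window).
#' @return list(rmsd, n_atoms, n_residues, superposition).
#' @export
actloop_rmsd <- function(mobile, reference, map_mobile, map_reference,
                         mode = c("full", "ntct", "nt5ct15")) {
  mode <- match.arg(mode)
  sp <- superpose_ctd(mobile, reference, map_mobile, map_reference)
  mobile_fit <- .apply_transform(mobile, sp)
  labels <- .loop_pair_labels(map_mobile, map_reference, mode)
  # deduplicate overlapping NT/CT windows within each structure
  res_m <- vapply(labels, function(l) actloop_index(map_mobile, l), 0L)
  res_r <- vapply(labels, function(l) actloop_index(map_reference, l), 0L)
  keep <- !duplicated(res_m) & !duplicated(res_r)
  res_m <- res_m[keep]; res_r <- res_r[keep]
  am <- ar <- NULL
  nres <- 0L
  for (i in seq_along(res_m)) {
    got <- FALSE
    for (nm in c("N", "CA", "C", "O")) {
      pm <- atom_xyz(mobile_fit, map_mobile$chain_id, res_m[i], nm)
      pr <- atom_xyz(reference, map_reference$chain_id, res_r[i], nm)
      if (is.null(pm) || is.null(pr)) next
      am <- rbind(am, pm); ar <- rbind(ar, pr); got <- TRUE
    }
    if (got) nres <- nres + 1L
  }
  if (is.null(am))
    stop("no paired backbone atoms in the selected window", call. = FALSE)
  list(rmsd = sqrt(mean(rowSums((am - ar)^2))), n_atoms = nrow(am),
       n_residues = nres, superposition = sp)
}
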