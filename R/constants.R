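# Default numeric cutoffs for the active-kinase criteria, and the built-in
# per-kinase exception tables.  Every cutoff can be overridden through
# active_config(); the defaults are the published criteria.

#' Configuration of all numeric cutoffs used by the classifier
#'
#' Returns the default criteria thresholds, optionally overridden.  Upper
#' bounds are strict "<" and lower bounds strict ">" throughout.
#'
#' @param ... Named overrides of any default (e.g.
#'   \code{active_config(saltbridge_max = 4)}).
#' @return A named list of cutoffs with class \code{"active_config"}:
#' \describe{
#'   \item{saltbridge_max}{Lys-Nz to Glu-Oe distance for SaltBr-in (3.6 A).}
#'   \item{hbond_max}{DFG6/XHRD backbone N-O distance for ActLoopNT-in (3.6 A).}
#'   \item{ape9_max_nontyr, ape9_max_tyr}{APE9-Ca / HRD-Arg-O upper bounds
#'     (6 and 8 A).}
#'   \item{ape10_max}{APE10-Cb / DFG4-Ca upper bound, non-TYR (8 A).}
#'   \item{ape11_bounds, ape12_bounds}{APE11/APE12-Cb to DFG4-Ca open
#'     intervals, non-TYR ((8,14) and (7,14) A).}
#'   \item{spatial_glu4_in_max, spatial_lys_in_min}{DFGin: Phe anchor within
#'     11 A of Glu4-Ca and at least 11 A from Lys-Ca.}
#'   \item{spatial_glu4_out_min, spatial_lys_out_max}{DFGout: Phe anchor
#'     beyond 11 A of Glu4-Ca and within 14 A of Lys-Ca.}
#'   \item{spine_max}{regulatory-spine contact distance (5.0 A; reported,
#'     never a criterion).}
#'   \item{plddt_min, plddt_strict}{pLDDT gate for ipSAE rows (60, strict >).}
#'   \item{d0}{ipSAE distance scale (4 A).}
#'   \item{contact_cutoff}{substrate/activation-loop any-atom contact (5 A).}
#'   \item{phospho_cutoff}{hydroxyl-O to HRD-Asp-O search distance (4.5 A).}
#'   \item{swap_cutoff}{domain-swap exclusion: candidate hydroxyl within
#'     this distance of the enzyme's own APE8 gamma-oxygen site (1.5 A).}
#' }
#' @export
active_config <- function(...) {
  cfg <- list(
    saltbridge_max      = 3.6,
    hbond_max           = 3.6,
    ape9_max_nontyr     = 6,
    ape9_max_tyr        = 8,
    ape10_max           = 8,
    ape11_bounds        = c(8, 14),
    ape12_bounds        = c(7, 14),
    spatial_glu4_in_max = 11,
    spatial_lys_in_min  = 11,
    spatial_glu4_out_min = 11,
    spatial_lys_out_max = 14,
    spine_max           = 5,
    plddt_min           = 60,
    plddt_strict        = TRUE,
    d0                  = 4,
    contact_cutoff      = 5,
    phospho_cutoff      = 4.5,
    swap_cutoff         = 1.5
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cfg[names(ov)] <- ov
  }
  class(cfg) <- "active_config"
  cfg
}

#' @keywords internal
config_digest <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x, digits = 12),
                                                       collapse = ","), ""),
             sep = "=", collapse = ";")
  # small deterministic polynomial hash; provenance only
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 268435399
  sprintf("%07x", h)
}

# Built-in exception lists, keyed by the HUGO gene part of a
# family-prefixed kinase id (e.g. "OTHER_WNK1" -> "WNK1").

.SKIP_SALTBRIDGE_GENES <- c("WNK1", "WNK2", "WNK3", "WNK4",
                            "MAP3K12", "MAP3K13")

.NOAPE_GENES <- c("HASPIN", "TP53RK", "PKDCC")

# kinases without the conserved alphaF-helix Asp: HRD dihedral criterion
# is skipped for these
.NO_AF_ASP_GENES <- c("PIM1", "PIM2", "PIM3", "HASPIN", "PKDCC",
                      "AATK", "LMTK2", "LMTK3")

#' Built-in per-kinase exception tables
#'
#' @return A list with character vectors \code{skip_saltbridge},
#'   \code{noape} and \code{no_af_asp} of gene names (without the family
#'   prefix) for which, respectively, the salt-bridge criterion is skipped,
#'   no APE motif exists (no ActLoopCT requirement), and the HRD dihedral
#'   criterion is skipped for lack of the alphaF-helix Asp.
#' @export
kinase_exceptions <- function() {
  list(skip_saltbridge = .SKIP_SALTBRIDGE_GENES,
       noape = .NOAPE_GENES,
       no_af_asp = .NO_AF_ASP_GENES)
}

#' @keywords internal
.gene_of <- function(kinase_id) {
  sub("^[A-Za-z0-9]+_", "", kinase_id)
}

#' @keywords internal
.family_of <- function(kinase_id) {
  if (grepl("_", kinase_id)) sub("_.*$", "", kinase_id) else ""
}
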