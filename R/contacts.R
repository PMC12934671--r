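# Substrate-bound / autophosphorylation pose detection across crystal
# symmetry mates, domain-swap exclusion, and substrate-by-activation-loop
# contact-frequency maps.

.HYDROXYL_ATOMS <- c(SER = "OG", THR = "OG1", TYR = "OH",
                     SEP = "OG", TPO = "OG1", PTR = "OH")

#' Find candidate phosphoacceptor poses
#'
#' Searches for Ser/Thr/Tyr hydroxyl oxygens of one chain within
#' hydrogen-bonding distance (4.5 A heavy-atom cutoff) of the HRD-Asp
#' side-chain oxygens of a mapped kinase chain in another chain --
#' including crystal-symmetry images from the 3x3x3 block of unit cells
#' when the cell is present and \code{use_symmetry} is TRUE.  Same-chain
#' (identity image) pairs are excluded.  Phospho-residues (SEP/TPO/PTR)
#' count as their parent type when the oxygen exists.
#'
#' @param model StructureModel.
#' @param maps KinaseMotifMap or list of them (the enzyme chains).
#' @param use_symmetry Search symmetry mates (requires cell + space group).
#' @param shell Unit-cell shell for the symmetry search (1 = 3x3x3).
#' @param config \code{\link{active_config}} (cutoff
#'   \code{phospho_cutoff}).
#' @return data.frame of hits: enzyme_chain, substrate_chain,
#'   substrate_resno, substrate_restype, substrate_atom, d_oh_asp,
#'   is_symmetry_mate, op_index, offset, swap_flag (NA until
#'   \code{\link{flag_domain_swap}} is applied).
#' @export
find_phosphoacceptors <- function(model, maps, use_symmetry = TRUE,
                                  shell = 1L, config = active_config()) {
  if (inherits(maps, "KinaseMotifMap")) maps <- list(maps)
  cutoff <- config$phospho_cutoff
  hits <- list()
  any_enzyme <- FALSE

  # substrate candidate hydroxyls from an atom table
  hydroxyls <- function(at) {
    sel <- at$resid %in% names(.HYDROXYL_ATOMS) &
      at$elety == unname(.HYDROXYL_ATOMS[at$resid])
    at[which(sel), , drop = FALSE]
  }
  add_hits <- function(map, asp_o, sub_at, sub_chain_label, sym, opi, off) {
    hs <- hydroxyls(sub_at)
    if (!nrow(hs)) return(invisible())
    for (r in seq_len(nrow(hs))) {
      p <- as.numeric(hs[r, c("x", "y", "z")])
      d <- min_pair_distance(p, asp_o)
      if (!is.na(d) && d <= cutoff) {
        hits[[length(hits) + 1L]] <<- data.frame(
          enzyme_chain = map$chain_id, substrate_chain = sub_chain_label,
          substrate_resno = hs$resno[r], substrate_restype = hs$resid[r],
          substrate_atom = hs$elety[r], d_oh_asp = d,
          is_symmetry_mate = sym, op_index = opi,
          offset = paste(off, collapse = ","), swap_flag = NA,
          stringsAsFactors = FALSE)
      }
    }
  }

  neighbors <- NULL
  if (use_symmetry && !is.null(model$cell) && !is.null(model$spacegroup))
    neighbors <- expand_crystal_neighbors(model, shell = shell)

  for (map in maps) {
    if (is.na(map$res_hrd_asp)) next
    rt <- res_table(model, map$chain_id, map$res_hrd_asp)
    asp_o <- as.matrix(rt[rt$elety %in% c("OD1", "OD2"),
                          c("x", "y", "z"), drop = FALSE])
    if (!nrow(asp_o)) next
    any_enzyme <- TRUE
    # deposited asymmetric unit: other chains
    for (ch in setdiff(unique(model$atoms$chain), map$chain_id))
      add_hits(map, asp_o, model$atoms[model$atoms$chain == ch, , drop = FALSE],
               ch, FALSE, 1L, c(0, 0, 0))
    # symmetry images of every chain (including the enzyme's own)
    if (!is.null(neighbors)) {
      for (cp in neighbors)
        add_hits(map, asp_o, cp$atoms,
                 sprintf("%s[op%d;%s]", cp$chain, cp$op_index,
                         paste(cp$offset, collapse = ",")),
                 TRUE, cp$op_index, cp$offset)
    }
  }
  if (!any_enzyme)
    stop("input error: no mapped kinase chain with HRD-Asp side-chain ",
         "oxygens", call. = FALSE)
  if (!length(hits))
    return(data.frame(enzyme_chain = character(), substrate_chain = character(),
                      substrate_resno = integer(), substrate_restype = character(),
                      substrate_atom = character(), d_oh_asp = numeric(),
                      is_symmetry_mate = logical(), op_index = integer(),
                      offset = character(), swap_flag = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Domain-swap exclusion flag for a phosphoacceptor hit
#'
#' Activation-loop swapped dimers place the swapped Thr hydroxyl below the
#' HRD-Asp, at the same position in sequence and structure as the enzyme's
#' own intramolecular APE8 hydrogen bond.  A hit is flagged as a swap when
#' its hydroxyl oxygen lies within \code{swap_cutoff} (1.5 A, strict) of
#' the enzyme's APE8 gamma-oxygen site -- measured when APE8 is Ser/Thr
#' with the atom present, otherwise virtually reconstructed at the ideal
#' gauche-minus position from the APE8 backbone.
#'
#' @param hit_xyz 3-vector: the candidate hydroxyl oxygen position.
#' @param model StructureModel (the enzyme).
#' @param map Enzyme KinaseMotifMap.
#' @param config \code{\link{active_config}}.
#' @return TRUE (swap, exclude), FALSE, or NA when the APE8 site cannot be
#'   placed (hit retained with a warning upstream).
#' @export
flag_domain_swap <- function(hit_xyz, model, map, config = active_config()) {
  if (map$group == "noAPE") return(NA)
  ape8 <- actloop_index(map, "APE8")
  site <- atom_xyz(model, map$chain_id, ape8, "OG")
  if (is.null(site)) site <- atom_xyz(model, map$chain_id, ape8, "OG1")
  if (is.null(site)) {
    n <- atom_xyz(model, map$chain_id, ape8, "N")
    ca <- atom_xyz(model, map$chain_id, ape8, "CA")
    cb <- .cbeta_or_virtual(model, map$chain_id, ape8)
    if (is.null(n) || is.null(ca) || is.null(cb)) return(NA)
    site <- .nerf(n, ca, cb, bond = 1.42, angle = 110.5, torsion = -60)
  }
  .euclid(hit_xyz, site) < config$swap_cutoff
}

#' Apply the swap flag to a table of hits
#'
#' @param hits Output of \code{\link{find_phosphoacceptors}}.
#' @param model,maps Enzyme model and motif map(s).
#' @param config \code{\link{active_config}}.
#' @return \code{hits} with the swap_flag column filled (NA =
#'   indeterminate, retained with warning).
#' @export
flag_domain_swaps <- function(hits, model, maps, config = active_config()) {
  if (inherits(maps, "KinaseMotifMap")) maps <- list(maps)
  by_chain <- stats::setNames(maps, vapply(maps, function(m) m$chain_id, ""))
  for (i in seq_len(nrow(hits))) {
    map <- by_chain[[hits$enzyme_chain[i]]]
    if (is.null(map)) next
    # hit position: the hydroxyl may belong to a symmetry image, whose
    # coordinates were recorded at search time through d_oh_asp only, so
    # re-derive from the deposited chain when not a symmetry mate
    if (hits$is_symmetry_mate[i]) {
      cp <- expand_crystal_neighbors(model, shell = max(abs(as.integer(
        strsplit(hits$offset[i], ",")[[1]]))))
      at <- NULL
      for (c0 in cp) {
        if (c0$op_index == hits$op_index[i] &&
            paste(c0$offset, collapse = ",") ==
            sub("^.*\\[op[0-9]+;(.*)\\]$", "\\1", hits$substrate_chain[i]) &&
            startsWith(hits$substrate_chain[i], c0$chain)) { at <- c0$atoms; break }
      }
      if (is.null(at)) { hits$swap_flag[i] <- NA; next }
      row <- at[at$resno == hits$substrate_resno[i] &
                  at$elety == hits$substrate_atom[i], , drop = FALSE]
    } else {
      row <- model$atoms[model$atoms$chain == hits$substrate_chain[i] &
                           model$atoms$resno == hits$substrate_resno[i] &
                           model$atoms$elety == hits$substrate_atom[i], ,
                         drop = FALSE]
    }
    if (!nrow(row)) { hits$swap_flag[i] <- NA; next }
    fl <- flag_domain_swap(as.numeric(row[1L, c("x", "y", "z")]), model, map,
                           config)
    if (is.na(fl))
      warning("swap flag indeterminate for hit ", i, "; hit retained",
              call. = FALSE)
    hits$swap_flag[i] <- fl
  }
  hits
}

.NT_LABELS <- paste0("DFG", 1:9)
.CT_LABELS <- paste0("APE", 15:1)

#' Substrate / activation-loop contact map
#'
#' Counts heavy-atom pairs within 5 A between each substrate residue of
#' the P-5..P+5 window and each activation-loop residue, the loop indexed
#' from both ends (DFG1..DFG9 and APE15..APE1).
#'
#' @param model StructureModel containing both chains.
#' @param map Enzyme KinaseMotifMap.
#' @param substrate_chain Substrate chain id.
#' @param p0 Residue number of the phosphoacceptor in the substrate chain.
#' @param config \code{\link{active_config}} (cutoff
#'   \code{contact_cutoff}).
#' @return Object of class \code{"ContactMap"}: integer matrix counts
#'   (11 substrate positions x 24 loop labels), n_structures = 1.
#' @export
contact_map <- function(model, map, substrate_chain, p0,
                        config = active_config()) {
  subs <- paste0("P", sprintf("%+d", -5:5))
  loop_labels <- c(.NT_LABELS, .CT_LABELS)
  counts <- matrix(0L, nrow = 11L, ncol = length(loop_labels),
                   dimnames = list(subs, loop_labels))
  cutoff <- config$contact_cutoff
  heavy <- function(chain, resno) {
    rt <- model$atoms[model$atoms$chain == chain & model$atoms$resno == resno, ,
                      drop = FALSE]
    if (!nrow(rt)) return(NULL)
    as.matrix(rt[, c("x", "y", "z")])
  }
  for (si in seq_along(-5:5)) {
    s_at <- heavy(substrate_chain, p0 + (-5:5)[si])
    if (is.null(s_at)) next
    for (li in seq_along(loop_labels)) {
      lr <- tryCatch(actloop_index(map, loop_labels[li]), error = function(e) NA)
      if (is.na(lr)) next
      l_at <- heavy(map$chain_id, lr)
      if (is.null(l_at)) next
      d2 <- outer(rowSums(s_at^2), rowSums(l_at^2), "+") -
        2 * tcrossprod(s_at, l_at)
      counts[si, li] <- sum(d2 < cutoff^2)
    }
  }
  cm <- list(counts = counts, n_structures = 1L)
  class(cm) <- "ContactMap"
  cm
}

#' Average contact maps across structures
#'
#' @param maps List of \code{\link{contact_map}} results with identical
#'   axes.
#' @return list(mean = element-wise mean matrix, per_loop_residue =
#'   mean total contacts of each loop residue per structure, highlighted =
#'   loop labels whose per-structure mean is >= 1, n_structures).
#' @export
average_contacts <- function(maps) {
  if (!length(maps)) stop("empty list of contact maps", call. = FALSE)
  dims <- lapply(maps, function(m) dimnames(m$counts))
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("aggregation error: contact maps have mismatched axes", call. = FALSE)
  tot <- Reduce(`+`, lapply(maps, function(m) m$counts))
  n <- sum(vapply(maps, function(m) m$n_structures, 0L))
  mean_map <- tot / n
  per_res <- colSums(mean_map)
  list(mean = mean_map, per_loop_residue = per_res,
       highlighted = names(per_res)[per_res >= 1], n_structures = n)
}
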