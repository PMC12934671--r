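# Intramolecular ipSAE scoring of the activation loop in predicted models,
# and selection of the best active model.
#
# The score for a model is
#   max over aligned residues i outside the loop (pLDDT_i > 60) of
#   mean over loop residues j of  1 / (1 + (PAE_ij / d0)^2)
# with d0 fixed at 4 A so that scores are comparable across loops of
# different lengths.

#' Construct PredictionScores
#'
#' @param pae Square predicted-aligned-error matrix in Angstroms;
#'   \code{pae[i, j]} is the expected error at residue j when the model is
#'   aligned on residue i.
#' @param plddt Per-residue confidence, 0-100, same length as the matrix
#'   side.
#' @param index_map Optional data.frame (chain, resno) mapping residue
#'   order to author numbering.
#' @return Object of class \code{"PredictionScores"}.
#' @export
prediction_scores <- function(pae, plddt, index_map = NULL) {
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae)) stop("PAE matrix must be square", call. = FALSE)
  if (any(pae < 0)) stop("PAE entries must be non-negative", call. = FALSE)
  if (length(plddt) != nrow(pae))
    stop("plddt length must equal the PAE side", call. = FALSE)
  s <- list(pae = pae, plddt = as.numeric(plddt), index_map = index_map)
  class(s) <- "PredictionScores"
  s
}

#' Read AlphaFold/ColabFold scores
#'
#' Reads a PAE JSON (field \code{pae} or \code{predicted_aligned_error},
#' possibly wrapped in a one-element array) and per-residue pLDDT either
#' from a \code{plddt} JSON field or from the B-factor column of the model
#' coordinates.
#'
#' @param pae_path Path to the PAE JSON.
#' @param model Optional StructureModel whose CA B-factors carry pLDDT.
#' @param chain Chain of \code{model} to take pLDDT from (default: first).
#' @return \code{\link{prediction_scores}}.
#' @export
read_prediction_scores <- function(pae_path, model = NULL, chain = NULL) {
  j <- jsonlite::fromJSON(pae_path)
  if (is.data.frame(j)) j <- as.list(j)
  if (is.null(names(j)) && length(j) == 1L) j <- j[[1L]]
  pae <- j$pae %||% j$predicted_aligned_error
  if (is.null(pae)) stop("no 'pae' or 'predicted_aligned_error' field in ",
                         pae_path, call. = FALSE)
  if (is.list(pae) && !is.matrix(pae)) pae <- do.call(rbind, pae)
  pae <- as.matrix(pae)
  plddt <- j$plddt
  index_map <- NULL
  if (is.null(plddt)) {
    if (is.null(model))
      stop("PAE JSON has no plddt field; supply the model coordinates",
           call. = FALSE)
    a <- model$atoms[!model$atoms$hetero & model$atoms$elety == "CA", ]
    if (!is.null(chain)) a <- a[a$chain == chain, ]
    plddt <- a$b
    index_map <- data.frame(chain = a$chain, resno = a$resno,
                            stringsAsFactors = FALSE)
  }
  prediction_scores(pae, as.numeric(plddt), index_map)
}

#' Intramolecular ipSAE of the activation loop
#'
#' @param scores \code{\link{prediction_scores}}.
#' @param loop Integer indices (residue order) of the activation-loop
#'   residues; must be a non-empty strict subset.
#' @param d0 Distance scale in Angstroms (default 4).
#' @param plddt_min pLDDT gate for the aligned residues i (default 60).
#' @param strict Gate comparison: TRUE uses pLDDT > plddt_min (the
#'   formula), FALSE uses >=.
#' @param domain Optional integer indices restricting the aligned residues
#'   i to the kinase domain (e.g. the motif map's span); flanking tag
#'   residues are excluded this way.
#' @return Object of class \code{"LoopScore"}: value in (0, 1], d0,
#'   n_aligned (eligible i count) and argmax_residue.
#' @export
ipsae_actloop <- function(scores, loop, d0 = 4, plddt_min = 60,
                          strict = TRUE, domain = NULL) {
  n <- nrow(scores$pae)
  loop <- sort(unique(as.integer(loop)))
  if (!length(loop)) stop("loop index set is empty", call. = FALSE)
  if (any(loop < 1L | loop > n)) stop("loop indices out of range", call. = FALSE)
  if (length(loop) >= n) stop("loop must be a strict subset of residues",
                              call. = FALSE)
  cand <- setdiff(if (is.null(domain)) seq_len(n) else as.integer(domain), loop)
  gate <- if (strict) scores$plddt[cand] > plddt_min
          else scores$plddt[cand] >= plddt_min
  eligible <- cand[gate]
  if (!length(eligible))
    stop("scoring error: no aligned residue outside the loop passes the ",
         "pLDDT gate", call. = FALSE)
  sim <- 1 / (1 + (scores$pae[eligible, loop, drop = FALSE] / d0)^2)
  rowmean <- rowMeans(sim)
  k <- which.max(rowmean)
  out <- list(value = rowmean[[k]], d0 = d0, n_aligned = length(eligible),
              argmax_residue = eligible[k])
  class(out) <- "LoopScore"
  out
}

#' @export
print.LoopScore <- function(x, ...) {
  cat(sprintf("ipSAE(activation loop) = %.4f  [d0 = %g A, %d aligned residues, argmax i = %d]\n",
              x$value, x$d0, x$n_aligned, x$argmax_residue))
  invisible(x)
}

#' Select the best active model
#'
#' Restricts the candidates to those labeled Active and returns the one
#' with the highest activation-loop ipSAE; exact ties are broken by the
#' lexicographically lowest model name.
#'
#' @param candidates List; each element has \code{name}, \code{label} (an
#'   activity label or an ActivityReport) and \code{score} (a LoopScore or
#'   a number).
#' @return list(selected = name or NA when no Active candidate, ranking =
#'   data.frame of all candidates sorted by score).
#' @export
select_best_model <- function(candidates) {
  if (!length(candidates)) stop("candidate list is empty", call. = FALSE)
  get_lab <- function(x) if (inherits(x, "ActivityReport")) x$label else as.character(x)
  get_sc <- function(x) if (inherits(x, "LoopScore")) x$value else as.numeric(x)
  rk <- data.frame(
    name = vapply(candidates, function(c) as.character(c$name), ""),
    label = vapply(candidates, function(c) get_lab(c$label), ""),
    ipsae = vapply(candidates, function(c) get_sc(c$score), 0),
    stringsAsFactors = FALSE)
  rk <- rk[order(-rk$ipsae, rk$name), , drop = FALSE]
  rownames(rk) <- NULL
  act <- rk[rk$label == "Active", , drop = FALSE]
  selected <- if (nrow(act)) act$name[1L] else NA_character_
  list(selected = selected, ranking = rk)
}

#' Activation-loop residue indices for a model
#'
#' Maps the motif map's loop span (DFG1 .. APE1 inclusive, author
#' numbering) to residue-order indices of the chain's CA trace, for use
#' with \code{\link{ipsae_actloop}}.
#'
#' @param model StructureModel.
#' @param map KinaseMotifMap.
#' @return list(loop = integer indices, domain = indices of all mapped
#'   chain residues).
#' @export
actloop_indices <- function(model, map) {
  a <- model$atoms[!model$atoms$hetero & model$atoms$elety == "CA" &
                     model$atoms$chain == map$chain_id, ]
  ord <- order(a$resno)
  resno <- a$resno[ord]
  list(loop = which(resno >= map$res_dfg_asp & resno <= map$res_ape_glu),
       domain = seq_along(resno))
}
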