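# Tri-state Active / Inactive / None verdict from the six criterion
# states.  Precedence: any failed criterion makes the structure Inactive
# even when other criteria are unmeasurable; otherwise missing
# measurements give None; a structure is Active only when every
# non-skipped criterion passes.

#' Classify one kinase chain as Active / Inactive / None
#'
#' Evaluates the six criteria (spatial DFGin, dihedral BLAminus,
#' salt bridge, HRD, ActLoopNT, ActLoopCT) and combines them:
#' \enumerate{
#'   \item any criterion "out" (for the dihedral criterion: any label
#'     other than DFGin-BLAminus) makes the chain \code{Inactive};
#'   \item otherwise, if the spatial, dihedral, salt-bridge or HRD state
#'     is unmeasurable the chain is \code{None};
#'   \item otherwise, if ActLoopNT or ActLoopCT is unmeasurable the chain
#'     is \code{None};
#'   \item otherwise \code{Active}.
#' }
#' Skipped criteria (per-kinase exceptions) count as neither required
#' passes nor failures.  Callers mark pseudokinases explicitly; they are
#' not classified.
#'
#' @param model StructureModel.
#' @param map KinaseMotifMap.
#' @param config \code{\link{active_config}}.
#' @param pseudokinase If TRUE the chain is not assessed and the label is
#'   "Pseudo-skip".
#' @return Object of class \code{"ActivityReport"}: label, per-criterion
#'   states, the feature vector, and notes recording skips.
#' @export
classify <- function(model, map, config = active_config(),
                     pseudokinase = FALSE) {
  if (!any(model$atoms$chain == map$chain_id & !model$atoms$hetero))
    stop("chain '", map$chain_id, "' not present in model '",
         model$entry_id, "'", call. = FALSE)
  fv <- compute_features(model, map)
  notes <- character()

  spatial <- .spatial_from_features(fv, config)
  xdf <- .xdf_from_features(fv)
  crit <- list(
    spatial = list(name = "spatial", label = spatial,
                   state = if (spatial == "None") "none"
                           else if (spatial == "DFGin") "in" else "out"),
    dihedral = list(name = "dihedral", label = xdf,
                    state = if (xdf == "None") "none"
                            else if (xdf == "BLAminus") "in" else "out"),
    saltbr = {
      if (map$skip_saltbridge) {
        notes <- c(notes, "salt-bridge criterion skipped (built-in exception)")
        list(name = "saltbr", state = "skipped", distance = NA_real_)
      } else {
        st <- .state(if (is.na(fv$d_saltbridge)) NA
                     else fv$d_saltbridge < config$saltbridge_max)
        if (isTRUE(fv$saltbridge_atypical))
          notes <- c(notes, "atypical residues at salt-bridge positions; nearest equivalent terminal atoms used")
        list(name = "saltbr", state = st, distance = fv$d_saltbridge)
      }
    },
    hrd = {
      if (map$skip_hrd) {
        notes <- c(notes, "HRD criterion skipped (no alphaF-helix Asp)")
        list(name = "hrd", state = "skipped")
      } else list(name = "hrd", state = .hrd_from_features(fv))
    },
    actloopNT = list(name = "actloopNT",
                     state = .state(if (is.na(fv$d_dfg6_xhrd)) NA
                                    else fv$d_dfg6_xhrd < config$hbond_max),
                     distance = fv$d_dfg6_xhrd),
    actloopCT = {
      if (map$group == "noAPE") {
        notes <- c(notes, "no APE motif: no ActLoopCT requirement")
        list(name = "actloopCT", state = "skipped", detail = character())
      } else {
        ct <- .ct_from_features(fv, model, map, config)
        list(name = "actloopCT", state = ct$state, detail = ct$detail)
      }
    }
  )

  if (pseudokinase) {
    label <- "Pseudo-skip"
  } else {
    states <- vapply(crit, function(x) x$state, "")
    core <- states[c("spatial", "dihedral", "saltbr", "hrd")]
    loops <- states[c("actloopNT", "actloopCT")]
    label <- if (any(states == "out")) "Inactive"
             else if (any(core == "none")) "None"
             else if (any(loops == "none")) "None"
             else "Active"
  }
  rep <- list(kinase_id = map$kinase_id, entry_id = model$entry_id,
              chain_id = map$chain_id, label = label, criteria = crit,
              features = fv, notes = notes)
  class(rep) <- "ActivityReport"
  rep
}

#' @export
print.ActivityReport <- function(x, ...) {
  cat(sprintf("%s %s chain %s: %s\n", x$kinase_id, x$entry_id, x$chain_id,
              x$label))
  for (cr in x$criteria) {
    extra <- if (!is.null(cr$label)) paste0(" (", cr$label, ")")
             else if (!is.null(cr$distance) && !is.na(cr$distance))
               sprintf(" (%.2f A)", cr$distance)
             else ""
    cat(sprintf("  %-10s %s%s\n", cr$name, cr$state, extra))
    if (!is.null(cr$detail) && length(cr$detail))
      cat("             [", paste(names(cr$detail), cr$detail, sep = ":",
                                  collapse = " "), "]\n")
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Classify many chains
#'
#' @param models A StructureModel, or a named list of them keyed by entry
#'   id (each map row is applied to every model that contains its chain,
#'   or to the model named by an optional \code{entry_id} attribute).
#' @param maps List of KinaseMotifMap, or a single map.
#' @param config \code{\link{active_config}}.
#' @return data.frame with one row per (entry, chain), ordered by entry
#'   then chain: kinase_id, entry_id, chain_id, label, the six criterion
#'   states, the dihedral label and the key distances.  Per-chain failures
#'   are recorded in the \code{error} column and do not stop the batch.
#'   A label count table is attached as attribute \code{"summary"}.
#' @export
classify_batch <- function(models, maps, config = active_config()) {
  if (inherits(models, "StructureModel")) models <- list(models)
  if (inherits(maps, "KinaseMotifMap")) maps <- list(maps)
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$entry_id, "")
  rows <- list()
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    for (map in maps) {
      if (!any(model$atoms$chain == map$chain_id & !model$atoms$hetero)) next
      row <- tryCatch({
        r <- classify(model, map, config)
        st <- vapply(r$criteria, function(x) x$state, "")
        data.frame(kinase_id = r$kinase_id, entry_id = r$entry_id,
                   chain_id = r$chain_id, label = r$label,
                   spatial = r$criteria$spatial$label,
                   dihedral = r$criteria$dihedral$label,
                   saltbr = st["saltbr"], hrd = st["hrd"],
                   actloopNT = st["actloopNT"], actloopCT = st["actloopCT"],
                   d_saltbridge = r$features$d_saltbridge,
                   d_dfg6_xhrd = r$features$d_dfg6_xhrd,
                   d_ape9ca_hrdargO = r$features$d_ape9ca_hrdargO,
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(kinase_id = map$kinase_id, entry_id = model$entry_id,
                   chain_id = map$chain_id, label = NA_character_,
                   spatial = NA, dihedral = NA, saltbr = NA, hrd = NA,
                   actloopNT = NA, actloopCT = NA,
                   d_saltbridge = NA_real_, d_dfg6_xhrd = NA_real_,
                   d_ape9ca_hrdargO = NA_real_,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(kinase_id = character(), entry_id = character(),
                         chain_id = character(), label = character(),
                         spatial = character(), dihedral = character(),
                         saltbr = character(), hrd = character(),
                         actloopNT = character(), actloopCT = character(),
                         d_saltbridge = numeric(), d_dfg6_xhrd = numeric(),
                         d_ape9ca_hrdargO = numeric(), error = character(),
                         stringsAsFactors = FALSE)
  out <- out[order(out$entry_id, out$chain_id), , drop = FALSE]
  rownames(out) <- NULL
  cnt <- c(Active = sum(out$label == "Active", na.rm = TRUE),
           Inactive = sum(out$label == "Inactive", na.rm = TRUE),
           None = sum(out$label == "None", na.rm = TRUE))
  attr(out, "summary") <- cnt
  out
}
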