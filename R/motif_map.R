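# Motif maps: author residue numbers of the conserved kinase motifs needed
# by the criteria, plus the per-kinase exception flags.  Residue numbers
# are user input (mirroring a curated alignment); sequence-based detection
# is a convenience fallback with explicit ambiguity reporting.

#' Construct and validate a KinaseMotifMap
#'
#' Addresses the conserved motifs of one kinase chain: the beta3 Lys and
#' C-helix Glu of the N-terminal salt bridge, Glu4 (four residues after
#' the Glu), HPN7 (seventh residue from the start of the HPN motif), the
#' HRD motif (His/Arg/Asp; the catalytic Asp engages the substrate
#' hydroxyl), the activation loop start (DFG-Asp) and end (APE-Glu).
#'
#' @param kinase_id Family-prefixed gene label, e.g. "TYR_BTK".
#' @param chain_id Chain identifier in the structure.
#' @param res_dfg_asp,res_ape_glu Activation loop start/end (author
#'   numbering, inclusive).
#' @param res_hrd_his HRD His residue number; Arg and Asp default to the
#'   two following numbers.
#' @param res_hrd_arg,res_hrd_asp Optional explicit HRD Arg/Asp numbers.
#' @param res_saltbridge_lys,res_saltbridge_glu beta3 Lys and C-helix Glu.
#' @param res_glu4 Defaults to \code{res_saltbridge_glu + 4}.
#' @param res_hpn7 HPN7 residue (optional; needed for spine3 only).
#' @param group "TYR", "nonTYR" or "noAPE"; defaults from the family
#'   prefix of \code{kinase_id} and the built-in noAPE list.  WEE/PKMYT1
#'   kinases are treated as nonTYR.
#' @param has_aF_asp Presence of the alphaF-helix Asp; defaults from the
#'   built-in exception list.  FALSE skips the HRD criterion.
#' @param skip_saltbridge Defaults from the built-in exception list
#'   (WNK1-4, MAP3K12/13).
#' @return Object of class \code{"KinaseMotifMap"}.
#' @export
motif_map <- function(kinase_id, chain_id = "A",
                      res_dfg_asp, res_ape_glu,
                      res_hrd_his = NA, res_hrd_arg = NA, res_hrd_asp = NA,
                      res_saltbridge_lys = NA, res_saltbridge_glu = NA,
                      res_glu4 = NA, res_hpn7 = NA,
                      group = NULL, has_aF_asp = NULL,
                      skip_saltbridge = NULL) {
  gene <- .gene_of(kinase_id)
  fam <- .family_of(kinase_id)
  if (is.null(group)) {
    group <- if (gene %in% .NOAPE_GENES) "noAPE"
             else if (fam == "TYR") "TYR" else "nonTYR"
  }
  if (!group %in% c("TYR", "nonTYR", "noAPE"))
    stop("group must be TYR, nonTYR or noAPE", call. = FALSE)
  if (is.null(has_aF_asp)) has_aF_asp <- !(gene %in% .NO_AF_ASP_GENES)
  if (is.null(skip_saltbridge)) skip_saltbridge <- gene %in% .SKIP_SALTBRIDGE_GENES
  to_i <- function(x) if (is.null(x) || is.na(x)) NA_integer_ else as.integer(x)
  m <- list(kinase_id = kinase_id, chain_id = chain_id, group = group,
            res_saltbridge_lys = to_i(res_saltbridge_lys),
            res_saltbridge_glu = to_i(res_saltbridge_glu),
            res_glu4 = if (!is.na(to_i(res_glu4))) to_i(res_glu4)
                       else if (!is.na(to_i(res_saltbridge_glu)))
                         to_i(res_saltbridge_glu) + 4L else NA_integer_,
            res_hpn7 = to_i(res_hpn7),
            res_hrd_his = to_i(res_hrd_his),
            res_hrd_arg = if (!is.na(to_i(res_hrd_arg))) to_i(res_hrd_arg)
                          else if (!is.na(to_i(res_hrd_his)))
                            to_i(res_hrd_his) + 1L else NA_integer_,
            res_hrd_asp = if (!is.na(to_i(res_hrd_asp))) to_i(res_hrd_asp)
                          else if (!is.na(to_i(res_hrd_his)))
                            to_i(res_hrd_his) + 2L else NA_integer_,
            res_xhrd = if (!is.na(to_i(res_hrd_his)))
                         to_i(res_hrd_his) - 1L else NA_integer_,
            res_dfg_asp = to_i(res_dfg_asp),
            res_ape_glu = to_i(res_ape_glu),
            has_aF_asp = isTRUE(has_aF_asp),
            skip_saltbridge = isTRUE(skip_saltbridge),
            skip_hrd = !isTRUE(has_aF_asp))
  .validate_motif_map(m)
  class(m) <- "KinaseMotifMap"
  m
}

.validate_motif_map <- function(m, row = NULL) {
  where <- if (is.null(row)) m$kinase_id else sprintf("row %s (%s)", row, m$kinase_id)
  fail <- function(field, msg)
    stop(sprintf("invalid motif map for %s, field %s: %s", where, field, msg),
         call. = FALSE)
  if (is.na(m$res_dfg_asp) || is.na(m$res_ape_glu))
    fail("res_dfg_asp/res_ape_glu", "activation loop bounds are required")
  if (m$res_dfg_asp >= m$res_ape_glu)
    fail("res_dfg_asp", "must precede res_ape_glu")
  len <- m$res_ape_glu - m$res_dfg_asp + 1L
  if (m$group != "noAPE" && len < 18L)
    fail("res_ape_glu", sprintf(
      "activation loop length %d < 18; DFG1-DFG6 and APE12-APE1 would overlap", len))
  invisible(TRUE)
}

#' @export
print.KinaseMotifMap <- function(x, ...) {
  cat(sprintf("KinaseMotifMap %s chain %s (%s): loop %d..%d, HRD %s, K/E %s/%s%s\n",
              x$kinase_id, x$chain_id, x$group, x$res_dfg_asp, x$res_ape_glu,
              ifelse(is.na(x$res_hrd_his), "?", x$res_hrd_his),
              ifelse(is.na(x$res_saltbridge_lys), "?", x$res_saltbridge_lys),
              ifelse(is.na(x$res_saltbridge_glu), "?", x$res_saltbridge_glu),
              paste0(if (x$skip_saltbridge) " [saltbridge skipped]" else "",
                     if (x$skip_hrd) " [HRD skipped]" else "",
                     if (x$group == "noAPE") " [no ActLoopCT]" else "")))
  invisible(x)
}

#' Load motif maps from a CSV/TSV or JSON file
#'
#' Tabular input has one row per structure chain with a header; required
#' columns are \code{kinase_id}, \code{chain_id}, \code{res_dfg_asp},
#' \code{res_ape_glu}; the remaining \code{\link{motif_map}} arguments are
#' optional columns.  Explicit \code{group}, \code{has_aF_asp} and
#' \code{skip_saltbridge} columns override the built-in exception lists.
#' A JSON file holds an array of objects with the same field names.
#'
#' @param path File path (.csv, .tsv/.tab, or .json).
#' @return List of \code{KinaseMotifMap} objects.
#' @export
load_motif_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    sep <- if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      comment.char = "#", strip.white = TRUE)
  }
  need <- c("kinase_id", "chain_id", "res_dfg_asp", "res_ape_glu")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("motif map lacks required column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  opt <- function(col, i) if (col %in% names(df)) df[[col]][i] else NULL
  lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      motif_map(kinase_id = df$kinase_id[i], chain_id = df$chain_id[i],
                res_dfg_asp = df$res_dfg_asp[i], res_ape_glu = df$res_ape_glu[i],
                res_hrd_his = opt("res_hrd_his", i) %||% NA,
                res_hrd_arg = opt("res_hrd_arg", i) %||% NA,
                res_hrd_asp = opt("res_hrd_asp", i) %||% NA,
                res_saltbridge_lys = opt("res_saltbridge_lys", i) %||% NA,
                res_saltbridge_glu = opt("res_saltbridge_glu", i) %||% NA,
                res_glu4 = opt("res_glu4", i) %||% NA,
                res_hpn7 = opt("res_hpn7", i) %||% NA,
                group = opt("group", i),
                has_aF_asp = opt("has_aF_asp", i),
                skip_saltbridge = opt("skip_saltbridge", i)),
      error = function(e) stop(sprintf("motif map row %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residue number of an activation-loop position
#'
#' Positions are addressed from both ends of the loop: DFGn is the n-th
#' residue counting from DFG-Asp (DFG1) and APEn the n-th counting
#' backwards from the terminal APE-Glu (APE1).
#'
#' @param map KinaseMotifMap.
#' @param label String like "DFG4" or "APE9".
#' @return Integer residue number (author numbering).
#' @export
actloop_index <- function(map, label) {
  m <- regmatches(label, regexec("^(DFG|APE)([0-9]+)$", label))[[1]]
  if (length(m) != 3L) stop("label must be DFGn or APEn, got '", label, "'",
                            call. = FALSE)
  n <- as.integer(m[3])
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  pos <- if (m[2] == "DFG") map$res_dfg_asp + (n - 1L)
         else map$res_ape_glu - (n - 1L)
  if (pos < map$res_dfg_asp || pos > map$res_ape_glu)
    stop(sprintf("%s is outside the activation loop %d..%d", label,
                 map$res_dfg_asp, map$res_ape_glu), call. = FALSE)
  pos
}

#' Detect conserved kinase motifs in a protein sequence
#'
#' Convenience fallback when no curated motif map is available.  Locates,
#' where unambiguous, HRD-like (\code{[HYFL]RD}), DFG-like
#' (\code{D[FLYWMV]G} downstream of HRD), APE-like (\code{[ASP]PE}
#' downstream of DFG at a plausible loop length) and \code{HPN} patterns.
#' Never guesses exception flags.  One-based positions refer to the first
#' residue of each motif.
#'
#' @param seq One-letter protein sequence (length >= 100).
#' @return List with elements \code{found} (named positions),
#'   \code{ambiguous} (named lists of candidate positions) and
#'   \code{note}.  A motif with no match is absent from both.
#' @export
detect_motifs_from_sequence <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) < 100L) stop("sequence shorter than 100 residues", call. = FALSE)
  all_pos <- function(pat) {
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m)
  }
  found <- list(); amb <- list()
  note <- character()
  place <- function(name, pos) {
    if (length(pos) == 1L) found[[name]] <<- pos
    else if (length(pos) > 1L) {
      amb[[name]] <<- pos
      note <<- c(note, sprintf("%s: %d candidate placements", name, length(pos)))
    } else note <<- c(note, sprintf("%s: no match", name))
  }
  hrd <- all_pos("(?=[HYFL]RD)")
  place("hrd", hrd)
  hrd1 <- if (length(hrd)) min(hrd) else 0L
  dfg <- all_pos("(?=D[FLYWMV]G)")
  dfg <- dfg[dfg > hrd1 + 2L]
  place("dfg", dfg)
  dfg1 <- if (length(dfg)) min(dfg) else 0L
  ape <- all_pos("(?=[ASP]PE)")
  # APE1 (the Glu) must close a loop of plausible length from DFG-Asp
  if (dfg1 > 0L) {
    len <- (ape + 2L) - dfg1 + 1L
    ape <- ape[len >= 18L & len <= 45L]
  }
  place("ape", ape)
  hpn <- all_pos("(?=HPN)")
  if (hrd1 > 0L) hpn <- hpn[hpn < hrd1]
  place("hpn", hpn)
  list(found = found, ambiguous = amb,
       note = if (length(note)) paste(note, collapse = "; ")
              else "all motifs unambiguous")
}
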