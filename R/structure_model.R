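# Reading and representing structures, and crystal-symmetry expansion.
#
# A StructureModel is a light wrapper around a flat atom table (one row
# per heavy atom) plus the crystallographic cell and symmetry operators
# when the file carries them.  PDB and mmCIF parsing is delegated to
# bio3d; cell and symmetry records are parsed here because bio3d does not
# expose them.

#' Construct a StructureModel
#'
#' @param atoms data.frame with columns chain, resno, insert, resid,
#'   elety, elesy, x, y, z, o, b, hetero.
#' @param entry_id Identifier for the structure.
#' @param cell Numeric vector of the six cell parameters
#'   (a, b, c in Angstroms; alpha, beta, gamma in degrees) or NULL.
#' @param spacegroup Hermann-Mauguin symbol or NULL.
#' @param symmetry_ops List of operators, each a list(rot = 3x3 matrix,
#'   trans = 3-vector) in fractional coordinates.  The identity operator
#'   is always first.  Non-empty iff \code{spacegroup} is present.
#' @return Object of class \code{"StructureModel"}.
#' @export
structure_model <- function(atoms, entry_id = "model", cell = NULL,
                            spacegroup = NULL, symmetry_ops = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o", "b", "hetero")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates", call. = FALSE)
  if (is.null(spacegroup)) {
    symmetry_ops <- list()
  } else if (is.null(symmetry_ops) || !length(symmetry_ops)) {
    symmetry_ops <- spacegroup_ops(spacegroup)
  }
  m <- list(entry_id = entry_id, atoms = atoms, cell = cell,
            spacegroup = spacegroup, symmetry_ops = symmetry_ops)
  class(m) <- "StructureModel"
  m
}

#' @export
print.StructureModel <- function(x, ...) {
  nres <- nrow(unique(x$atoms[!x$atoms$hetero, c("chain", "resno", "insert")]))
  cat(sprintf("StructureModel '%s': %d atoms, %d polymer residues, chains: %s\n",
              x$entry_id, nrow(x$atoms), nres,
              paste(unique(x$atoms$chain), collapse = " ")))
  if (!is.null(x$spacegroup))
    cat(sprintf("  cell %s  spacegroup '%s' (%d symmetry operators)\n",
                paste(format(x$cell, nsmall = 1), collapse = " "),
                x$spacegroup, length(x$symmetry_ops)))
  invisible(x)
}

#' Read a structure from PDB or mmCIF
#'
#' Polymer heavy atoms are retained; hydrogens are dropped; waters and
#' ligands are kept with \code{hetero = TRUE}.  Alternate locations are
#' resolved by keeping the highest-occupancy conformer (ties go to altloc
#' "A").  For multi-model (NMR) files only the first model is used.  The
#' crystallographic cell and space group are captured when present, along
#' with symmetry operators from REMARK 290 / _symmetry_equiv records or,
#' failing that, a built-in table of common space groups.
#'
#' @param path File path.
#' @param fmt One of "auto", "pdb", "cif".
#' @return A \code{\link{structure_model}}.
#' @export
read_structure <- function(path, fmt = c("auto", "pdb", "cif")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    fmt <- if (ext %in% c("cif", "mmcif")) "cif"
           else if (ext %in% c("pdb", "ent", "")) "pdb"
           else stop("cannot infer format from extension '", ext,
                     "'; pass fmt explicitly", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  pdb <- tryCatch(
    if (fmt == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop(sprintf("failed to parse %s as %s: %s",
                                     path, fmt, conditionMessage(e)),
                             call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || !nrow(at))
    stop(sprintf("failed to parse %s as %s: no atom records found",
                 path, fmt), call. = FALSE)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  if (is.null(at$elesy) || all(is.na(at$elesy)))
    at$elesy <- .element_from_name(at$elety)
  at$elesy[is.na(at$elesy) | at$elesy == ""] <- .element_from_name(
    at$elety[is.na(at$elesy) | at$elesy == ""])
  # drop hydrogens/deuteriums
  at <- at[!(toupper(at$elesy) %in% c("H", "D")), , drop = FALSE]
  # first model only: bio3d returns first-model rows in $atom already
  at <- .resolve_altloc(at)
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      insert = as.character(at$insert),
                      resid = as.character(at$resid),
                      elety = as.character(at$elety),
                      elesy = toupper(as.character(at$elesy)),
                      x = at$x, y = at$y, z = at$z,
                      o = at$o, b = at$b,
                      hetero = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  sym <- if (fmt == "pdb") .parse_pdb_symmetry(lines) else .parse_cif_symmetry(lines)
  structure_model(atoms,
                  entry_id = sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "",
                                 basename(path)),
                  cell = sym$cell, spacegroup = sym$spacegroup,
                  symmetry_ops = sym$ops)
}

.element_from_name <- function(elety) {
  e <- sub("^[0-9]*", "", toupper(elety))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA."),
         two, one)
}

# keep the highest-occupancy altloc per atom site; ties -> altloc "A"
.resolve_altloc <- function(at) {
  if (all(at$alt %in% c("", " "))) return(at)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
    if (length(ix) == 1L) return(ix)
    occ <- at$o[ix]
    best <- ix[occ == max(occ)]
    if (length(best) > 1L) {
      alt <- at$alt[best]
      best <- best[order(alt)][1L]
    }
    best
  }), use.names = FALSE)
  out <- at[sort(keep), , drop = FALSE]
  out
}

# ---- cell and symmetry records -------------------------------------------

.parse_pdb_symmetry <- function(lines) {
  cell <- NULL; sg <- NULL; ops <- list()
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl)) {
    cl <- cl[1L]
    cell <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                         substr(cl, 25, 33), substr(cl, 34, 40),
                         substr(cl, 41, 47), substr(cl, 48, 54)))
    sg <- trimws(substr(cl, 56, 66))
    if (!nzchar(sg)) sg <- NULL
  }
  sm <- grep("^REMARK 290\\s+SMTRY", lines, value = TRUE)
  if (length(sm)) {
    f <- lapply(sm, function(l) {
      v <- strsplit(trimws(substr(l, 12, nchar(l))), "\\s+")[[1]]
      # SMTRYn  opno  r1 r2 r3 t
      list(axis = as.integer(substr(v[1], 6, 6)), op = as.integer(v[2]),
           r = as.numeric(v[3:5]), t = as.numeric(v[6]))
    })
    nop <- max(vapply(f, function(z) z$op, 0L))
    ops <- vector("list", nop)
    for (k in seq_len(nop)) {
      rot <- matrix(0, 3, 3); tr <- numeric(3)
      for (z in f) if (z$op == k) { rot[z$axis, ] <- z$r; tr[z$axis] <- z$t }
      # SMTRY operators act on cartesian coordinates; convert to fractional
      ops[[k]] <- list(rot = rot, trans = tr, frame = "cartesian")
    }
    if (!is.null(cell)) ops <- lapply(ops, .op_to_fractional, cell = cell)
  }
  if (!length(ops) && !is.null(sg)) {
    ops <- tryCatch(spacegroup_ops(sg), error = function(e) {
      warning("space group '", sg, "' not in built-in table and no SMTRY ",
              "records; using identity operator only", call. = FALSE)
      list(.identity_op())
    })
  }
  list(cell = cell, spacegroup = sg, ops = ops)
}

.parse_cif_symmetry <- function(lines) {
  getv <- function(tag) {
    l <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(l)) return(NULL)
    v <- trimws(sub(paste0("^", tag, "\\s+"), "", l[1L]))
    gsub("^['\"]|['\"]$", "", v)
  }
  cellv <- vapply(c("_cell\\.length_a", "_cell\\.length_b", "_cell\\.length_c",
                    "_cell\\.angle_alpha", "_cell\\.angle_beta",
                    "_cell\\.angle_gamma"),
                  function(t) { v <- getv(t); if (is.null(v)) NA_real_ else as.numeric(v) },
                  0)
  cell <- if (all(is.finite(cellv))) unname(cellv) else NULL
  sg <- getv("_symmetry\\.space_group_name_H-M")
  if (is.null(sg)) sg <- getv("_symmetry_space_group_name_H-M")
  ops <- list()
  # explicit operator loop, if present
  ix <- grep("_symmetry_equiv\\.pos_as_xyz|_space_group_symop\\.operation_xyz|_symmetry_equiv_pos_as_xyz",
             lines)
  if (length(ix)) {
    j <- ix[1L] + 1L
    xyz <- character()
    while (j <= length(lines)) {
      l <- trimws(lines[j])
      if (!nzchar(l) || startsWith(l, "_") || startsWith(l, "loop_") ||
          startsWith(l, "#") || startsWith(l, "data_")) break
      m <- regmatches(l, regexpr("['\"][^'\"]+['\"]|[-+0-9XYZxyz/,(). ]+$", l))
      if (length(m)) xyz <- c(xyz, gsub("^['\"]|['\"]$", "", m))
      j <- j + 1L
    }
    xyz <- xyz[grepl(",", xyz)]
    if (length(xyz)) ops <- lapply(xyz, parse_symop)
  }
  if (!length(ops) && !is.null(sg)) {
    ops <- tryCatch(spacegroup_ops(sg), error = function(e) {
      warning("space group '", sg, "' not in built-in table; ",
              "using identity operator only", call. = FALSE)
      list(.identity_op())
    })
  }
  list(cell = cell, spacegroup = sg, ops = ops)
}

.identity_op <- function() list(rot = diag(3), trans = numeric(3))

#' Parse a symmetry operator triplet
#'
#' Converts a crystallographic operator string such as
#' \code{"-X,Y+1/2,-Z"} into a fractional-coordinate rotation matrix and
#' translation vector.
#'
#' @param xyz Operator string with three comma-separated components.
#' @return list(rot = 3x3 matrix, trans = 3-vector).
#' @export
parse_symop <- function(xyz) {
  parts <- strsplit(gsub("\\s", "", toupper(xyz)), ",")[[1]]
  if (length(parts) != 3L) stop("malformed symmetry operator: ", xyz, call. = FALSE)
  rot <- matrix(0, 3, 3); tr <- numeric(3)
  for (i in 1:3) {
    p <- parts[i]
    # axis terms
    for (j in 1:3) {
      ax <- c("X", "Y", "Z")[j]
      m <- regmatches(p, gregexpr(paste0("[+-]?", ax), p))[[1]]
      for (t in m) rot[i, j] <- rot[i, j] + if (startsWith(t, "-")) -1 else 1
      p <- gsub(paste0("[+-]?", ax), "", p)
    }
    # remaining numeric translation (fractions like 1/2, or decimals)
    if (nzchar(p)) {
      fr <- regmatches(p, gregexpr("[+-]?[0-9]+(/[0-9]+)?(\\.[0-9]+)?", p))[[1]]
      for (t in fr) {
        if (grepl("/", t)) {
          ab <- as.numeric(strsplit(sub("^\\+", "", t), "/")[[1]])
          tr[i] <- tr[i] + ab[1] / ab[2]
        } else tr[i] <- tr[i] + as.numeric(t)
      }
    }
  }
  list(rot = rot, trans = tr)
}

# built-in operator table for common protein space groups (triplets from
# International Tables, vol. A); keys are normalized H-M symbols
.SG_TABLE <- list(
  "P1"       = c("X,Y,Z"),
  "P2"       = c("X,Y,Z", "-X,Y,-Z"),
  "P21"      = c("X,Y,Z", "-X,Y+1/2,-Z"),
  "C2"       = c("X,Y,Z", "-X,Y,-Z", "X+1/2,Y+1/2,Z", "-X+1/2,Y+1/2,-Z"),
  "P21212"   = c("X,Y,Z", "-X,-Y,Z", "-X+1/2,Y+1/2,-Z", "X+1/2,-Y+1/2,-Z"),
  "P212121"  = c("X,Y,Z", "-X+1/2,-Y,Z+1/2", "-X,Y+1/2,-Z+1/2",
                 "X+1/2,-Y+1/2,-Z"),
  "C2221"    = c("X,Y,Z", "-X,-Y,Z+1/2", "-X,Y,-Z+1/2", "X,-Y,-Z",
                 "X+1/2,Y+1/2,Z", "-X+1/2,-Y+1/2,Z+1/2",
                 "-X+1/2,Y+1/2,-Z+1/2", "X+1/2,-Y+1/2,-Z"),
  "P41212"   = c("X,Y,Z", "-X,-Y,Z+1/2", "-Y+1/2,X+1/2,Z+1/4",
                 "Y+1/2,-X+1/2,Z+3/4", "-X+1/2,Y+1/2,-Z+1/4",
                 "X+1/2,-Y+1/2,-Z+3/4", "Y,X,-Z", "-Y,-X,-Z+1/2"),
  "P43212"   = c("X,Y,Z", "-X,-Y,Z+1/2", "-Y+1/2,X+1/2,Z+3/4",
                 "Y+1/2,-X+1/2,Z+1/4", "-X+1/2,Y+1/2,-Z+3/4",
                 "X+1/2,-Y+1/2,-Z+1/4", "Y,X,-Z", "-Y,-X,-Z+1/2"),
  "P3121"    = c("X,Y,Z", "-Y,X-Y,Z+1/3", "-X+Y,-X,Z+2/3",
                 "Y,X,-Z", "X-Y,-Y,-Z+2/3", "-X,-X+Y,-Z+1/3"),
  "P3221"    = c("X,Y,Z", "-Y,X-Y,Z+2/3", "-X+Y,-X,Z+1/3",
                 "Y,X,-Z", "X-Y,-Y,-Z+1/3", "-X,-X+Y,-Z+2/3"),
  "P61"      = c("X,Y,Z", "-Y,X-Y,Z+1/3", "-X+Y,-X,Z+2/3", "-X,-Y,Z+1/2",
                 "Y,-X+Y,Z+5/6", "X-Y,X,Z+1/6"),
  "P65"      = c("X,Y,Z", "-Y,X-Y,Z+2/3", "-X+Y,-X,Z+1/3", "-X,-Y,Z+1/2",
                 "Y,-X+Y,Z+1/6", "X-Y,X,Z+5/6"),
  "I222"     = c("X,Y,Z", "-X,-Y,Z", "-X,Y,-Z", "X,-Y,-Z",
                 "X+1/2,Y+1/2,Z+1/2", "-X+1/2,-Y+1/2,Z+1/2",
                 "-X+1/2,Y+1/2,-Z+1/2", "X+1/2,-Y+1/2,-Z+1/2")
)

.normalize_sg <- function(sg) {
  s <- toupper(gsub("[ ()]", "", sg))
  alias <- c("P1211" = "P21", "P121" = "P2", "C121" = "C2", "P111" = "P1",
             "P1121" = "P21")
  if (s %in% names(alias)) s <- unname(alias[s])
  s
}

#' Symmetry operators for a space group
#'
#' @param sg Hermann-Mauguin symbol (e.g. "P 21 21 21").
#' @return List of operators (rot, trans) in fractional coordinates;
#'   identity first.
#' @export
spacegroup_ops <- function(sg) {
  key <- .normalize_sg(sg)
  if (!key %in% names(.SG_TABLE))
    stop("space group '", sg, "' not in built-in table", call. = FALSE)
  lapply(.SG_TABLE[[key]], parse_symop)
}

# orthogonalization matrix (fractional -> cartesian), PDB convention
.orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- .rad(cell[4]); be <- .rad(cell[5]); ga <- .rad(cell[6])
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)), nrow = 3, byrow = TRUE)
}

.op_to_fractional <- function(op, cell) {
  O <- .orth_matrix(cell)
  Oi <- solve(O)
  list(rot = Oi %*% op$rot %*% O, trans = as.numeric(Oi %*% op$trans))
}

.is_identity_op <- function(op, tol = 1e-6) {
  max(abs(op$rot - diag(3))) < tol && max(abs(op$trans %% 1)) < tol
}

#' Crystal-symmetry neighbor copies of every chain
#'
#' Applies every symmetry operator combined with every lattice translation
#' of the (2*shell+1)^3 block of unit cells, excluding the identity image
#' at zero translation, and returns the placed chain copies with operator
#' provenance.  shell = 1 gives the 3x3x3 block used when searching for
#' substrate-bound and autophosphorylation complexes in crystals.
#'
#' @param model A \code{\link{structure_model}} with cell and space group.
#' @param shell Non-negative integer; shell = 0 returns an empty list.
#' @return List of copies; each has \code{chain}, \code{op_index},
#'   \code{offset} (lattice translation) and \code{atoms} (transformed
#'   atom table).
#' @export
expand_crystal_neighbors <- function(model, shell = 1L) {
  stopifnot(inherits(model, "StructureModel"))
  if (shell < 0) stop("shell must be >= 0", call. = FALSE)
  if (is.null(model$cell) || is.null(model$spacegroup))
    stop("capability error: cell or space group absent; ",
         "only the deposited asymmetric unit is available", call. = FALSE)
  O <- .orth_matrix(model$cell)
  Oi <- solve(O)
  xyz <- t(as.matrix(model$atoms[, c("x", "y", "z")]))
  frac <- Oi %*% xyz
  chains <- unique(model$atoms$chain)
  offs <- expand.grid(i = -shell:shell, j = -shell:shell, k = -shell:shell)
  out <- list()
  for (ci in chains) {
    sel <- model$atoms$chain == ci
    f0 <- frac[, sel, drop = FALSE]
    for (oi in seq_along(model$symmetry_ops)) {
      op <- model$symmetry_ops[[oi]]
      f1 <- op$rot %*% f0 + op$trans
      for (r in seq_len(nrow(offs))) {
        off <- as.numeric(offs[r, ])
        if (oi == 1L && all(off == 0)) next  # identity image
        f2 <- f1 + off
        cart <- O %*% f2
        at <- model$atoms[sel, , drop = FALSE]
        at$x <- cart[1, ]; at$y <- cart[2, ]; at$z <- cart[3, ]
        out[[length(out) + 1L]] <- list(chain = ci, op_index = oi,
                                        offset = off, atoms = at)
      }
    }
  }
  out
}

#' Remove residues from a model
#'
#' Utility for ablation studies: drops all atoms of the given residues.
#' @param model StructureModel.
#' @param chain Chain identifier.
#' @param resnos Integer residue numbers to drop.
#' @param atom_names Optional: drop only these atom names.
#' @return Modified StructureModel.
#' @export
drop_residues <- function(model, chain, resnos, atom_names = NULL) {
  sel <- model$atoms$chain == chain & model$atoms$resno %in% resnos
  if (!is.null(atom_names)) sel <- sel & model$atoms$elety %in% atom_names
  model$atoms <- model$atoms[!sel, , drop = FALSE]
  model
}

# ---- residue lookup helpers (used by the feature computations) -----------

#' @keywords internal
res_table <- function(model, chain, resno) {
  a <- model$atoms
  a[a$chain == chain & a$resno == resno, , drop = FALSE]
}

#' @keywords internal
atom_xyz <- function(model, chain, resno, name) {
  rt <- res_table(model, chain, resno)
  rt <- rt[rt$elety == name, , drop = FALSE]
  if (!nrow(rt)) return(NULL)
  as.numeric(rt[1L, c("x", "y", "z")])
}

#' @keywords internal
res_name <- function(model, chain, resno) {
  rt <- res_table(model, chain, resno)
  if (!nrow(rt)) return(NULL)
  rt$resid[1L]
}

# side-chain heavy atoms of a residue; for Gly/Ala (or when none) CA may
# be included via include_ca
#' @keywords internal
sidechain_xyz <- function(model, chain, resno, include_ca_fallback = TRUE) {
  rt <- res_table(model, chain, resno)
  bb <- c("N", "CA", "C", "O", "OXT")
  sc <- rt[!(rt$elety %in% bb), , drop = FALSE]
  if (!nrow(sc) && include_ca_fallback)
    sc <- rt[rt$elety == "CA", , drop = FALSE]
  if (!nrow(sc)) return(NULL)
  as.matrix(sc[, c("x", "y", "z")])
}
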