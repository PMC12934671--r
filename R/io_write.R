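# Minimal writers for the fixture generator and the CLI: standard-dialect
# PDB and a minimal mmCIF with the atom_site loop plus cell/symmetry.

#' Write a StructureModel as PDB
#'
#' @param model StructureModel.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  ord <- order(a$chain, a$resno, a$insert)
  a <- a[ord, , drop = FALSE]
  lines <- character()
  if (!is.null(model$cell) && !is.null(model$spacegroup)) {
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      model$cell[1], model$cell[2], model$cell[3], model$cell[4],
      model$cell[5], model$cell[6], model$spacegroup,
      length(model$symmetry_ops)))
  }
  rec <- ifelse(a$hetero, "HETATM", "ATOM  ")
  name4 <- vapply(a$elety, function(n) {
    if (nchar(n) >= 4L) substr(n, 1, 4)
    else sprintf(" %-3s", n)   # element in column 14 for short names
  }, "")
  for (i in seq_len(nrow(a))) {
    lines <- c(lines, sprintf(
      "%s%5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec[i], i %% 100000L, name4[i], a$resid[i], a$chain[i], a$resno[i],
      ifelse(nzchar(a$insert[i]), a$insert[i], " "),
      a$x[i], a$y[i], a$z[i], a$o[i], a$b[i], a$elesy[i]))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a StructureModel as minimal mmCIF
#'
#' @inheritParams write_pdb
#' @export
write_cif <- function(model, path) {
  a <- model$atoms
  ord <- order(a$chain, a$resno, a$insert)
  a <- a[ord, , drop = FALSE]
  lines <- c(sprintf("data_%s", gsub("[^A-Za-z0-9]", "_", model$entry_id)))
  if (!is.null(model$cell)) {
    lines <- c(lines,
               sprintf("_cell.length_a    %.3f", model$cell[1]),
               sprintf("_cell.length_b    %.3f", model$cell[2]),
               sprintf("_cell.length_c    %.3f", model$cell[3]),
               sprintf("_cell.angle_alpha %.2f", model$cell[4]),
               sprintf("_cell.angle_beta  %.2f", model$cell[5]),
               sprintf("_cell.angle_gamma %.2f", model$cell[6]))
  }
  if (!is.null(model$spacegroup))
    lines <- c(lines, sprintf("_symmetry.space_group_name_H-M  '%s'",
                              model$spacegroup))
  lines <- c(lines, "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  for (i in seq_len(nrow(a))) {
    lines <- c(lines, paste(
      ifelse(a$hetero[i], "HETATM", "ATOM"), i, a$elesy[i], a$elety[i], ".",
      a$resid[i], a$chain[i], "1", a$resno[i],
      ifelse(nzchar(a$insert[i]), a$insert[i], "?"),
      sprintf("%.3f %.3f %.3f %.2f %.2f", a$x[i], a$y[i], a$z[i],
              a$o[i], a$b[i]),
      a$resno[i], a$resid[i], a$chain[i], a$elety[i], "1"))
  }
  writeLines(lines, path)
  invisible(path)
}
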