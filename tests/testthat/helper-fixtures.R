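# Shared fixtures (cached across test files: toy builds are deterministic,
# so a single build serves every test that needs it) and the independent
# brute-force oracles used to cross-check the implementation.

.fixture_cache <- new.env(parent = emptyenv())

toy <- function(name = "all_pass_nonTYR", ...) {
  key <- paste(name, paste(deparse(list(...)), collapse = ""), collapse = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sp <- if (name %in% names(jsonlite::fromJSON(system.file(
    "extdata", "toy_presets.json", package = "kinactive"), simplifyVector = FALSE)))
    toy_presets(name) else toy_kinase_spec(...)
  extra <- list(...)
  if (length(extra)) {
    args <- utils::modifyList(list(group = sp$group, violate = sp$violate),
                              extra)
    sp <- do.call(toy_kinase_spec, args)
  }
  fx <- build_toy_kinase(sp)
  .fixture_cache[[key]] <- fx
  fx
}

# independent torsion formula (atan2 of cross/dot products, distinct from
# the implementation's normal-vector route)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2]*b[3] - a[3]*b[2], a[3]*b[1] - a[1]*b[3],
                         a[1]*b[2] - a[2]*b[1])
  y <- sum(sqrt(sum(b2^2)) * b1 * cr(b2, b3))
  x <- sum(cr(b1, b2) * cr(b2, b3))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# exhaustive double-loop minimum pair distance
oracle_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# exhaustive contact count oracle between two residue atom tables
oracle_contact_count <- function(A, B, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    if (sqrt(sum((A[i, ] - B[j, ])^2)) < cutoff) n <- n + 1L
  n
}

# independently coded RMSD
oracle_rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# brute-force ipSAE: explicit double loop over the formula
oracle_ipsae <- function(pae, plddt, loop, d0 = 4, gate = 60) {
  n <- nrow(pae)
  best <- -Inf
  for (i in setdiff(seq_len(n), loop)) {
    if (!(plddt[i] > gate)) next
    s <- 0
    for (j in loop) s <- s + 1 / (1 + (pae[i, j] / d0)^2)
    best <- max(best, s / length(loop))
  }
  best
}

rigid_copy <- function(model, rotvec = c(0.3, 0.8, -0.5), trans = c(5, -3, 10)) {
  R <- kinactive:::.rotvec_matrix(rotvec)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, trans, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# minimal hand-written two-residue PDB / mmCIF pair
write_mini_pdb <- function(path) {
  writeLines(c(
    "CRYST1   30.000   40.000   50.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 50.00           N",
    "ATOM      2  CA  ALA A   1       2.458   2.000   3.000  1.00 50.00           C",
    "ATOM      3  C   ALA A   1       3.010   3.420   3.000  1.00 50.00           C",
    "ATOM      4  O   ALA A   1       2.260   4.390   3.100  1.00 50.00           O",
    "ATOM      5  CB AALA A   1       2.960   1.210   1.800  0.40 50.00           C",
    "ATOM      6  CB BALA A   1       2.970   1.200   1.820  0.60 50.00           C",
    "ATOM      7  N   GLY A   2       4.330   3.560   3.000  1.00 48.00           N",
    "ATOM      8  CA  GLY A   2       4.990   4.870   3.050  1.00 48.00           C",
    "TER", "END"), path)
  path
}

write_mini_cif <- function(path) {
  writeLines(c(
    "data_MINI",
    "_cell.length_a   30.000", "_cell.length_b   40.000",
    "_cell.length_c   50.000", "_cell.angle_alpha 90.00",
    "_cell.angle_beta  90.00", "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M  'P 1'",
    "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
             "auth_seq_id", "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 50.00 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.458 2.000 3.000 1.00 50.00 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 3.010 3.420 3.000 1.00 50.00 1 ALA A C 1",
    "ATOM 4 O O . ALA A 1 1 ? 2.260 4.390 3.100 1.00 50.00 1 ALA A O 1",
    "ATOM 5 C CB . ALA A 1 1 ? 2.970 1.200 1.820 1.00 50.00 1 ALA A CB 1",
    "ATOM 6 N N . GLY A 1 2 ? 4.330 3.560 3.000 1.00 48.00 2 GLY A N 1",
    "ATOM 7 C CA . GLY A 1 2 ? 4.990 4.870 3.050 1.00 48.00 2 GLY A CA 1"),
    path)
  path
}

# motif map CSV for a toy fixture
write_toy_map_csv <- function(map, path) {
  utils::write.csv(data.frame(
    kinase_id = map$kinase_id, chain_id = map$chain_id, group = map$group,
    res_dfg_asp = map$res_dfg_asp, res_ape_glu = map$res_ape_glu,
    res_hrd_his = map$res_hrd_his,
    res_saltbridge_lys = map$res_saltbridge_lys,
    res_saltbridge_glu = map$res_saltbridge_glu,
    res_glu4 = map$res_glu4, res_hpn7 = map$res_hpn7,
    stringsAsFactors = FALSE), path, row.names = FALSE)
  path
}
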