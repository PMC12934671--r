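# The six criterion states and the underlying features, on constructed
# fixtures whose geometry is known exactly.

test_that("spatial DFG label separates DFGin and DFGout fixtures", {
  fx <- toy("all_pass_nonTYR")      # phe_glu4 = 8, phe_lys = 14
  expect_equal(spatial_dfg_label(fx$model, fx$map), "DFGin")
  out <- toy("violate_spatial")     # phe_glu4 = 14, phe_lys = 9
  expect_equal(spatial_dfg_label(out$model, out$map), "DFGout")
  # intermediate geometry
  inter <- toy("inter", group = "nonTYR",
               distances = list(phe_glu4 = 12.5, phe_lys = 16, spine2 = NA))
  expect_equal(spatial_dfg_label(inter$model, inter$map), "DFGinter")
  # missing anchor atoms propagate to None
  m <- drop_residues(fx$model, "A", 102)
  expect_equal(spatial_dfg_label(m, fx$map), "None")
})

test_that("dihedral XDF label composes region letters with the rotamer word", {
  fx <- toy("all_pass_nonTYR")      # regions B, L, A; chi1 = -65
  expect_equal(dihedral_xdf_label(fx$model, fx$map), "BLAminus")
  # peptide-flipped geometry: X in A, Asp in B -> ABAminus
  aba <- toy("aba", group = "nonTYR",
             dihedrals = list(x = c(-75, -30), asp = c(-120, 130)))
  expect_equal(dihedral_xdf_label(aba$model, aba$map), "ABAminus")
  plus <- toy("violate_dihedral")   # chi1 = +55
  expect_equal(dihedral_xdf_label(plus$model, plus$map), "BLAplus")
  # Phe-position residue without chi1 -> None
  m <- drop_residues(fx$model, "A", 102,
                     atom_names = c("CB", "CG", "CD1", "CD2", "CE1", "CE2",
                                    "CZ"))
  expect_equal(dihedral_xdf_label(m, fx$map), "None")
})

test_that("salt-bridge state applies the 3.6 A cutoff and exceptions", {
  fx <- toy("all_pass_nonTYR")
  sb <- saltbridge_state(fx$model, fx$map)
  expect_equal(sb$state, "in")
  expect_equal(sb$distance, 3.0, tolerance = 0.05)
  out <- toy("violate_saltbr")      # 4.5 A
  expect_equal(saltbridge_state(out$model, out$map)$state, "out")
  # skip flag honored
  wnk <- fx$map
  wnk$skip_saltbridge <- TRUE
  expect_equal(saltbridge_state(fx$model, wnk)$state, "skipped")
  # missing Glu side chain -> none
  m <- drop_residues(fx$model, "A", 45, atom_names = c("OE1", "OE2"))
  expect_equal(saltbridge_state(m, fx$map)$state, "none")
})

test_that("ActLoopNT state measures the DFG6/XHRD backbone hydrogen bond", {
  fx <- toy("all_pass_nonTYR")      # 2.9 A
  nt <- actloopNT_state(fx$model, fx$map)
  expect_equal(nt$state, "in")
  expect_equal(nt$distance, 2.9, tolerance = 0.05)
  out <- toy("violate_actloopNT")   # 5.0 A
  nt2 <- actloopNT_state(out$model, out$map)
  expect_equal(nt2$state, "out")
  expect_equal(nt2$distance, 5.0, tolerance = 0.05)
  m <- drop_residues(fx$model, "A", 70)
  expect_equal(actloopNT_state(m, fx$map)$state, "none")
})

test_that("HRD state requires His in A and Arg in L, with the no-Asp skip", {
  fx <- toy("all_pass_nonTYR")      # His (-70,-35)-like A, Arg (60,40) L
  expect_equal(hrd_state(fx$model, fx$map), "in")
  out <- toy("violate_hrd")         # Arg flipped to (-120,140): region B
  expect_equal(hrd_state(out$model, out$map), "out")
  pim <- fx$map
  pim$skip_hrd <- FALSE
  expect_equal(hrd_state(fx$model, pim), "in")
  pim2 <- motif_map("CAMK_PIM1", res_dfg_asp = 101, res_ape_glu = 126,
                    res_hrd_his = 71)
  expect_equal(hrd_state(fx$model, pim2), "skipped")
})

test_that("ActLoopCT applies the non-TYR sub-criteria and names the violator", {
  ok <- toy("ctok", group = "nonTYR",
            distances = list(ape9_hrdargO = 4.0, ape10_dfg4 = 7.0,
                             ape11_dfg4 = 10.0, ape12_dfg4 = 11.0))
  ct <- actloopCT_state(ok$model, ok$map)
  expect_equal(ct$state, "in")
  expect_setequal(names(ct$detail),
                  c("APE7_6", "APE8", "APE8_chi1", "APE9_dist", "APE10_dist",
                    "APE11_dist", "APE12_dist"))
  bad <- toy("violate_actloopCT")   # ape10 = 9.0 > 8
  ct2 <- actloopCT_state(bad$model, bad$map)
  expect_equal(ct2$state, "out")
  expect_equal(ct2$detail[["APE10_dist"]], "out")
  expect_equal(ct2$detail[["APE11_dist"]], "in")
  # the APE7/APE6 peptide flip (B, L) also passes
  flip <- toy("ctflip", group = "nonTYR",
              dihedrals = list(ape7 = c(-120, 130), ape6 = c(60, 40)))
  expect_equal(actloopCT_state(flip$model, flip$map)$detail[["APE7_6"]], "in")
  # flip of only one of the pair fails
  half <- toy("cthalf", group = "nonTYR",
              dihedrals = list(ape7 = c(-120, 130)))
  expect_equal(actloopCT_state(half$model, half$map)$state, "out")
})

test_that("ActLoopCT applies the TYR-specific sub-criteria", {
  ty <- toy("all_pass_TYR")         # APE8/9/10 in B, ape9 dist 7.0 < 8
  ct <- actloopCT_state(ty$model, ty$map)
  expect_equal(ct$state, "in")
  expect_setequal(names(ct$detail),
                  c("APE7_6", "APE8", "APE9_dihe", "APE10_dihe", "APE9_dist"))
  # 7 A passes the TYR bound but would fail the non-TYR bound
  expect_false("APE10_dist" %in% names(ct$detail))
  far <- toy("tyfar", group = "TYR", distances = list(ape9_hrdargO = 8.5))
  expect_equal(actloopCT_state(far$model, far$map)$detail[["APE9_dist"]], "out")
  noape <- toy("all_pass_noAPE")
  expect_equal(actloopCT_state(noape$model, noape$map)$state, "skipped")
})

test_that("APE8 chi1 is required only for Ser/Thr in non-TYR kinases", {
  rot <- toy("ape8rot", group = "nonTYR", dihedrals = list(ape8_chi1 = 55))
  ct <- actloopCT_state(rot$model, rot$map)
  expect_equal(ct$detail[["APE8_chi1"]], "out")
  expect_equal(ct$state, "out")
  # TYR group (Pro at APE8): no chi1 requirement at all
  ty <- toy("all_pass_TYR")
  expect_false("APE8_chi1" %in% names(actloopCT_state(ty$model, ty$map)$detail))
})

test_that("spine distances report min side-chain contacts and the intact flag", {
  fx <- toy("all_pass_nonTYR")      # all three at 4.0
  sp <- spine_distances(fx$model, fx$map)
  expect_equal(c(sp$spine1, sp$spine2, sp$spine3), rep(4, 3),
               tolerance = 0.06)
  expect_true(sp$intact)
  broken <- toy("spine3off", group = "nonTYR", distances = list(spine3 = 6.5))
  expect_false(spine_distances(broken$model, broken$map)$intact)
  # brute-force oracle over the actual side-chain atom sets
  a <- sidechain_xyz(fx$model, "A", 71)
  b <- sidechain_xyz(fx$model, "A", 102)
  expect_equal(sp$spine1, oracle_min_dist(a, b), tolerance = 1e-10)
})

test_that("criterion states are pure functions of coordinates and map", {
  fx <- toy("all_pass_nonTYR")
  f1 <- compute_features(fx$model, fx$map)
  f2 <- compute_features(fx$model, fx$map)
  expect_identical(f1, f2)
  expect_equal(dihedral_xdf_label(fx$model, fx$map) == "BLAminus",
               all(f1$xdf_regions == c("B", "L", "A")) &&
                 isTRUE(chi1_minus(f1$phe_chi1)))
})

test_that("states are robust to 0.05 A coordinate noise away from boundaries", {
  fx <- toy("all_pass_nonTYR")
  states0 <- vapply(classify(fx$model, fx$map)$criteria,
                    function(x) x$state, "")
  set.seed(42)
  for (rep in 1:3) {
    m <- fx$model
    n <- nrow(m$atoms)
    m$atoms$x <- m$atoms$x + runif(n, -0.05, 0.05)
    m$atoms$y <- m$atoms$y + runif(n, -0.05, 0.05)
    m$atoms$z <- m$atoms$z + runif(n, -0.05, 0.05)
    states1 <- vapply(classify(m, fx$map)$criteria, function(x) x$state, "")
    expect_identical(states1, states0)
  }
})
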