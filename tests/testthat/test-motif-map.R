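# Motif map construction, validation, loop indexing, file loading, the
# built-in exception tables, and sequence-based motif detection.

test_that("motif_map validates the activation-loop invariants", {
  m <- motif_map("AGC_AKT1", chain_id = "A", res_dfg_asp = 292,
                 res_ape_glu = 314, res_hrd_his = 272,
                 res_saltbridge_lys = 179, res_saltbridge_glu = 198)
  expect_equal(m$res_xhrd, 271L)
  expect_equal(m$res_hrd_arg, 273L)
  expect_equal(m$res_hrd_asp, 274L)
  expect_equal(m$res_glu4, 202L)
  expect_error(motif_map("X_Y", res_dfg_asp = 100, res_ape_glu = 90),
               "precede")
  expect_error(motif_map("X_Y", res_dfg_asp = 100, res_ape_glu = 110),
               "overlap")
})

test_that("actloop_index implements indexing from both loop ends", {
  m <- motif_map("CAMK_TOY", res_dfg_asp = 100, res_ape_glu = 130,
                 res_hrd_his = 71)
  expect_equal(actloop_index(m, "DFG1"), 100L)
  expect_equal(actloop_index(m, "APE1"), 130L)
  expect_equal(actloop_index(m, "APE9"), 122L)
  expect_error(actloop_index(m, "DFG40"), "outside")
  # arithmetic closure over many (n, m)
  for (n in c(1, 3, 9, 14)) for (k in c(1, 5, 12, 15))
    expect_equal(actloop_index(m, paste0("DFG", n)) +
                   actloop_index(m, paste0("APE", k)),
                 100 + 130 + n - k)
})

test_that("built-in exception tables are applied exactly", {
  ex <- kinase_exceptions()
  expect_setequal(ex$skip_saltbridge,
                  c("WNK1", "WNK2", "WNK3", "WNK4", "MAP3K12", "MAP3K13"))
  expect_setequal(ex$noape, c("HASPIN", "TP53RK", "PKDCC"))
  expect_setequal(ex$no_af_asp,
                  c("PIM1", "PIM2", "PIM3", "HASPIN", "PKDCC", "AATK",
                    "LMTK2", "LMTK3"))
  mk <- function(id) motif_map(id, res_dfg_asp = 100, res_ape_glu = 126,
                               res_hrd_his = 71)
  for (g in c("OTHER_WNK1", "OTHER_WNK2", "OTHER_WNK3", "OTHER_WNK4",
              "TKL_MAP3K12", "TKL_MAP3K13"))
    expect_true(mk(g)$skip_saltbridge, label = g)
  expect_false(mk("AGC_AKT1")$skip_saltbridge)
  for (g in c("OTHER_HASPIN", "OTHER_TP53RK", "OTHER_PKDCC"))
    expect_equal(mk(g)$group, "noAPE", label = g)
  for (g in c("CAMK_PIM1", "CAMK_PIM2", "CAMK_PIM3", "OTHER_HASPIN",
              "OTHER_PKDCC", "TYR_AATK", "TYR_LMTK2", "TYR_LMTK3"))
    expect_true(mk(g)$skip_hrd, label = g)
  expect_false(mk("CMGC_CDK2")$skip_hrd)
  # group from the family prefix; explicit flags override
  expect_equal(mk("TYR_ABL1")$group, "TYR")
  expect_equal(mk("CMGC_CDK2")$group, "nonTYR")
  m <- motif_map("TYR_ABL1", res_dfg_asp = 100, res_ape_glu = 126,
                 res_hrd_his = 71, group = "nonTYR", skip_saltbridge = TRUE)
  expect_equal(m$group, "nonTYR")
  expect_true(m$skip_saltbridge)
})

test_that("motif maps load from CSV and JSON with row-level validation", {
  df <- data.frame(kinase_id = c("AGC_AKT1", "OTHER_WNK1"),
                   chain_id = c("A", "A"),
                   res_dfg_asp = c(292, 100), res_ape_glu = c(314, 126),
                   res_hrd_his = c(272, 71),
                   res_saltbridge_lys = c(179, 30),
                   res_saltbridge_glu = c(198, 45))
  fcsv <- tempfile(fileext = ".csv")
  utils::write.csv(df, fcsv, row.names = FALSE)
  maps <- load_motif_map(fcsv)
  expect_length(maps, 2L)
  expect_equal(maps[[1]]$res_hrd_his, 272L)
  expect_true(maps[[2]]$skip_saltbridge)   # via built-in list
  fjson <- tempfile(fileext = ".json")
  jsonlite::write_json(df, fjson)
  maps2 <- load_motif_map(fjson)
  expect_equal(maps2[[1]]$res_glu4, maps[[1]]$res_glu4)
  # invariant violation names the row
  df$res_ape_glu[2] <- 90
  utils::write.csv(df, fcsv, row.names = FALSE)
  expect_error(load_motif_map(fcsv), "row 2")
  # missing required column
  utils::write.csv(df[, -3], fcsv, row.names = FALSE)
  expect_error(load_motif_map(fcsv), "required column")
})

test_that("sequence motif detection locates canonical motifs and reports ambiguity", {
  filler <- function(n, ch = "G") strrep(ch, n)
  s1 <- paste0(filler(40), "HPN", filler(20), "HRD", filler(10, "A"),
               "DFG", filler(15, "S"), "APE", filler(30, "A"))
  r1 <- detect_motifs_from_sequence(s1)
  expect_equal(r1$found$hrd, 64L)
  expect_equal(r1$found$dfg, 77L)
  expect_equal(r1$found$ape, 95L)
  expect_equal(r1$found$hpn, 41L)
  expect_length(r1$ambiguous, 0L)
  # two DFG occurrences between HRD and APE -> ambiguity, both listed
  s2 <- paste0(filler(40), "HRD", filler(8, "A"), "DFG", filler(3, "A"),
               "DFG", filler(14, "S"), "APE", filler(40, "A"))
  r2 <- detect_motifs_from_sequence(s2)
  expect_null(r2$found$dfg)
  expect_length(r2$ambiguous$dfg, 2L)
  # no APE-like motif: APE absent, others still located
  s3 <- paste0(filler(40), "HRD", filler(10, "A"), "DFG", filler(60, "A"))
  r3 <- detect_motifs_from_sequence(s3)
  expect_equal(r3$found$hrd, 41L)
  expect_null(r3$found$ape)
  expect_null(r3$ambiguous$ape)
  expect_match(r3$note, "ape: no match")
  expect_error(detect_motifs_from_sequence("SHORT"), "100")
})
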