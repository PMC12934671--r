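# The tri-state Active / Inactive / None verdict and batch behavior.

test_that("the all-pass fixture is Active and each violation is Inactive", {
  fx <- toy("all_pass_nonTYR")
  expect_equal(classify(fx$model, fx$map)$label, "Active")
  for (v in c("spatial", "dihedral", "saltbr", "hrd", "actloopNT",
              "actloopCT")) {
    r <- classify(toy(paste0("violate_", v))$model,
                  toy(paste0("violate_", v))$map)
    expect_equal(r$label, "Inactive", label = v)
    st <- vapply(r$criteria, function(x) x$state, "")
    expect_equal(unname(names(st)[st == "out"]), v)
  }
})

test_that("a non-BLAminus dihedral label alone makes the chain Inactive", {
  aba <- toy("aba", group = "nonTYR",
             dihedrals = list(x = c(-75, -30), asp = c(-120, 130)))
  r <- classify(aba$model, aba$map)
  expect_equal(r$criteria$dihedral$label, "ABAminus")
  expect_equal(r$label, "Inactive")
})

test_that("missing activation-loop atoms give None unless some criterion fails", {
  fx <- toy("all_pass_nonTYR")
  # APE9-APE12 deleted: ActLoopCT unmeasurable, nothing fails -> None
  resnos <- vapply(paste0("APE", 9:12),
                   function(l) actloop_index(fx$map, l), 0L)
  m <- drop_residues(fx$model, "A", resnos)
  expect_equal(classify(m, fx$map)$label, "None")
  # fail beats missing: salt-bridge violation plus the same deletion
  bad <- toy("violate_saltbr")
  m2 <- drop_residues(bad$model, "A",
                      vapply(paste0("APE", 9:12),
                             function(l) actloop_index(bad$map, l), 0L))
  expect_equal(classify(m2, bad$map)$label, "Inactive")
  # missing core criterion (salt-bridge atoms) -> None
  m3 <- drop_residues(fx$model, "A", 45)
  expect_equal(classify(m3, fx$map)$label, "None")
})

test_that("skipped criteria count as neither pass nor fail", {
  noape <- toy("all_pass_noAPE")
  r <- classify(noape$model, noape$map)
  expect_equal(r$criteria$actloopCT$state, "skipped")
  expect_equal(r$label, "Active")
  # HRD skipped via the PIM-style exception, all else passing -> Active
  fx <- toy("all_pass_nonTYR")
  pim <- motif_map("CAMK_PIM1", res_dfg_asp = 101, res_ape_glu = 126,
                   res_hrd_his = 71, res_saltbridge_lys = 30,
                   res_saltbridge_glu = 45, res_glu4 = 49, res_hpn7 = 60)
  r2 <- classify(fx$model, pim)
  expect_equal(r2$criteria$hrd$state, "skipped")
  expect_equal(r2$label, "Active")
})

test_that("pseudokinase marking bypasses the verdict", {
  fx <- toy("all_pass_nonTYR")
  expect_equal(classify(fx$model, fx$map, pseudokinase = TRUE)$label,
               "Pseudo-skip")
})

test_that("classify errors on a chain absent from the model", {
  fx <- toy("all_pass_nonTYR")
  map2 <- fx$map
  map2$chain_id <- "Z"
  expect_error(classify(fx$model, map2), "not present")
})

test_that("labels are exclusive and exhaustive over measurable fixtures", {
  cases <- list(toy("all_pass_nonTYR"), toy("violate_saltbr"),
                toy("all_pass_TYR"), toy("violate_actloopCT"))
  for (fx in cases) {
    lab <- classify(fx$model, fx$map)$label
    expect_true(lab %in% c("Active", "Inactive", "None"))
  }
})

test_that("atom deletion never turns an Active or Inactive chain the wrong way", {
  fx <- toy("all_pass_nonTYR")
  # deleting from an Active structure yields Active or None, never Inactive
  for (res in list(45, 70, 102, 115:118, c(30, 45))) {
    lab <- classify(drop_residues(fx$model, "A", res), fx$map)$label
    expect_true(lab %in% c("Active", "None"),
                label = paste("deleted", paste(res, collapse = ",")))
  }
  # deleting unrelated atoms from an Inactive structure keeps it Inactive
  bad <- toy("violate_actloopNT")
  lab2 <- classify(drop_residues(bad$model, "A", 45), bad$map)$label
  expect_equal(lab2, "Inactive")
  # ... unless the deleted atoms carried the sole failing criterion
  lab3 <- classify(drop_residues(bad$model, "A", 70), bad$map)$label
  expect_equal(lab3, "None")
})

test_that("classify_batch aggregates labels with deterministic ordering", {
  fx <- toy("all_pass_nonTYR")
  bad <- toy("violate_saltbr")
  none <- list(model = drop_residues(fx$model, "A", 115:118), map = fx$map)
  none$model$entry_id <- "toy_missing_ct"
  res <- classify_batch(list(fx$model, bad$model, none$model), fx$map)
  expect_equal(nrow(res), 3L)
  expect_equal(unname(attr(res, "summary")),
               c(1L, 1L, 1L))
  expect_equal(res$entry_id, sort(res$entry_id))
  empty <- classify_batch(list(), list())
  expect_equal(nrow(empty), 0L)
  expect_equal(unname(attr(empty, "summary")), c(0L, 0L, 0L))
})
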