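# Intramolecular ipSAE of the activation loop and model selection.

test_that("ipSAE closed forms: zero PAE gives 1, PAE = d0 gives 0.5", {
  s0 <- synth_prediction_scores(30, 10:20, "uniform", pae_value = 0)
  expect_equal(ipsae_actloop(s0, 10:20)$value, 1)
  s4 <- synth_prediction_scores(30, 10:20, "uniform", pae_value = 4)
  expect_equal(ipsae_actloop(s4, 10:20, d0 = 4)$value, 0.5)
  # score is bounded in (0, 1]
  sbig <- synth_prediction_scores(30, 10:20, "uniform", pae_value = 30)
  v <- ipsae_actloop(sbig, 10:20)$value
  expect_gt(v, 0); expect_lte(v, 1)
})

test_that("ipSAE equals a hand-written double loop on random matrices", {
  for (seed in c(7, 19, 101)) {
    s <- synth_prediction_scores(12, 4:7, "random", pae_max = 15, seed = seed,
                                 plddt_value = c(rep(90, 6), rep(40, 6)))
    got <- ipsae_actloop(s, 4:7)
    expect_equal(got$value, oracle_ipsae(s$pae, s$plddt, 4:7),
                 tolerance = 1e-12, label = paste("seed", seed))
    expect_equal(got$n_aligned, sum(s$plddt[-(4:7)] > 60))
  }
  # a 6-residue toy with exactly two eligible rows: max of the two means
  pae <- matrix(8, 6, 6)
  pae[1, 3:5] <- c(2, 4, 6); pae[6, 3:5] <- c(1, 1, 10)
  s <- prediction_scores(pae, c(90, 10, 90, 90, 90, 70))
  v <- ipsae_actloop(s, 3:5)
  by_hand <- max(mean(1 / (1 + (c(2, 4, 6) / 4)^2)),
                 mean(1 / (1 + (c(1, 1, 10) / 4)^2)))
  expect_equal(v$value, by_hand, tolerance = 1e-12)
})

test_that("ipSAE is monotone in eligible-row PAE and ignores the rest", {
  s <- synth_prediction_scores(15, 6:9, "random", pae_max = 10, seed = 5)
  base <- ipsae_actloop(s, 6:9)$value
  # raising any PAE entry in eligible rows never raises the score
  for (i in c(1, 3, 12)) for (j in 6:9) {
    s2 <- s
    s2$pae[i, j] <- s2$pae[i, j] + 5
    expect_lte(ipsae_actloop(s2, 6:9)$value, base + 1e-12)
  }
  # entries in loop rows (ineligible i) and non-loop columns are irrelevant
  s3 <- s
  s3$pae[6:9, ] <- 99
  s3$pae[, c(1:5, 10:15)] <- 99
  expect_equal(ipsae_actloop(s3, 6:9)$value, base, tolerance = 1e-12)
  # loop order is irrelevant
  expect_equal(ipsae_actloop(s, c(9, 7, 6, 8))$value, base)
})

test_that("the pLDDT gate is strict by default and configurable", {
  s <- synth_prediction_scores(10, 5:7, "uniform", pae_value = 2,
                               plddt_value = c(rep(60, 7), rep(80, 3)))
  # strict >: only residues 8..10 are eligible
  expect_equal(ipsae_actloop(s, 5:7)$n_aligned, 3L)
  expect_equal(ipsae_actloop(s, 5:7, strict = FALSE)$n_aligned, 7L)
  s2 <- synth_prediction_scores(10, 5:7, "uniform", pae_value = 2,
                                plddt_value = 50)
  expect_error(ipsae_actloop(s2, 5:7), "scoring error")
  expect_error(ipsae_actloop(s, integer()), "empty")
  expect_error(ipsae_actloop(s, 1:10), "strict subset")
})

test_that("the domain restriction excludes flanking residues from alignment", {
  s <- synth_prediction_scores(20, 8:12, "uniform", pae_value = 8)
  s$pae[1, 8:12] <- 0    # a flanking tag residue with perfect PAE
  full <- ipsae_actloop(s, 8:12)
  expect_equal(full$argmax_residue, 1L)
  dom <- ipsae_actloop(s, 8:12, domain = 5:16)
  expect_false(dom$argmax_residue == 1L)
  expect_lt(dom$value, full$value)
})

test_that("select_best_model picks the top-scoring Active candidate", {
  cands <- list(list(name = "m1", label = "Active", score = 0.4),
                list(name = "m2", label = "Active", score = 0.7),
                list(name = "m3", label = "Inactive", score = 0.9))
  sel <- select_best_model(cands)
  expect_equal(sel$selected, "m2")
  expect_equal(sel$ranking$name, c("m3", "m2", "m1"))
  # no Active candidates: none selected, ranking still emitted
  sel2 <- select_best_model(list(
    list(name = "a", label = "Inactive", score = 0.9),
    list(name = "b", label = "None", score = 0.8)))
  expect_true(is.na(sel2$selected))
  expect_equal(nrow(sel2$ranking), 2L)
  # exact tie: lexicographically lowest name wins
  sel3 <- select_best_model(list(
    list(name = "zeta", label = "Active", score = 0.5),
    list(name = "alpha", label = "Active", score = 0.5)))
  expect_equal(sel3$selected, "alpha")
})

test_that("scores read from JSON with pLDDT from the B-factor column", {
  fx <- toy("all_pass_nonTYR")
  ix <- actloop_indices(fx$model, fx$map)
  n <- length(ix$domain)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(predicted_aligned_error =
                              matrix(4, n, n)), f)
  s <- read_prediction_scores(f, fx$model, chain = "A")
  expect_equal(dim(s$pae), c(n, n))
  expect_equal(s$plddt, rep(90, n))   # fixture B-factors carry pLDDT 90
  v <- ipsae_actloop(s, ix$loop, domain = ix$domain)
  expect_equal(v$value, 0.5)
})
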