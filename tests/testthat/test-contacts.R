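# Phosphoacceptor search (with crystal symmetry), domain-swap exclusion
# and contact-frequency maps.

test_that("hydroxyl/HRD-Asp search finds in-range poses and rejects far ones", {
  fx <- toy("all_pass_nonTYR")
  m <- add_substrate_chain(fx$model, fx$map, d_oh_asp = 3.0)
  h <- find_phosphoacceptors(m, fx$map, use_symmetry = FALSE)
  expect_equal(nrow(h), 1L)
  expect_equal(h$d_oh_asp, 3.0, tolerance = 1e-6)
  expect_equal(h$substrate_chain, "B")
  expect_false(h$is_symmetry_mate)
  far <- add_substrate_chain(fx$model, fx$map, d_oh_asp = 5.0)
  expect_equal(nrow(find_phosphoacceptors(far, fx$map,
                                          use_symmetry = FALSE)), 0L)
  # no mapped enzyme chain -> input error
  nohrd <- drop_residues(m, "A", fx$map$res_hrd_asp)
  expect_error(find_phosphoacceptors(nohrd, fx$map), "input error")
})

test_that("a symmetry mate can carry the phosphoacceptor", {
  # single chain in P1; the a-axis translation places a Ser hydroxyl of
  # the neighboring copy 3.2 A from the deposited HRD-Asp Od1
  asp <- rbind(
    c("CB", 0, 0, 0), c("CG", 1.4, 0.5, 0),
    c("OD1", 2.4, -0.2, 0.3), c("OD2", 2.0, -1.8, 0.0))
  ser <- rbind(c("CB", 20, 0, 0.3), c("OG", 21.2, 0.7, 0.3))
  at <- data.frame(chain = "A",
                   resno = c(rep(73L, 4), rep(10L, 2)), insert = "",
                   resid = c(rep("ASP", 4), rep("SER", 2)),
                   elety = c(asp[, 1], ser[, 1]), elesy = "C",
                   x = as.numeric(c(asp[, 2], ser[, 2])),
                   y = as.numeric(c(asp[, 3], ser[, 3])),
                   z = as.numeric(c(asp[, 4], ser[, 4])),
                   o = 1, b = 0, hetero = FALSE, stringsAsFactors = FALSE)
  # OG + a-axis image at offset -1 lands at (21.2 - a, ...): choose a so the
  # distance to OD1 (2.4, -0.2, 0.3) is 3.2 exactly
  a_len <- 21.2 - 2.4 + sqrt(3.2^2 - 0.9^2)
  model <- structure_model(at, "p1sym", cell = c(a_len, 40, 50, 90, 90, 90),
                           spacegroup = "P 1")
  map <- motif_map("CAMK_SYM", chain_id = "A", res_dfg_asp = 101,
                   res_ape_glu = 126, res_hrd_his = 71)
  h <- find_phosphoacceptors(model, map, use_symmetry = TRUE)
  expect_equal(nrow(h), 1L)
  expect_true(h$is_symmetry_mate)
  expect_equal(h$d_oh_asp, 3.2, tolerance = 1e-6)
  # asymmetric-unit-only search is a strict subset
  h0 <- find_phosphoacceptors(model, map, use_symmetry = FALSE)
  expect_equal(nrow(h0), 0L)
})

test_that("domain-swap geometry is flagged strictly below 1.5 A of the APE8 site", {
  fx <- toy("all_pass_nonTYR")
  site <- atom_xyz(fx$model, "A", actloop_index(fx$map, "APE8"), "OG1")
  expect_true(flag_domain_swap(site + c(0.5, 0, 0), fx$model, fx$map))
  expect_false(flag_domain_swap(site + c(0, 0, 6), fx$model, fx$map))
  expect_false(flag_domain_swap(site + c(1.5, 0, 0), fx$model, fx$map))
  # reconstructed site when APE8 has no hydroxyl (TYR fixtures have Pro)
  ty <- toy("all_pass_TYR")
  cb <- atom_xyz(ty$model, "A", actloop_index(ty$map, "APE8"), "CB")
  expect_type(flag_domain_swap(cb + c(0, 0, 6), ty$model, ty$map), "logical")
  # substrate placed from above is not a swap end-to-end
  m <- add_substrate_chain(fx$model, fx$map, d_oh_asp = 3.0)
  h <- flag_domain_swaps(find_phosphoacceptors(m, fx$map,
                                               use_symmetry = FALSE),
                         m, fx$map)
  expect_false(h$swap_flag[1])
})

test_that("contact maps count heavy-atom pairs within 5 A, axes fixed", {
  fx <- toy("all_pass_nonTYR")
  dfg4_ca <- atom_xyz(fx$model, "A", actloop_index(fx$map, "DFG4"), "CA")
  sub <- data.frame(chain = "B", resno = 501L, insert = "", resid = "ALA",
                    elety = "CA", elesy = "C", x = dfg4_ca[1] + 3,
                    y = dfg4_ca[2], z = dfg4_ca[3], o = 1, b = 0,
                    hetero = FALSE, stringsAsFactors = FALSE)
  # isolate DFG4: remove every other activation-loop residue so the probe
  # can only contact DFG4
  m <- fx$model
  loop_res <- fx$map$res_dfg_asp:fx$map$res_ape_glu
  m <- drop_residues(m, "A",
                     setdiff(loop_res, actloop_index(fx$map, "DFG4")))
  m$atoms <- rbind(m$atoms, sub)
  cm <- contact_map(m, fx$map, "B", 501L)
  expect_equal(dim(cm$counts), c(11L, 24L))
  nz <- which(cm$counts > 0, arr.ind = TRUE)
  expect_equal(unique(rownames(cm$counts)[nz[, 1]]), "P+0")
  expect_equal(unique(colnames(cm$counts)[nz[, 2]]), "DFG4")
  # shifted 20 A away: all-zero map
  m2 <- m
  sel <- m2$atoms$chain == "B"
  m2$atoms$x[sel] <- m2$atoms$x[sel] + 20
  expect_equal(sum(contact_map(m2, fx$map, "B", 501L)$counts), 0L)
})

test_that("contact counts equal an exhaustive pairwise oracle", {
  fx <- toy("all_pass_nonTYR")
  m <- add_substrate_chain(fx$model, fx$map, d_oh_asp = 3.0)
  cm <- contact_map(m, fx$map, "B", 501L)
  cfg <- active_config()
  for (si in seq(-5, 5)) for (l in c("DFG4", "DFG6", "APE9", "APE8", "APE5")) {
    sres <- m$atoms[m$atoms$chain == "B" & m$atoms$resno == 501L + si, ]
    lres <- m$atoms[m$atoms$chain == "A" &
                      m$atoms$resno == actloop_index(fx$map, l), ]
    if (!nrow(sres) || !nrow(lres)) next
    expect_equal(cm$counts[paste0("P", sprintf("%+d", si)), l],
                 oracle_contact_count(as.matrix(sres[, c("x", "y", "z")]),
                                      as.matrix(lres[, c("x", "y", "z")]),
                                      cfg$contact_cutoff))
  }
})

test_that("contact-map averaging reproduces hand aggregation", {
  fx <- toy("all_pass_nonTYR")
  m <- add_substrate_chain(fx$model, fx$map, d_oh_asp = 3.0)
  cm <- contact_map(m, fx$map, "B", 501L)
  avg2 <- average_contacts(list(cm, cm))
  expect_equal(avg2$mean, cm$counts + 0)
  zero <- cm
  zero$counts[] <- 0L
  half <- average_contacts(list(cm, zero))
  expect_equal(half$mean, cm$counts / 2)
  # three maps vs hand aggregation
  three <- average_contacts(list(cm, cm, zero))
  expect_equal(three$mean, (2 * cm$counts) / 3)
  expect_equal(three$per_loop_residue, colSums((2 * cm$counts) / 3))
  # axis mismatch
  badaxes <- cm
  colnames(badaxes$counts)[1] <- "XXX"
  expect_error(average_contacts(list(cm, badaxes)), "aggregation error")
})
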