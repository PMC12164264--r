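test_that("only exact potencies survive filtering", {
  recs <- data.frame(ligand_id = c("a", "b", "c", "d"),
                     qualifier = c("exact", "<", ">", "~"))
  expect_message(out <- filter_exact_activities(recs), "removed 3")
  expect_identical(out$ligand_id, "a")
  all_exact <- data.frame(ligand_id = c("a", "b"), qualifier = "exact")
  expect_identical(filter_exact_activities(all_exact), all_exact)
  empty <- all_exact[0, ]
  expect_identical(nrow(filter_exact_activities(empty)), 0L)
})

test_that("potency ratios convert to the conventional free-energy scale", {
  # the 100-fold activity-cliff threshold
  expect_equal(round(pair_free_energy_difference(100e-9, 1e-9), 2), 2.73)
  expect_equal(pair_free_energy_difference(5e-9, 5e-9), 0)
  # the strongest cliff in the benchmark series: K_D 51.2 vs 0.494 nM
  expect_equal(round(pair_free_energy_difference(51.2e-9, 0.494e-9), 2), 2.75)
  expect_error(pair_free_energy_difference(-1, 2), "positive")
})

test_that("unit conversion recognizes molar prefixes and rejects junk", {
  expect_equal(potency_to_molar(1, "nM"), 1e-9)
  expect_equal(potency_to_molar(c(2, 2), c("uM", "µM")), c(2e-6, 2e-6))
  expect_error(potency_to_molar(1, "furlongs"), "unrecognized")
  expect_error(potency_to_molar(0, "nM"), "positive")
})

test_that("Tanimoto handles identity, disjoint sets, and the MACCS reference pair", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(maccs_tanimoto("c1ccccc1", "c1ccccc1"), 1)
  # value frozen from an independent cheminformatics toolkit (RDKit MACCS):
  # benzene vs toluene share 3 of 4 set keys
  expect_equal(maccs_tanimoto("c1ccccc1", "Cc1ccccc1"), 0.75)
  expect_equal(maccs_tanimoto("Cc1ccccc1", "c1ccccc1"), 0.75)  # symmetric
  expect_error(maccs_fingerprint("not-a-smiles(("), "parse")
})

test_that("pairs are canonically ordered, labelled, and similarity-gated", {
  recs <- toy_records()
  fps <- uniform_fps(3)
  pairs <- build_pairs(recs, cliff_criteria(), fingerprints = fps)
  expect_equal(nrow(pairs), 3L)          # all pairs, identical fingerprints
  ab <- pairs[pairs$id_weak == "A" & pairs$id_strong == "B", ]
  expect_equal(nrow(ab), 1L)             # 51.2/0.494 = 103.6-fold: a cliff
  expect_true(ab$is_cliff)
  ac <- pairs[pairs$id_weak == "A" & pairs$id_strong == "C", ]
  expect_false(ac$is_cliff)              # 10.2-fold: below 100-fold

  # similarity gate: disjoint fingerprints drop every pair
  fps2 <- rbind(c(TRUE, rep(FALSE, 15)), c(FALSE, TRUE, rep(FALSE, 14)),
                c(rep(FALSE, 2), TRUE, rep(FALSE, 13)))
  expect_equal(nrow(build_pairs(recs, cliff_criteria(), fingerprints = fps2)),
               0L)
  expect_warning(build_pairs(recs[1, ], cliff_criteria(),
                             fingerprints = fps[1, , drop = FALSE]),
                 "fewer than two")
})

test_that("pair labels are invariant to record order and unit choice", {
  recs <- toy_records()
  fps <- uniform_fps(3)
  a <- build_pairs(recs, cliff_criteria(), fingerprints = fps)
  perm <- c(3, 1, 2)
  b <- build_pairs(recs[perm, ], cliff_criteria(),
                   fingerprints = fps[perm, , drop = FALSE])
  expect_equal(a, b)

  recs_m <- recs
  recs_m$potency_value <- recs$potency_value * 1e-9
  recs_m$potency_units <- "M"
  c2 <- build_pairs(recs_m, cliff_criteria(), fingerprints = fps)
  expect_equal(a$ddg_bind, c2$ddg_bind)
  expect_equal(a$is_cliff, c2$is_cliff)
})

test_that("pair count is bounded by n(n-1)/2 with equality at cutoff zero", {
  set.seed(21)
  n <- 8
  recs <- data.frame(ligand_id = sprintf("L%02d", 1:n),
                     potency_value = 10^runif(n, -1, 3),
                     potency_units = "nM", potency_type = "KD",
                     qualifier = "exact", stringsAsFactors = FALSE)
  fps <- matrix(runif(n * 32) < 0.5, nrow = n)
  all_pairs <- build_pairs(recs, cliff_criteria(similarity_cutoff = 0),
                           fingerprints = fps)
  expect_equal(nrow(all_pairs), n * (n - 1) / 2)
  some <- build_pairs(recs, cliff_criteria(similarity_cutoff = 0.6),
                      fingerprints = fps)
  expect_lte(nrow(some), n * (n - 1) / 2)
})

test_that("IC50 potencies are only compared within a series", {
  recs <- data.frame(ligand_id = c("a", "b", "c"),
                     potency_value = c(1000, 5, 12),
                     potency_units = "nM", potency_type = "IC50",
                     qualifier = "exact",
                     series_id = c("s1", "s1", "s2"),
                     stringsAsFactors = FALSE)
  pairs <- build_pairs(recs, cliff_criteria(similarity_cutoff = 0),
                       fingerprints = uniform_fps(3))
  expect_equal(nrow(pairs), 1L)
  expect_identical(pairs$id_weak, "a")
  expect_identical(pairs$id_strong, "b")
})
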