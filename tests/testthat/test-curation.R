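records_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(pdb_id = r[[1]], chain = r[[2]], mut_code = r[[3]],
               ddg = r[[4]], ph = r[[5]], temp = r[[6]],
               stringsAsFactors = FALSE)))
}

validated <- function(df) mutation_records(df)$records

test_that("condition split partitions exhaustively; partial conditions are Group II", {
  recs <- validated(records_df(
    list("1AAA", "A", "A1G", 1.0, 7.0, 25.0),
    list("1AAA", "A", "A2G", 1.0, NA, 25.0),
    list("1AAA", "A", "A3G", 1.0, 6.0, NA)))
  g <- split_by_conditions(recs)
  expect_equal(nrow(g$group1), 1)
  expect_equal(nrow(g$group2), 2)
  expect_equal(nrow(g$group1) + nrow(g$group2), nrow(recs))
  g0 <- split_by_conditions(recs[0, ])
  expect_equal(nrow(g0$group1), 0)
  expect_equal(nrow(g0$group2), 0)
})

test_that("core selection minimizes condition distance with deterministic ties", {
  recs <- validated(records_df(
    list("1AAA", "A", "A1G", 1.0, 7.0, 25.0),
    list("1AAA", "A", "A1G", 2.0, 6.5, 25.0),
    list("2BBB", "A", "A1G", 3.0, 6.8, 25.0),
    list("2BBB", "A", "A1G", 4.0, 7.2, 25.0),
    list("3CCC", "A", "A1G", 5.0, 5.0, 40.0)))
  cores <- select_core_samples(recs)
  expect_equal(nrow(cores), 3)
  expect_equal(cores$ddg[cores$pdb_id == "1AAA"], 1.0)  # exact standard wins
  expect_equal(cores$ddg[cores$pdb_id == "2BBB"], 3.0)  # tie -> lower pH
  expect_equal(cores$ddg[cores$pdb_id == "3CCC"], 5.0)  # singleton
  expect_equal(nrow(attr(cores, "rest")), 2)
})

test_that("additional selection uses closed windows around the core's conditions", {
  recs <- validated(records_df(
    list("1AAA", "A", "A1G", 1.0, 7.0, 25.0),   # core
    list("1AAA", "A", "A1G", 2.0, 7.4, 30.0),   # inside both windows
    list("1AAA", "A", "A1G", 3.0, 7.5, 35.0),   # boundary pH, boundary T
    list("1AAA", "A", "A1G", 4.0, 7.6, 25.0),   # outside pH window
    list("1AAA", "A", "A1G", 5.0, 7.0, 36.0),   # outside T window
    list("2BBB", "A", "A1G", 6.0, NA, NA),      # Group II, unique ID
    list("1AAA", "A", "A1G", 7.0, NA, NA)))     # Group II, ID in Group I
  g <- split_by_conditions(recs)
  cores <- select_core_samples(g$group1)
  add <- select_additional_samples(attr(cores, "rest"), g$group2, cores)
  expect_setequal(add$selected$ddg, c(2.0, 3.0, 6.0))
  expect_setequal(add$rejected$ddg, c(4.0, 5.0, 7.0))
  expect_equal(sort(unique(add$rejected$reason)),
               c("ID present in Group I", "outside condition window"))
})

test_that("averaging is the arithmetic mean over member values per ID", {
  recs <- validated(records_df(
    list("1AAA", "A", "A1G", 1.0, 7.0, 25.0),
    list("1AAA", "A", "A1G", 2.0, 7.0, 25.0),
    list("2BBB", "A", "A1G", -0.7, 7.0, 25.0),
    list("3CCC", "A", "A1G", 2.0, 7.0, 25.0),
    list("3CCC", "A", "A1G", 2.0, 7.0, 25.0),
    list("3CCC", "A", "A1G", 2.0, 7.0, 25.0)))
  avg <- average_by_id(recs)
  expect_equal(setNames(avg$ddg, avg$pdb_id),
               c("1AAA" = 1.5, "2BBB" = -0.7, "3CCC" = 2.0))
  expect_equal(setNames(avg$n_members, avg$pdb_id),
               c("1AAA" = 2L, "2BBB" = 1L, "3CCC" = 3L))
})

test_that("conflict filter drops opposite signs and high kJ-space variance", {
  mk <- function(members_kcal) {
    df <- data.frame(pdb_id = "1AAA", chain = "A", mut_code = "A1G",
                     wt_aa = "A", position = 1L, mt_aa = "G",
                     id = "1AAA_A_A1G", ddg = mean(members_kcal),
                     n_members = length(members_kcal),
                     stringsAsFactors = FALSE)
    df$members <- I(list(members_kcal))
    df
  }
  # opposite signs
  out <- discard_inconsistent(mk(c(1.0, -0.5)))
  expect_equal(out$discarded$reason, "opposite signs")
  # {0, 6} kJ/mol: sample variance 18 kJ units > 5 -> dropped
  out <- discard_inconsistent(mk(kj_to_kcal(c(0, 6))))
  expect_equal(out$discarded$reason, "variance above threshold")
  # {1.0, 1.1} kJ/mol: variance 0.005 -> kept
  out <- discard_inconsistent(mk(kj_to_kcal(c(1.0, 1.1))))
  expect_equal(nrow(out$discarded), 0)
  # zero members never trigger the sign rule
  out <- discard_inconsistent(mk(c(0, 0.5)))
  expect_equal(nrow(out$discarded), 0)
  # single member always kept
  out <- discard_inconsistent(mk(c(99)))
  expect_equal(nrow(out$discarded), 0)
})

test_that("full pipeline matches the brute-force oracle on a generated fixture", {
  fx <- make_mutation_tables(fixture_spec(n_proteins = 12,
                                          ids_per_protein = 5, seed = 42))
  cur <- curate_dataset(fx$records)
  orc <- oracle_curate(fx$records)
  expect_setequal(cur$kept$id, names(orc$kept))
  expect_equal(cur$kept$ddg, unname(orc$kept[cur$kept$id]),
               tolerance = 1e-12)
  expect_setequal(cur$discarded$id, names(orc$dropped))
  expect_equal(cur$discarded$reason,
               unname(orc$dropped[cur$discarded$id]))
})

test_that("pipeline conserves records and is idempotent on its own output", {
  fx <- make_mutation_tables(fixture_spec(seed = 9))
  cur <- curate_dataset(fx$records)
  rep <- cur$report
  expect_equal(rep$n_group1 + rep$n_group2, rep$n_input)
  expect_equal(rep$n_core + rep$n_additional + rep$n_rejected_window +
                 rep$n_rejected_duplicate_id, rep$n_input)
  expect_equal(rep$n_ids_kept + rep$n_ids_discarded, rep$n_ids_averaged)

  # re-run on the curated output (unique IDs, single members): no change
  again <- cur$kept[, c("pdb_id", "chain", "mut_code", "ddg")]
  again$ph <- 7.0
  again$temp <- 25.0
  cur2 <- curate_dataset(mutation_records(again)$records)
  expect_setequal(cur2$kept$id, cur$kept$id)
  expect_equal(cur2$kept$ddg[match(cur$kept$id, cur2$kept$id)],
               cur$kept$ddg, tolerance = 1e-12)
  expect_equal(nrow(cur2$discarded), 0)
})

test_that("shrinking the condition windows never adds additional samples", {
  fx <- make_mutation_tables(fixture_spec(seed = 5))
  g <- split_by_conditions(fx$records)
  n_add <- sapply(c(1.0, 0.5, 0.25, 0.1), function(w) {
    cfg <- curation_config(ph_window = 0.5 * w, temp_window = 10 * w)
    cores <- select_core_samples(g$group1, cfg)
    nrow(select_additional_samples(attr(cores, "rest"), g$group2,
                                   cores, cfg)$selected)
  })
  expect_true(all(diff(n_add) <= 0))
})

test_that("per-wild-type subsampling caps at 70 and is seed-deterministic", {
  n_big <- 200
  recs <- validated(do.call(records_df, c(
    lapply(seq_len(n_big), function(i)
      list("1BIG", "A", sprintf("A%dG", i), 1.0, 7.0, 25.0)),
    lapply(1:12, function(i)
      list("2SML", "A", sprintf("A%dG", i), 1.0, 7.0, 25.0)))))
  seqs <- c("1BIG_A" = paste(rep("A", n_big), collapse = ""),
            "2SML_A" = paste(rep("A", 12), collapse = ""))
  cfg <- curation_config(seed = 31)
  sub <- subsample_per_wt(recs, seqs, cfg)
  expect_equal(sum(sub$pdb_id == "1BIG"), 70)
  expect_equal(sum(sub$pdb_id == "2SML"), 12)
  sub2 <- subsample_per_wt(recs, seqs, cfg)
  expect_identical(sub, sub2)
  sub3 <- subsample_per_wt(recs, seqs, curation_config(seed = 32))
  expect_false(identical(sub$mut_code, sub3$mut_code))
})

test_that("reverse augmentation doubles the set with antisymmetric targets", {
  bb <- backbone_mock(width = 8, seed = 1)
  ds <- make_recoverable_dataset(bb, n = 25, seed = 3)
  aug <- augment_with_reverses(ds$pairs)
  expect_equal(nrow(aug), 2 * nrow(ds$pairs))
  expect_equal(sum(aug$ddg), 0, tolerance = 1e-12)
  # grouped by unordered sequence pair, ddg sums vanish
  key <- apply(cbind(aug$wt_seq, aug$mt_seq), 1,
               function(x) paste(sort(x), collapse = "|"))
  sums <- tapply(aug$ddg, key, sum)
  expect_true(all(abs(sums) < 1e-12))
  # no reverse-of-reverse duplication: each unordered pair appears twice
  expect_true(all(table(key) == 2))
})

test_that("homology filter removes training proteins hitting test sequences", {
  seqs <- c(
    T001_A = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
    T002_A = "ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNP",
    T003_A = "WYYWWYWYWWYYWWYWYWYYWWYWYWYWYWYWW")
  train <- validated(records_df(
    list("T001", "A", "M1A", 1.0, 7.0, 25.0),
    list("T002", "A", "A1G", 1.0, 7.0, 25.0),
    list("T003", "A", "W1A", 1.0, 7.0, 25.0)))
  # test set contains T001's exact sequence; T002/T003 are unrelated
  out <- homology_filter(train, c(test1 = seqs[["T001_A"]]),
                         sequences = seqs)
  expect_equal(out$removed$pdb_id, "T001")
  expect_setequal(out$kept$pdb_id, c("T002", "T003"))
  expect_true(all(out$hits$identity > 30 & out$hits$evalue < 0.05))
  expect_error(homology_filter(train, c(t = "AAAA"), backend = NULL,
                               sequences = seqs),
               "identity_backend_naive")
})

test_that("homology removal requires identity AND E-value jointly", {
  fake_backend <- function(q, s)
    data.frame(query = names(q)[1], subject = names(s)[1],
               identity = 40, evalue = 0.5, stringsAsFactors = FALSE)
  train <- validated(records_df(list("T001", "A", "M1A", 1.0, 7.0, 25.0)))
  out <- homology_filter(train, c(t = "AAAA"), backend = fake_backend,
                         sequences = c(T001_A = "MAAA"))
  expect_equal(nrow(out$removed), 0)
})

test_that("structure-defined test sets follow ligand and interface rules", {
  d <- withr::local_tempdir()
  toy <- make_toy_structures(d, n_per_chain = 10, n_contact = 4)
  # a second dimer sitting exactly at the 30% boundary (3 of 10)
  toy3 <- make_toy_structures(file.path(d, "b"), n_per_chain = 10,
                              n_contact = 3)
  structures <- list(
    DIM4 = read_structure(toy$files[["dimer"]]),
    DIM3 = read_structure(toy3$files[["dimer"]]),
    MONO = read_structure(toy$files[["monomer"]]),
    LIGD = read_structure(toy$files[["liganded"]]))
  recs <- validated(records_df(
    list("DIM4", "A", "A1G", 1.0, 7.0, 25.0),
    list("DIM3", "A", "A1G", 1.0, 7.0, 25.0),
    list("MONO", "A", "A1G", 1.0, 7.0, 25.0),
    list("LIGD", "A", "A1G", 1.0, 7.0, 25.0),
    list("MISS", "A", "A1G", 1.0, 7.0, 25.0)))
  expect_warning(sets <- build_stability_test_sets(recs, structures),
                 "no structure")
  expect_equal(sets$hemoglobin$pdb_id, "LIGD")
  # strictly-over-30% rule: 0.40 qualifies, 0.30 does not; monomers never
  expect_equal(sets$oligomerization$pdb_id, "DIM4")
  expect_equal(sets$report$n_missing_structure, 1)
})
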