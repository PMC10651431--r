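test_that("interchain contacts respect the 4.5 A cutoff boundary", {
  d <- withr::local_tempdir()
  near <- file.path(d, "near.pdb")
  write_toy_pdb(list(A = data.frame(resno = 1, x = 0, y = 0, z = 0),
                     B = data.frame(resno = 1, x = 0, y = 4.4, z = 0)),
                path = near)
  st <- read_structure(near)
  flags <- interchain_contacts(st, 4.5)
  expect_setequal(paste(flags$chain, flags$resno), c("A 1", "B 1"))

  far <- file.path(d, "far.pdb")
  write_toy_pdb(list(A = data.frame(resno = 1, x = 0, y = 0, z = 0),
                     B = data.frame(resno = 1, x = 0, y = 4.6, z = 0)),
                path = far)
  expect_equal(nrow(interchain_contacts(read_structure(far), 4.5)), 0)

  mono <- file.path(d, "mono.pdb")
  write_toy_pdb(list(A = data.frame(resno = 1:3, x = c(0, 4, 8),
                                    y = 0, z = 0)), path = mono)
  expect_equal(nrow(interchain_contacts(read_structure(mono), 4.5)), 0)
})

test_that("contact flags are symmetric across chains", {
  d <- withr::local_tempdir()
  p <- file.path(d, "dim.pdb")
  toy <- make_toy_structures(d, n_per_chain = 8, n_contact = 3)
  st <- read_structure(toy$files[["dimer"]])
  flags <- interchain_contacts(st, 4.5)
  expect_true(all(c("A", "B") %in% flags$chain))
  expect_setequal(flags$resno[flags$chain == "A"],
                  flags$resno[flags$chain == "B"])
})

test_that("interface fraction applies the strict over-30% rule", {
  d <- withr::local_tempdir()
  toy3 <- make_toy_structures(file.path(d, "c3"), n_per_chain = 10,
                              n_contact = 3)
  toy4 <- make_toy_structures(file.path(d, "c4"), n_per_chain = 10,
                              n_contact = 4)
  st3 <- read_structure(toy3$files[["dimer"]])
  st4 <- read_structure(toy4$files[["dimer"]])
  cfg <- contact_config()
  f3 <- interface_fraction(st3, "A", cfg$distance_cutoff)
  f4 <- interface_fraction(st4, "A", cfg$distance_cutoff)
  expect_equal(f3, 0.30)
  expect_equal(f4, 0.40)
  expect_false(f3 > cfg$interface_fraction_threshold)
  expect_true(f4 > cfg$interface_fraction_threshold)
  expect_error(interface_fraction(st3, "Z"), "not in structure")
})

test_that("interface fraction is monotone non-decreasing in the cutoff", {
  d <- withr::local_tempdir()
  toy <- make_toy_structures(d, n_per_chain = 10, n_contact = 4,
                             far_dist = 12)
  st <- read_structure(toy$files[["dimer"]])
  fr <- sapply(c(2, 4.5, 8, 13, 20), function(cut)
    interface_fraction(st, "A", cut))
  expect_true(all(diff(fr) >= 0))
})

test_that("ligand contacts flag residues near selected hetero codes only", {
  d <- withr::local_tempdir()
  toy <- make_toy_structures(d)
  stl <- read_structure(toy$files[["liganded"]])
  lc <- ligand_contacts(stl, c("HEM", "HEC", "BLA"), 4.5)
  expect_equal(lc, toy$expected$ligand_contacts)
  expect_equal(nrow(ligand_contacts(stl, "XYZ", 4.5)), 0)
  expect_equal(nrow(ligand_contacts(stl, "HEM", 0)), 0)
  st_no <- read_structure(toy$files[["dimer"]])
  expect_equal(nrow(ligand_contacts(st_no, c("HEM", "HEC", "BLA"), 4.5)), 0)
})

test_that("neighbor flags equal the brute-force all-pairs oracle", {
  d <- withr::local_tempdir()
  with_seed(17, {
    for (rep in 1:3) {
      n <- sample(10:25, 1)
      chains <- list(
        A = data.frame(resno = 1:n, x = runif(n, 0, 25),
                       y = runif(n, 0, 25), z = runif(n, 0, 25)),
        B = data.frame(resno = 1:n, x = runif(n, 0, 25),
                       y = runif(n, 0, 25), z = runif(n, 0, 25)))
      het <- data.frame(code = "HEM", chain = "A", resno = 900L,
                        x = runif(1, 0, 25), y = runif(1, 0, 25),
                        z = runif(1, 0, 25))
      p <- file.path(d, sprintf("rand%d.pdb", rep))
      write_toy_pdb(chains, hetero = het, path = p)
      st <- read_structure(p)
      got <- interchain_contacts(st, 4.5)
      expect_equal(sort(paste(got$chain, got$resno)),
                   oracle_interchain(st, 4.5))
      gotl <- ligand_contacts(st, "HEM", 4.5)
      expect_equal(sort(paste(gotl$chain, gotl$resno)),
                   oracle_ligand(st, "HEM", 4.5))
    }
  })
})

test_that("DSSP parsing maps states, normalizes ASA and clips to 1", {
  d <- withr::local_tempdir()
  toy <- make_toy_structures(d, n_per_chain = 6)
  st <- read_structure(toy$files[["monomer"]])
  ann_in <- data.frame(chain = "A", resno = 1:5,  # residue 6 left unknown
                       aa = rep("A", 5),
                       ss8 = c("H", "G", "E", "B", "T"),
                       acc = c(10, 200, 30, 64, 130))
  dssp_path <- file.path(d, "toy.dssp")
  write_toy_dssp(ann_in, dssp_path)
  parsed <- read_dssp(dssp_path)
  expect_equal(parsed$ss8, ann_in$ss8)
  expect_equal(parsed$acc, ann_in$acc)

  ann <- annotate_burial_ss(st, dssp_path)
  expect_equal(ann$ss3[1:5], c("helix", "helix", "strand", "strand",
                               "coil"))
  # ALA reference max 129: 200 clips to 1; 10/129 is buried at 0.25
  expect_equal(ann$rel_asa[2], 1.0)
  expect_equal(ann$rel_asa[1], 10 / 129)
  expect_true(ann$buried[1])
  expect_false(ann$buried[2])
  # residue missing from DSSP is unknown and counted
  expect_true(is.na(ann$rel_asa[6]))
  expect_equal(attr(ann, "n_unknown"), 1)
})

test_that("stratified metrics preserve the partition and handle small strata", {
  with_seed(8, {
    n <- 30
    preds <- rnorm(n)
    targ <- preds  # identical within every stratum -> r = 1
    strata <- sample(c("buried", "exposed", NA), n, replace = TRUE)
    out <- stratified_metrics(preds, targ, strata)
    total <- sum(vapply(out, `[[`, 0, "n"))
    expect_equal(total, n)
    for (nm in setdiff(names(out), "unknown"))
      if (!out[[nm]]$insufficient) expect_equal(out[[nm]]$r, 1)
    # single stratum: others absent, no crash
    out1 <- stratified_metrics(preds, targ, rep("helix", n))
    expect_named(out1, "helix")
    # stratum of size 1 is insufficient
    out2 <- stratified_metrics(preds[1:3], targ[1:3],
                               c("a", "a", "b"))
    expect_true(out2$b$insufficient)
  })
})

test_that("full structure annotation merges interface, ligand and DSSP labels", {
  d <- withr::local_tempdir()
  toy <- make_toy_structures(d, n_per_chain = 6, n_contact = 2)
  st <- read_structure(toy$files[["dimer"]])
  ann <- annotate_structure(st)
  expect_equal(sum(ann$interface), 4)  # 2 per chain
  expect_true(all(is.na(ann$rel_asa)))
  stl <- read_structure(toy$files[["liganded"]])
  annl <- annotate_structure(stl)
  expect_equal(annl$resno[annl$ligand_contact], 1)
})
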