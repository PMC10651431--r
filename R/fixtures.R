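#' Specification for synthetic mutation-table fixtures
#'
#' Controls a generator that emulates the heterogeneity of merged
#' thermodynamic sources: duplicate IDs across tables, divergent pH/T,
#' records without conditions, planted sign conflicts and high-variance
#' groups. Every planted scenario has a known curation outcome, so the
#' generator emits a manifest stating, for every ID, whether the
#' pipeline should keep or drop it and the expected averaged ddG.
#'
#' @param n_proteins Number of wild-type proteins.
#' @param ids_per_protein Mutation IDs per protein.
#' @param seq_len_range Min/max sequence length.
#' @param frac_group2 Fraction of IDs measured without conditions
#'   (kept via the unique-to-Group-II rule).
#' @param frac_conflict Fraction of IDs planted with opposite-sign
#'   members (dropped).
#' @param frac_high_variance Fraction of IDs planted with uniform-sign,
#'   high-variance members (dropped).
#' @param frac_multi Fraction of clean IDs given several in-window
#'   members (averaged).
#' @param frac_window_outlier Fraction of clean IDs given an extra
#'   member outside the condition window (excluded from the mean).
#' @param n_tables Number of overlapping source tables to split records
#'   across (2 or 3).
#' @param seed Mandatory seed; the generator is a pure function of
#'   (spec, seed).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 10L, ids_per_protein = 5L,
                         seq_len_range = c(30L, 60L),
                         frac_group2 = 0.15, frac_conflict = 0.10,
                         frac_high_variance = 0.10, frac_multi = 0.30,
                         frac_window_outlier = 0.15, n_tables = 3L,
                         seed = 1L) {
  fr <- c(frac_group2, frac_conflict, frac_high_variance, frac_multi,
          frac_window_outlier)
  abort_if(any(fr < 0 | fr > 1) || sum(fr) > 1,
           "scenario fractions must lie in [0,1] and sum to at most 1")
  abort_if(!(n_tables %in% 2:3), "n_tables must be 2 or 3")
  abort_if(is.null(seed), "seed is mandatory")
  structure(list(n_proteins = as.integer(n_proteins),
                 ids_per_protein = as.integer(ids_per_protein),
                 seq_len_range = as.integer(seq_len_range),
                 frac_group2 = frac_group2, frac_conflict = frac_conflict,
                 frac_high_variance = frac_high_variance,
                 frac_multi = frac_multi,
                 frac_window_outlier = frac_window_outlier,
                 n_tables = as.integer(n_tables), seed = as.integer(seed)),
            class = "fixture_spec")
}

random_sequence <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# a clean base ddG: magnitude in [0.5, 3] so small in-group spreads can
# never flip the sign, random direction
base_ddg <- function() sample(c(-1, 1), 1) * runif(1, 0.5, 3)

#' Generate synthetic mutation tables with a known curation outcome
#'
#' Emits `n_tables` overlapping source tables plus a manifest. Scenario
#' vocabulary (one per ID): `single` (one Group-I record at standard
#' conditions), `multi` (core plus in-window members, averaged),
#' `window_outlier` (an extra member outside the condition window,
#' excluded from the mean; its record is window-rejected),
#' `group2_unique` (one record without conditions, kept),
#' `sign_conflict` (opposite-sign members, dropped),
#' `high_variance` (uniform-sign members with sample variance above
#' 5 kJ/mol, dropped). A further duplicate without conditions is planted
#' for some Group-I IDs to exercise the duplicate-ID rejection.
#'
#' @param spec A [fixture_spec()].
#' @return List: `tables` (list of record data frames, canonical units),
#'   `records` (all rows combined, validated), `sequences` (named
#'   wild-type sequences), `manifest` (per-ID expectations: id,
#'   scenario, expect_kept, expect_reason, expect_ddg,
#'   expect_n_members), `counts` (expected record-level rejection
#'   counts).
#' @export
make_mutation_tables <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    n_ids <- spec$n_proteins * spec$ids_per_protein
    n_of <- function(f) round(f * n_ids)
    scen <- c(rep("group2_unique", n_of(spec$frac_group2)),
              rep("sign_conflict", n_of(spec$frac_conflict)),
              rep("high_variance", n_of(spec$frac_high_variance)),
              rep("multi", n_of(spec$frac_multi)),
              rep("window_outlier", n_of(spec$frac_window_outlier)))
    abort_if(length(scen) > n_ids, "infeasible spec: fractions exceed 1")
    scen <- sample(c(scen, rep("single", n_ids - length(scen))))

    sequences <- character(spec$n_proteins)
    names(sequences) <- sprintf("P%03d_A", seq_len(spec$n_proteins))
    rows <- list()
    manifest <- list()
    n_window_rejected <- 0L
    n_dup_rejected <- 0L
    k <- 0L

    for (p in seq_len(spec$n_proteins)) {
      len <- sample(spec$seq_len_range[1]:spec$seq_len_range[2], 1)
      seqp <- random_sequence(len)
      pdb_id <- sprintf("P%03d", p)
      sequences[[sprintf("%s_A", pdb_id)]] <- seqp
      positions <- sample(seq_len(len), spec$ids_per_protein)
      for (j in seq_len(spec$ids_per_protein)) {
        k <- k + 1L
        pos <- positions[j]
        wt <- substr(seqp, pos, pos)
        mt <- sample(setdiff(AA_ALPHABET, wt), 1)
        code <- sprintf("%s%d%s", wt, pos, mt)
        id <- paste(pdb_id, "A", code, sep = "_")
        sc <- scen[k]
        v <- base_ddg()
        s <- sign(v)
        add <- function(ddg, ph, temp) {
          rows[[length(rows) + 1L]] <<- data.frame(
            pdb_id = pdb_id, chain = "A", mut_code = code, ddg = ddg,
            ph = ph, temp = temp, stringsAsFactors = FALSE)
        }
        if (sc == "single") {
          add(v, 7.0, 25.0)
          exp <- list(TRUE, NA_character_, v, 1L)
        } else if (sc == "multi") {
          d <- s * runif(1, 0.05, 0.2)
          add(v, 7.0, 25.0)
          add(v + d, 7 + runif(1, -0.4, 0.4), 25 + runif(1, -8, 8))
          exp <- list(TRUE, NA_character_, mean(c(v, v + d)), 2L)
        } else if (sc == "window_outlier") {
          add(v, 7.0, 25.0)
          add(v + s * runif(1, 0.05, 0.2), 8.2, 25.0)  # pH outside core+-0.5
          n_window_rejected <- n_window_rejected + 1L
          # half of these also get a duplicate Group-II record
          if (runif(1) < 0.5) {
            add(v + s * 0.1, NA, NA)
            n_dup_rejected <- n_dup_rejected + 1L
          }
          exp <- list(TRUE, NA_character_, v, 1L)
        } else if (sc == "group2_unique") {
          add(v, NA, NA)
          exp <- list(TRUE, NA_character_, v, 1L)
        } else if (sc == "sign_conflict") {
          add(v, 7.0, 25.0)
          add(-s * runif(1, 0.5, 2), 7.1, 26.0)
          exp <- list(FALSE, "opposite signs", NA_real_, 2L)
        } else { # high_variance: spread > sqrt(10)/4.184 kcal keeps the
          # kJ-space sample variance of a 2-point set above 5
          d <- s * runif(1, 1.1, 2.0)
          add(v, 7.0, 25.0)
          add(v + d, 7.1, 26.0)
          exp <- list(FALSE, "variance above threshold", NA_real_, 2L)
        }
        manifest[[k]] <- data.frame(
          id = id, scenario = sc, expect_kept = exp[[1]],
          expect_reason = exp[[2]], expect_ddg = exp[[3]],
          expect_n_members = exp[[4]], stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rows)
    records$source <- sprintf("table%d",
                              sample.int(spec$n_tables, nrow(records),
                                         replace = TRUE))
    tables <- split(records, records$source)
    validated <- mutation_records(records)$records
    list(tables = unname(tables), records = validated,
         sequences = sequences,
         manifest = do.call(rbind, manifest),
         counts = list(n_window_rejected = n_window_rejected,
                       n_duplicate_id_rejected = n_dup_rejected))
  })
}

pdb_atom_line <- function(record, serial, name, resn, chain, resno,
                          x, y, z, element) {
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, " ", resn, chain, resno, " ",
          x, y, z, 1.00, 0.00, element)
}

#' Write a toy PDB file from explicit coordinates
#'
#' Idealized single-atom residues (CA only) plus optional hetero atoms,
#' in fixed-column PDB format, sufficient for distance-rule tests; no
#' attempt at stereochemical realism.
#'
#' @param chains Named list (by chain ID) of data frames with `resno`,
#'   `x`, `y`, `z` and optionally `aa3` (default `"ALA"`).
#' @param hetero Optional data frame with `code`, `chain`, `resno`,
#'   `x`, `y`, `z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toy_pdb <- function(chains, hetero = NULL, path) {
  lines <- character(0)
  serial <- 0L
  for (ch in names(chains)) {
    d <- chains[[ch]]
    aa3 <- d$aa3 %||% rep("ALA", nrow(d))
    for (i in seq_len(nrow(d))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line("ATOM", serial, " CA ", aa3[i], ch,
                                      d$resno[i], d$x[i], d$y[i], d$z[i],
                                      "C"))
    }
    lines <- c(lines, "TER")
  }
  if (!is.null(hetero)) {
    for (i in seq_len(nrow(hetero))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line("HETATM", serial, "FE  ",
                                      hetero$code[i], hetero$chain[i],
                                      hetero$resno[i], hetero$x[i],
                                      hetero$y[i], hetero$z[i], "FE"))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate toy structures with known contact sets
#'
#' Writes three small PDB files into `dir`: a dimer whose first
#' `n_contact` residue pairs sit at `contact_dist` across the two chains
#' (the rest far apart), a monomer, and a monomer with a planted
#' hetero-residue (`ligand_code`) 3 Angstrom from residue 1. The
#' expected interface and ligand-contact sets follow by construction.
#'
#' @param dir Output directory.
#' @param n_per_chain Residues per chain.
#' @param n_contact Cross-chain residue pairs placed at `contact_dist`.
#' @param contact_dist Separation of contacting pairs (default 4.4).
#' @param far_dist Separation of non-contacting pairs (default 30).
#' @param ligand_code Hetero-residue code for the liganded monomer.
#' @return List with `files` (named paths) and `expected` (interface
#'   residues per chain, interface fraction, ligand-contact set).
#' @export
make_toy_structures <- function(dir, n_per_chain = 10L, n_contact = 4L,
                                contact_dist = 4.4, far_dist = 30,
                                ligand_code = "HEM") {
  abort_if(n_contact > n_per_chain, "n_contact exceeds n_per_chain")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  i <- seq_len(n_per_chain)
  chain_a <- data.frame(resno = i, x = 10 * i, y = 0, z = 0)
  chain_b <- data.frame(resno = i, x = 10 * i,
                        y = ifelse(i <= n_contact, contact_dist, far_dist),
                        z = 0)
  dimer <- file.path(dir, "toy_dimer.pdb")
  write_toy_pdb(list(A = chain_a, B = chain_b), path = dimer)
  monomer <- file.path(dir, "toy_monomer.pdb")
  write_toy_pdb(list(A = chain_a), path = monomer)
  liganded <- file.path(dir, "toy_liganded.pdb")
  write_toy_pdb(list(A = chain_a),
                hetero = data.frame(code = ligand_code, chain = "A",
                                    resno = 900L, x = 10, y = -3, z = 0),
                path = liganded)
  contact_res <- seq_len(n_contact)
  list(
    files = c(dimer = dimer, monomer = monomer, liganded = liganded),
    expected = list(
      interface = data.frame(
        chain = rep(c("A", "B"), each = n_contact),
        resno = rep(contact_res, 2), stringsAsFactors = FALSE),
      interface_fraction = n_contact / n_per_chain,
      monomer_interface = data.frame(chain = character(0),
                                     resno = integer(0)),
      ligand_contacts = data.frame(chain = "A", resno = 1L,
                                   stringsAsFactors = FALSE)
    )
  )
}

#' Write a synthetic classic-format DSSP file
#'
#' Produces the per-residue block of a classic DSSP file from explicit
#' annotations, for testing the DSSP consumer without the external tool.
#' The file is synthetic: its ASA and secondary-structure values are
#' whatever the caller supplies, not computed from coordinates.
#'
#' @param annotations Data frame with `chain`, `resno`, `aa` (1-letter),
#'   `ss8` (one DSSP state character, `""` for none), `acc` (absolute
#'   ASA, A^2).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toy_dssp <- function(annotations, path) {
  header <- c("==== Secondary Structure Definition (synthetic fixture) ====",
              "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N")
  body <- vapply(seq_len(nrow(annotations)), function(i) {
    ss <- annotations$ss8[i]
    if (is.na(ss) || ss == "") ss <- " "
    sprintf("%5d%5d %1s %1s  %1s%17s%4d", i, annotations$resno[i],
            annotations$chain[i], annotations$aa[i], ss, "",
            as.integer(round(annotations$acc[i])))
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a dataset whose targets are recoverable by construction
#'
#' Draws random wild-type sequences and single substitutions, embeds
#' them with the (mock) backbone, and sets each target to an exact
#' linear function of the difference between the wild-type and mutant
#' mutation-position rows, plus optional Gaussian noise. Because the
#' feature is antisymmetric under swapping the two sequences, every
#' pair's reverse has exactly the negated noise-free target. The
#' generating coefficients are returned for recovery tests (ordinary
#' least squares on the same features is the exact oracle at zero
#' noise).
#'
#' @param backbone A `protstab_backbone` (mock recommended).
#' @param n Number of pairs.
#' @param seed Seed; the generator is a pure function of its arguments.
#' @param noise_sd Standard deviation of additive target noise
#'   (default 0).
#' @param seq_len Sequence length of the generated wild types.
#' @param target_sd Approximate standard deviation the noise-free
#'   targets are scaled to (default 1.5, a realistic ddG spread in
#'   kcal/mol).
#' @return List: `pairs` (data frame wt_seq, mt_seq, position, ddg),
#'   `coefficients` (the generating weight vector), `features` (the
#'   n x D matrix of wt-minus-mt mutation rows).
#' @export
make_recoverable_dataset <- function(backbone, n, seed = 1L,
                                     noise_sd = 0, seq_len = 30L,
                                     target_sd = 1.5) {
  with_seed(seed, {
    beta <- rnorm(backbone$width)
    wt_seq <- character(n)
    mt_seq <- character(n)
    position <- integer(n)
    X <- matrix(0, n, backbone$width)
    cache <- embedding_cache()
    for (i in seq_len(n)) {
      s <- random_sequence(seq_len)
      pos <- sample.int(seq_len, 1)
      wt <- substr(s, pos, pos)
      mt <- sample(setdiff(AA_ALPHABET, wt), 1)
      vp <- apply_mutation(s, wt, pos, mt)
      wt_seq[i] <- vp$wt_seq
      mt_seq[i] <- vp$mt_seq
      position[i] <- pos
      X[i, ] <- mutation_row(embed_cached(vp$wt_seq, backbone, cache), pos) -
        mutation_row(embed_cached(vp$mt_seq, backbone, cache), pos)
    }
    raw <- as.vector(X %*% beta)
    scale <- target_sd / max(sd(raw), .Machine$double.eps)
    beta <- beta * scale
    ddg <- raw * scale + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
    list(pairs = data.frame(wt_seq = wt_seq, mt_seq = mt_seq,
                            position = position, ddg = ddg,
                            stringsAsFactors = FALSE),
         coefficients = beta, features = X)
  })
}
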