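#' Configuration of the dataset-curation pipeline
#'
#' Collects the thresholds of the five-step aggregation and of the
#' downstream filters. Standard conditions and windows are in the units
#' of the measurements (pH dimensionless, temperature in degrees C). The
#' consistency filter's variance threshold is stated in kJ/mol (the unit
#' the threshold is conventionally quoted in); record ddG values, stored
#' in kcal/mol, are converted back to kJ/mol at that filter boundary.
#'
#' @param ph_standard,temp_standard Standard conditions the core sample
#'   of every ID is chosen closest to (default pH 7, 25 degrees C).
#' @param ph_window,temp_window Half-widths of the closed acceptance
#'   windows around the core's conditions (default 0.5 pH units, 10
#'   degrees C).
#' @param variance_threshold Maximum sample variance of an ID's member
#'   ddG values, in kJ/mol units (default 5).
#' @param per_wt_cap Maximum number of records retained per wild-type
#'   sequence when subsampling high-throughput data (default 70).
#' @param identity_threshold Percent sequence identity above which two
#'   proteins are considered homologous (default 30).
#' @param evalue_threshold E-value below which a homology hit counts
#'   (default 0.05).
#' @param seed Seed for any sampling performed by the pipeline.
#' @return A `curation_config` list.
#' @export
curation_config <- function(ph_standard = 7.0, temp_standard = 25.0,
                            ph_window = 0.5, temp_window = 10.0,
                            variance_threshold = 5.0, per_wt_cap = 70L,
                            identity_threshold = 30.0,
                            evalue_threshold = 0.05, seed = 1L) {
  abort_if(ph_window <= 0 || temp_window <= 0 || variance_threshold <= 0,
           "windows and thresholds must be strictly positive")
  abort_if(per_wt_cap < 1, "per_wt_cap must be >= 1")
  structure(list(ph_standard = ph_standard, temp_standard = temp_standard,
                 ph_window = ph_window, temp_window = temp_window,
                 variance_threshold = variance_threshold,
                 per_wt_cap = as.integer(per_wt_cap),
                 identity_threshold = identity_threshold,
                 evalue_threshold = evalue_threshold,
                 seed = as.integer(seed)),
            class = "curation_config")
}

#' Split records by availability of experimental conditions
#'
#' Group I holds records with both pH and temperature recorded; Group II
#' the rest (records with only one of the two are treated as conditions
#' unavailable). The partition is exhaustive and disjoint.
#'
#' @param records Validated record data frame.
#' @return List with `group1` and `group2` data frames.
#' @export
split_by_conditions <- function(records) {
  has <- !is.na(records$ph) & !is.na(records$temp)
  list(group1 = records[has, , drop = FALSE],
       group2 = records[!has, , drop = FALSE])
}

# normalized L2 distance of (pH, T) from the standard conditions, scaled
# by the window widths
condition_distance <- function(ph, temp, config) {
  sqrt(((ph - config$ph_standard) / config$ph_window)^2 +
         ((temp - config$temp_standard) / config$temp_window)^2)
}

#' Select the core sample of every record ID
#'
#' Within Group I, picks for each distinct ID the measurement whose
#' conditions are closest to the standard (pH 7, 25 C) under a normalized
#' L2 distance scaled by the window widths. Ties are broken by smaller pH
#' deviation, then lower pH, then input order — fully deterministic.
#'
#' @param group1 Group-I records (pH and temperature present).
#' @param config A [curation_config()].
#' @return Data frame of core records, one row per ID, with an `id`
#'   column; attribute `rest` holds the non-selected Group-I rows.
#' @export
select_core_samples <- function(group1, config = curation_config()) {
  if (nrow(group1) == 0) {
    out <- group1
    out$id <- character(0)
    attr(out, "rest") <- group1
    return(out)
  }
  id <- record_id(group1)
  d <- condition_distance(group1$ph, group1$temp, config)
  ord <- order(id, d, abs(group1$ph - config$ph_standard), group1$ph,
               seq_len(nrow(group1)))
  sorted <- group1[ord, , drop = FALSE]
  sid <- id[ord]
  first <- !duplicated(sid)
  core <- sorted[first, , drop = FALSE]
  core$id <- sid[first]
  rest <- sorted[!first, , drop = FALSE]
  # restore input order within each part
  core <- core[order(match(rownames(core), rownames(group1))), , drop = FALSE]
  rest <- rest[order(match(rownames(rest), rownames(group1))), , drop = FALSE]
  rownames(core) <- NULL
  attr(core, "rest") <- rest
  core
}

#' Select additional samples compatible with the cores
#'
#' From the remaining Group-I records, keeps those whose ID has a core
#' and whose conditions lie within the closed windows around that core's
#' own conditions (pH core +/- 0.5, T core +/- 10 C). From Group II,
#' keeps records whose ID does not occur anywhere in Group I.
#'
#' @param group1_rest Group-I records not selected as cores.
#' @param group2 Group-II records (conditions unavailable).
#' @param cores Output of [select_core_samples()].
#' @param config A [curation_config()].
#' @return List with `selected` (kept records) and `rejected` (records
#'   dropped here, with a `reason` column: `"outside condition window"`
#'   or `"ID present in Group I"`).
#' @export
select_additional_samples <- function(group1_rest, group2, cores,
                                      config = curation_config()) {
  core_ph <- setNames(cores$ph, cores$id)
  core_temp <- setNames(cores$temp, cores$id)
  g1_ids <- unique(c(cores$id, record_id(group1_rest)))

  keep1 <- logical(nrow(group1_rest))
  if (nrow(group1_rest) > 0) {
    rid <- record_id(group1_rest)
    has_core <- rid %in% cores$id
    keep1 <- has_core &
      abs(group1_rest$ph - core_ph[rid]) <= config$ph_window &
      abs(group1_rest$temp - core_temp[rid]) <= config$temp_window
    keep1[is.na(keep1)] <- FALSE
  }
  keep2 <- if (nrow(group2) > 0) !(record_id(group2) %in% g1_ids)
  else logical(0)

  rej1 <- group1_rest[!keep1, , drop = FALSE]
  if (nrow(rej1) > 0) rej1$reason <- "outside condition window"
  rej2 <- group2[!keep2, , drop = FALSE]
  if (nrow(rej2) > 0) rej2$reason <- "ID present in Group I"
  selected <- rbind(group1_rest[keep1, , drop = FALSE],
                    group2[keep2, , drop = FALSE])
  rejected <- rbind(rej1, rej2)
  rownames(selected) <- rownames(rejected) <- NULL
  list(selected = selected, rejected = rejected)
}

#' Average ddG over the selected members of each ID
#'
#' One output record per ID, with ddG the arithmetic mean of the member
#' values; member values and count are retained (list column `members`)
#' for the consistency filter.
#'
#' @param selected Data frame of core + additional + unique Group-II
#'   records.
#' @return Data frame with one row per ID: id, pdb_id, chain, mut_code,
#'   wt_aa, position, mt_aa, ddg (mean), n_members, members.
#' @export
average_by_id <- function(selected) {
  id <- record_id(selected)
  first <- !duplicated(id)
  out <- selected[first, c("pdb_id", "chain", "mut_code", "wt_aa",
                           "position", "mt_aa"), drop = FALSE]
  out$id <- id[first]
  groups <- split(selected$ddg, factor(id, levels = out$id))
  out$ddg <- vapply(groups, mean, 0)
  out$n_members <- vapply(groups, length, 0L)
  out$members <- I(unname(groups))
  rownames(out) <- NULL
  out
}

# sample variance of an ID's member values expressed in kJ/mol;
# single-member groups have variance 0 by convention
member_variance_kj <- function(members_kcal) {
  if (length(members_kcal) < 2) return(0)
  var(kcal_to_kj(members_kcal))
}

#' Discard IDs with conflicting measurements
#'
#' An ID is dropped if its member values contain both a strictly positive
#' and a strictly negative ddG (sign conflict; zeros never trigger it),
#' or if the unbiased sample variance of the members — computed on the
#' values expressed in kJ/mol — exceeds the threshold. Single-member IDs
#' are always kept.
#'
#' @param averaged Output of [average_by_id()].
#' @param config A [curation_config()].
#' @return List with `kept` and `discarded` (the latter with a `reason`
#'   column: `"opposite signs"` or `"variance above threshold"`).
#' @export
discard_inconsistent <- function(averaged, config = curation_config()) {
  sign_conflict <- vapply(averaged$members, function(v)
    any(v > 0) && any(v < 0), TRUE)
  high_var <- vapply(averaged$members, member_variance_kj, 0) >
    config$variance_threshold
  drop <- sign_conflict | high_var
  discarded <- averaged[drop, , drop = FALSE]
  if (nrow(discarded) > 0)
    discarded$reason <- ifelse(sign_conflict[drop], "opposite signs",
                               "variance above threshold")
  kept <- averaged[!drop, , drop = FALSE]
  rownames(kept) <- rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded)
}

#' Run the five-step aggregation pipeline
#'
#' Splits by condition availability, selects core and additional samples,
#' averages per ID, and discards inconsistent IDs, returning the curated
#' records together with a conservation report in which every input
#' record is accounted for exactly once.
#'
#' @param records Validated record data frame.
#' @param config A [curation_config()].
#' @return List with `kept` (curated per-ID records), `discarded`
#'   (per-ID, with reasons) and `report` (a `curation_report`).
#' @export
curate_dataset <- function(records, config = curation_config()) {
  groups <- split_by_conditions(records)
  cores <- select_core_samples(groups$group1, config)
  rest <- attr(cores, "rest")
  add <- select_additional_samples(rest, groups$group2, cores, config)
  core_noid <- cores[, setdiff(names(cores), "id"), drop = FALSE]
  selected <- rbind(core_noid, add$selected)
  averaged <- average_by_id(selected)
  filtered <- discard_inconsistent(averaged, config)
  report <- structure(list(
    n_input = nrow(records),
    n_group1 = nrow(groups$group1),
    n_group2 = nrow(groups$group2),
    n_core = nrow(cores),
    n_additional = nrow(add$selected),
    n_rejected_window = sum(add$rejected$reason == "outside condition window"),
    n_rejected_duplicate_id = sum(add$rejected$reason == "ID present in Group I"),
    n_ids_averaged = nrow(averaged),
    n_ids_kept = nrow(filtered$kept),
    n_ids_discarded = nrow(filtered$discarded),
    discard_reasons = if (nrow(filtered$discarded) > 0)
      table(filtered$discarded$reason) else table(character(0)),
    seed = config$seed
  ), class = "curation_report")
  list(kept = filtered$kept, discarded = filtered$discarded,
       rejected_records = add$rejected, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("curation report\n")
  cat(sprintf("  input records        : %d\n", x$n_input))
  cat(sprintf("  Group I / Group II   : %d / %d\n", x$n_group1, x$n_group2))
  cat(sprintf("  cores / additional   : %d / %d\n", x$n_core, x$n_additional))
  cat(sprintf("  window-rejected      : %d\n", x$n_rejected_window))
  cat(sprintf("  duplicate-ID rejects : %d\n", x$n_rejected_duplicate_id))
  cat(sprintf("  IDs kept / discarded : %d / %d\n",
              x$n_ids_kept, x$n_ids_discarded))
  invisible(x)
}

#' Subsample records per wild-type sequence
#'
#' High-throughput sources over-represent short proteins; to maintain
#' diversity, at most `per_wt_cap` records are retained per wild-type
#' sequence, drawn uniformly at random under the configured seed.
#' Wild-types at or below the cap are untouched. Deterministic for a
#' fixed seed.
#'
#' @param records Record data frame.
#' @param sequences Named character vector of wild-type sequences, names
#'   `pdb_id "_" chain`.
#' @param config A [curation_config()].
#' @return The subsampled record data frame.
#' @export
subsample_per_wt <- function(records, sequences,
                             config = curation_config()) {
  if (nrow(records) == 0) return(records)
  key <- paste(records$pdb_id, records$chain, sep = "_")
  miss <- setdiff(unique(key), names(sequences))
  abort_if(length(miss) > 0, "no sequence for: %s",
           paste(miss, collapse = ", "))
  wt <- sequences[key]
  keep <- with_seed(config$seed, {
    idx <- unlist(lapply(split(seq_len(nrow(records)), wt), function(i) {
      if (length(i) <= config$per_wt_cap) i
      else sort(sample(i, config$per_wt_cap))
    }), use.names = FALSE)
    sort(idx)
  })
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build wild-type/mutant pairs from curated records
#'
#' Resolves each record against its wild-type sequence, checking that the
#' residue found at the mapped position equals the record's wild-type
#' residue (numbering drift is a hard error). Source (PDB) numbering is
#' mapped to the 1-based sequence index via an explicit per-protein
#' offset (sequence index = source position + offset).
#'
#' @param records Record data frame (columns wt_aa, position, mt_aa).
#' @param sequences Named character vector, names `pdb_id "_" chain`.
#' @param offsets Named integer vector of numbering offsets per
#'   `pdb_id "_" chain`; proteins absent from it use offset 0.
#' @return Data frame of pairs: wt_seq, mt_seq, position (1-based
#'   sequence index), ddg, id.
#' @export
pairs_from_records <- function(records, sequences, offsets = integer(0)) {
  key <- paste(records$pdb_id, records$chain, sep = "_")
  miss <- setdiff(unique(key), names(sequences))
  abort_if(length(miss) > 0, "no sequence for: %s",
           paste(miss, collapse = ", "))
  off <- rep(0L, nrow(records))
  hit <- key %in% names(offsets)
  off[hit] <- as.integer(offsets[key[hit]])
  pos <- records$position + off
  pairs <- lapply(seq_len(nrow(records)), function(i) {
    vp <- apply_mutation(sequences[[key[i]]], records$wt_aa[i], pos[i],
                         records$mt_aa[i], records$ddg[i])
    data.frame(wt_seq = vp$wt_seq, mt_seq = vp$mt_seq,
               position = vp$position, ddg = vp$ddg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pairs)
  out$id <- record_id(records)
  out
}

#' Augment a training set with reverse mutations
#'
#' For every pair (wt, mt, ddg) adds the reversed pair (mt, wt, -ddg), so
#' the set is exactly balanced between stabilizing and destabilizing
#' directions. Output size is exactly twice the input; a `direction`
#' column distinguishes the two. Intended for the training split only,
#' after homology filtering.
#'
#' @param pairs Data frame with wt_seq, mt_seq, position, ddg.
#' @return Data frame of 2n rows with a `direction` column
#'   (`"direct"`/`"reverse"`).
#' @export
augment_with_reverses <- function(pairs) {
  direct <- pairs
  direct$direction <- "direct"
  reverse <- pairs
  reverse$wt_seq <- pairs$mt_seq
  reverse$mt_seq <- pairs$wt_seq
  reverse$ddg <- -pairs$ddg
  reverse$direction <- "reverse"
  out <- rbind(direct, reverse)
  rownames(out) <- NULL
  out
}

#' Naive pairwise-identity backend
#'
#' Built-in identity backend for homology filtering and clustering:
#' global (Needleman-Wunsch) alignment of each query against each
#' subject via Biostrings, identity = matches / alignment length, and a
#' surrogate E-value of 0 when identity exceeds the threshold (1
#' otherwise). Production-scale curation should delegate to an external
#' BLAST-compatible search exposing the same interface.
#'
#' @param identity_threshold Percent identity above which the surrogate
#'   E-value is 0.
#' @return A function `(query_seqs, subject_seqs) -> data.frame(query,
#'   subject, identity, evalue)` over all pairs; sequence names are used
#'   as labels (positional indices if unnamed).
#' @export
identity_backend_naive <- function(identity_threshold = 30) {
  function(query_seqs, subject_seqs) {
    qn <- names(query_seqs) %||% as.character(seq_along(query_seqs))
    sn <- names(subject_seqs) %||% as.character(seq_along(subject_seqs))
    grid <- expand.grid(q = seq_along(query_seqs),
                        s = seq_along(subject_seqs))
    ident <- mapply(function(qi, si) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(query_seqs[[qi]]),
        Biostrings::AAString(subject_seqs[[si]]),
        substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5, type = "global")
      Biostrings::pid(aln, type = "PID2")
    }, grid$q, grid$s)
    ident[!is.finite(ident)] <- 0  # degenerate alignments: no identity
    data.frame(query = qn[grid$q], subject = sn[grid$s],
               identity = ident,
               evalue = ifelse(ident > identity_threshold, 0, 1),
               stringsAsFactors = FALSE)
  }
}

#' Remove training records homologous to test proteins
#'
#' Drops every training record whose wild-type sequence hits any test
#' sequence with identity above the threshold AND E-value below the
#' threshold (a conjunction), preventing leakage between training and
#' test sets.
#'
#' @param train_records Record data frame (training candidates).
#' @param test_sequences Named character vector of test-set sequences.
#' @param config A [curation_config()].
#' @param backend Identity backend, e.g. [identity_backend_naive()].
#' @param sequences Named character vector giving the wild-type sequence
#'   of each training protein (`pdb_id "_" chain`).
#' @return List with `kept`, `removed` (records), and `hits` (the
#'   triggering alignments per removed protein).
#' @export
homology_filter <- function(train_records, test_sequences,
                            config = curation_config(),
                            backend = identity_backend_naive(
                              config$identity_threshold),
                            sequences) {
  abort_if(!is.function(backend),
           "identity backend unavailable; use identity_backend_naive()")
  key <- paste(train_records$pdb_id, train_records$chain, sep = "_")
  prot <- unique(key)
  miss <- setdiff(prot, names(sequences))
  abort_if(length(miss) > 0, "no sequence for: %s",
           paste(miss, collapse = ", "))
  hits <- backend(sequences[prot], test_sequences)
  trig <- hits[hits$identity > config$identity_threshold &
                 hits$evalue < config$evalue_threshold, , drop = FALSE]
  bad_prot <- unique(trig$query)
  removed <- train_records[key %in% bad_prot, , drop = FALSE]
  kept <- train_records[!(key %in% bad_prot), , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed, hits = trig)
}

#' Build structure-defined stability test sets
#'
#' Two labelled test partitions derived from structures: the cofactor
#' ("hemoglobin") subset — records whose structure contains a
#' hetero-residue with ligand code HEM, HEC or BLA — and the
#' oligomerization subset — records whose chain has strictly more than
#' 30% of its residues within the contact cutoff of another chain.
#' Records without a structure are skipped with a warning and counted.
#'
#' @param records Record data frame.
#' @param structures Named list of [read_structure()] objects, names =
#'   PDB IDs.
#' @param config A [contact_config()].
#' @param ligand_codes Cofactor codes defining the cofactor subset.
#' @return List with `hemoglobin`, `oligomerization` (record subsets) and
#'   `report` (counts, including skipped records).
#' @export
build_stability_test_sets <- function(records, structures,
                                      config = contact_config(),
                                      ligand_codes = c("HEM", "HEC", "BLA")) {
  have <- records$pdb_id %in% names(structures)
  if (any(!have))
    warning(sprintf("%d record(s) skipped: no structure", sum(!have)))
  rec <- records[have, , drop = FALSE]
  in_heme <- logical(nrow(rec))
  in_olig <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    st <- structures[[rec$pdb_id[i]]]
    in_heme[i] <- any(hetero_codes(st) %in% ligand_codes)
    if (length(st$chains) > 1 && rec$chain[i] %in% names(st$chains))
      in_olig[i] <- interface_fraction(st, rec$chain[i],
                                       config$distance_cutoff) >
        config$interface_fraction_threshold
  }
  list(hemoglobin = rec[in_heme, , drop = FALSE],
       oligomerization = rec[in_olig, , drop = FALSE],
       report = list(n_records = nrow(records),
                     n_missing_structure = sum(!have),
                     n_hemoglobin = sum(in_heme),
                     n_oligomerization = sum(in_olig)))
}
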