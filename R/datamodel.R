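#' Parse a compact mutation code
#'
#' Mutation codes are strings of the form `"A123G"`: wild-type residue
#' (one letter), residue position (integer, in the numbering of the source
#' — usually PDB numbering), mutant residue (one letter). Both residues
#' must be members of the 20-letter alphabet and distinct.
#'
#' @param code Character vector of mutation codes.
#' @return A data frame with columns `wt_aa`, `position`, `mt_aa`.
#' @examples
#' parse_mutation_code("A123G")
#' @export
parse_mutation_code <- function(code) {
  m <- regmatches(code, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", code))
  bad <- vapply(m, length, 0L) != 4L
  abort_if(any(bad), "malformed mutation code: %s",
           paste(code[bad], collapse = ", "))
  wt <- toupper(vapply(m, `[`, "", 2L))
  pos <- as.integer(vapply(m, `[`, "", 3L))
  mt <- toupper(vapply(m, `[`, "", 4L))
  bad_aa <- !(wt %in% AA_ALPHABET) | !(mt %in% AA_ALPHABET)
  abort_if(any(bad_aa), "mutation code with residue outside alphabet: %s",
           paste(code[bad_aa], collapse = ", "))
  data.frame(wt_aa = wt, position = pos, mt_aa = mt,
             stringsAsFactors = FALSE)
}

#' Build the aggregation key for mutation records
#'
#' A record's identity is the combination of PDB ID, chain and mutation
#' code; all curation steps group by this key.
#'
#' @param records A mutation-record data frame.
#' @return Character vector of IDs.
#' @export
record_id <- function(records) {
  paste(records$pdb_id, records$chain, records$mut_code, sep = "_")
}

#' Construct a validated table of mutation records
#'
#' The canonical in-memory form of thermodynamic measurements: one row per
#' measurement with ddG in kcal/mol (positive = destabilizing), optional
#' pH and temperature (degrees C), and a free-text provenance tag.
#' Invalid rows are split off with a reason rather than silently dropped.
#'
#' @param df Data frame with columns `pdb_id`, `chain`, `mut_code`, `ddg`
#'   and optionally `ph`, `temp`, `source`.
#' @return List with `records` (validated rows, plus parsed `wt_aa`,
#'   `position`, `mt_aa` columns) and `rejected` (rows that failed
#'   validation, with a `reason` column).
#' @export
mutation_records <- function(df) {
  need <- c("pdb_id", "chain", "mut_code", "ddg")
  miss <- setdiff(need, names(df))
  abort_if(length(miss) > 0, "missing mandatory column(s): %s",
           paste(miss, collapse = ", "))
  if (is.null(df$ph)) df$ph <- NA_real_
  if (is.null(df$temp)) df$temp <- NA_real_
  if (is.null(df$source)) df$source <- NA_character_
  df$ddg <- suppressWarnings(as.numeric(df$ddg))
  df$ph <- suppressWarnings(as.numeric(df$ph))
  df$temp <- suppressWarnings(as.numeric(df$temp))

  reason <- rep(NA_character_, nrow(df))
  code_ok <- grepl("^[A-Za-z][0-9]+[A-Za-z]$", df$mut_code)
  reason[!code_ok] <- "unparseable mutation code"
  df$wt_aa <- df$mt_aa <- NA_character_
  df$position <- NA_integer_
  if (any(code_ok)) {
    codes <- toupper(df$mut_code[code_ok])
    ok_idx <- which(code_ok)
    df$wt_aa[ok_idx] <- substr(codes, 1, 1)
    df$mt_aa[ok_idx] <- substr(codes, nchar(codes), nchar(codes))
    df$position[ok_idx] <- as.integer(substr(codes, 2, nchar(codes) - 1))
  }
  alpha_ok <- is.na(reason) &
    df$wt_aa %in% AA_ALPHABET & df$mt_aa %in% AA_ALPHABET
  reason[is.na(reason) & !alpha_ok] <- "residue outside amino-acid alphabet"
  same <- is.na(reason) & df$wt_aa == df$mt_aa
  reason[same] <- "wild-type equals mutant"
  reason[is.na(reason) & !is.finite(df$ddg)] <- "missing target"
  reason[is.na(reason) & df$position < 1L] <- "non-positive position"

  bad <- !is.na(reason)
  rejected <- df[bad, , drop = FALSE]
  rejected$reason <- reason[bad]
  records <- df[!bad, , drop = FALSE]
  rownames(records) <- rownames(rejected) <- NULL
  list(records = records, rejected = rejected)
}

#' Describe the layout and conventions of a source mutation table
#'
#' Each source table declares, through a dialect, which columns map to
#' which fields, its ddG unit, and its sign convention. All values are
#' normalized on read to kcal/mol with positive = destabilizing.
#'
#' @param columns Named character vector mapping canonical field names
#'   (`pdb_id`, `chain`, `mut_code`, `ddg`, and optionally `ph`, `temp`)
#'   to the source's column names.
#' @param unit `"kcal/mol"` or `"kJ/mol"`.
#' @param sign `"destabilizing_positive"` or `"stabilizing_positive"`.
#' @param sep Field separator of the file (`","` or `"\t"`).
#' @param source Provenance tag recorded on every record.
#' @return A `ddg_dialect` object.
#' @export
ddg_dialect <- function(columns = c(pdb_id = "pdb_id", chain = "chain",
                                    mut_code = "mut_code", ddg = "ddg",
                                    ph = "ph", temp = "temp"),
                        unit = c("kcal/mol", "kJ/mol"),
                        sign = c("destabilizing_positive",
                                 "stabilizing_positive"),
                        sep = ",", source = NA_character_) {
  unit <- match.arg(unit)
  sign <- match.arg(sign)
  need <- c("pdb_id", "chain", "mut_code", "ddg")
  miss <- setdiff(need, names(columns))
  abort_if(length(miss) > 0, "dialect must map column(s): %s",
           paste(miss, collapse = ", "))
  structure(list(columns = columns, unit = unit, sign = sign,
                 sep = sep, source = source),
            class = "ddg_dialect")
}

#' Read a dialect description from a YAML file
#'
#' @param path Path to a YAML file with keys `columns` (map), `unit`,
#'   `sign`, `sep`, `source`.
#' @return A `ddg_dialect` object.
#' @export
read_dialect <- function(path) {
  y <- yaml::read_yaml(path)
  ddg_dialect(columns = unlist(y$columns),
              unit = y$unit %||% "kcal/mol",
              sign = y$sign %||% "destabilizing_positive",
              sep = y$sep %||% ",",
              source = y$source %||% NA_character_)
}

#' Read a tabular file of ddG mutation measurements
#'
#' Reads a delimited file with a header, renames columns according to the
#' dialect, normalizes ddG to kcal/mol with positive = destabilizing, and
#' validates every row. Rows failing validation are returned with reasons.
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect A [ddg_dialect()] describing the file.
#' @return As [mutation_records()]: list with `records` and `rejected`.
#' @export
read_mutation_table <- function(path, dialect = ddg_dialect()) {
  abort_if(!file.exists(path), "file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  cols <- dialect$columns
  miss <- setdiff(unname(cols[c("pdb_id", "chain", "mut_code", "ddg")]),
                  names(raw))
  abort_if(length(miss) > 0, "table %s lacks mandatory column(s): %s",
           path, paste(miss, collapse = ", "))
  df <- data.frame(pdb_id = as.character(raw[[cols[["pdb_id"]]]]),
                   chain = as.character(raw[[cols[["chain"]]]]),
                   mut_code = as.character(raw[[cols[["mut_code"]]]]),
                   ddg = raw[[cols[["ddg"]]]],
                   stringsAsFactors = FALSE)
  df$ph <- if ("ph" %in% names(cols) && cols[["ph"]] %in% names(raw))
    raw[[cols[["ph"]]]] else NA_real_
  df$temp <- if ("temp" %in% names(cols) && cols[["temp"]] %in% names(raw))
    raw[[cols[["temp"]]]] else NA_real_
  df$source <- dialect$source %||% NA_character_
  df$ddg <- suppressWarnings(as.numeric(df$ddg))
  if (dialect$unit == "kJ/mol") df$ddg <- kj_to_kcal(df$ddg)
  if (dialect$sign == "stabilizing_positive") df$ddg <- -df$ddg
  mutation_records(df)
}

#' Write mutation records to a TSV file
#'
#' Writes the canonical columns (kcal/mol, positive = destabilizing), so
#' that re-reading with the default TSV dialect round-trips the records.
#'
#' @param records Validated record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  cols <- c("pdb_id", "chain", "mut_code", "ddg", "ph", "temp", "source")
  utils::write.table(records[, intersect(cols, names(records))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a wild-type/mutant sequence pair
#'
#' The unit of model input: two equal-length sequences differing at
#' exactly one (1-based) position, optionally with a ddG target.
#'
#' @param wt_seq,mt_seq Amino-acid strings.
#' @param position 1-based index of the substituted residue.
#' @param ddg Optional target value, kcal/mol.
#' @return A `variant_pair` list.
#' @export
variant_pair <- function(wt_seq, mt_seq, position, ddg = NA_real_) {
  abort_if(nchar(wt_seq) != nchar(mt_seq),
           "wild-type and mutant sequences differ in length (%d vs %d)",
           nchar(wt_seq), nchar(mt_seq))
  w <- strsplit(wt_seq, "")[[1]]
  m <- strsplit(mt_seq, "")[[1]]
  diff <- which(w != m)
  abort_if(length(diff) != 1L,
           "sequences must differ at exactly one position (found %d)",
           length(diff))
  abort_if(diff != position,
           "sequences differ at position %d, not the declared %d",
           diff, position)
  structure(list(wt_seq = wt_seq, mt_seq = mt_seq,
                 position = as.integer(position), ddg = ddg),
            class = "variant_pair")
}

#' Apply a single-residue substitution to a sequence
#'
#' Guards against numbering drift between the mutation table and the
#' sequence: the residue found at `seq_position` must equal the declared
#' wild-type residue, otherwise a hard error reports expected vs found.
#' Mapping from source (PDB) numbering to the 1-based sequence index is
#' the caller's responsibility, via an explicit `offset` (sequence index =
#' source position + offset).
#'
#' @param wt_seq Wild-type sequence.
#' @param wt_aa Expected residue at the position (1-letter).
#' @param seq_position 1-based index into `wt_seq`.
#' @param mt_aa Substituting residue (1-letter).
#' @param ddg Optional target, kcal/mol.
#' @return A [variant_pair()].
#' @export
apply_mutation <- function(wt_seq, wt_aa, seq_position, mt_aa,
                           ddg = NA_real_) {
  abort_if(seq_position < 1L || seq_position > nchar(wt_seq),
           "position %d outside sequence of length %d",
           seq_position, nchar(wt_seq))
  found <- substr(wt_seq, seq_position, seq_position)
  abort_if(found != wt_aa,
           "residue mismatch at position %d: expected %s, found %s",
           seq_position, wt_aa, found)
  abort_if(!(mt_aa %in% AA_ALPHABET), "mutant residue %s not in alphabet",
           mt_aa)
  mt_seq <- wt_seq
  substr(mt_seq, seq_position, seq_position) <- mt_aa
  variant_pair(wt_seq, mt_seq, seq_position, ddg)
}

#' Read protein sequences from a FASTA file
#'
#' Accessions follow the `pdb_id "_" chain` convention used to join
#' sequences to mutation records.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a protein structure from a PDB file
#'
#' Parses fixed-column PDB via bio3d and reduces it to the carrier used
#' by the stratification filters: heavy atoms only, first model, highest
#' occupancy altloc, polymer residues (standard amino acids in ATOM
#' records) separated from hetero-residues (HETATM and nonstandard
#' residues), chain and residue numbering preserved verbatim.
#'
#' @param pdb_path Path to a PDB file.
#' @return A `protstab_structure`: list with `atoms` (data frame: chain,
#'   resno, resid, aa1, elety, x, y, z, het) and `chains` (per-chain
#'   residue tables).
#' @export
read_structure <- function(pdb_path) {
  pdb <- bio3d::read.pdb(pdb_path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  abort_if(is.null(at) || nrow(at) == 0 || !any(at$type == "ATOM"),
           "no ATOM records in %s", pdb_path)
  # drop hydrogens: heavy atoms only
  elesy <- at$elesy
  elesy[is.na(elesy) | elesy == ""] <- substr(trimws(at$elety[is.na(elesy) | elesy == ""]), 1, 1)
  at <- at[toupper(trimws(elesy)) != "H", , drop = FALSE]
  # highest-occupancy altloc per (chain, resno, resid, atom name)
  key <- paste(at$chain, at$resno, at$resid, at$elety)
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$resid, at$elety)), ,
           drop = FALSE]
  at <- at[order(at$chain, at$resno), , drop = FALSE]

  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  polymer <- at$type == "ATOM" & aa1 %in% AA_ALPHABET
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resid = at$resid, aa1 = ifelse(polymer, aa1, NA),
                      elety = trimws(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      het = !polymer, stringsAsFactors = FALSE)
  abort_if(any(!is.finite(atoms$x) | !is.finite(atoms$y) |
                 !is.finite(atoms$z)), "non-finite coordinates in %s",
           pdb_path)
  poly <- atoms[!atoms$het, , drop = FALSE]
  chains <- lapply(split(poly, poly$chain), function(d) {
    u <- !duplicated(d$resno)
    data.frame(resno = d$resno[u], aa1 = d$aa1[u], stringsAsFactors = FALSE)
  })
  structure(list(atoms = atoms, chains = chains, path = pdb_path),
            class = "protstab_structure")
}

#' @export
print.protstab_structure <- function(x, ...) {
  nhet <- length(unique(paste(x$atoms$chain, x$atoms$resno)[x$atoms$het]))
  cat(sprintf("protstab_structure: %d chain(s) [%s], %d hetero-residue(s)\n",
              length(x$chains), paste(names(x$chains), collapse = ","),
              nhet))
  invisible(x)
}

#' Hetero-residue (ligand) codes present in a structure
#'
#' @param structure A `protstab_structure`.
#' @return Character vector of unique hetero-residue codes.
#' @export
hetero_codes <- function(structure) {
  unique(structure$atoms$resid[structure$atoms$het])
}
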