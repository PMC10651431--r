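#' Configuration of structure-derived stratification
#'
#' @param distance_cutoff Heavy-atom distance defining a contact
#'   (default 4.5 Angstrom).
#' @param interface_fraction_threshold A chain is oligomeric when
#'   strictly more than this fraction of its residues contacts another
#'   chain (default 0.30; the boundary value itself does not qualify).
#' @param burial_threshold Relative ASA below which a residue counts as
#'   buried (default 0.25, a common convention).
#' @param ligand_codes Hetero-residue codes treated as cofactors.
#' @return A `contact_config` list.
#' @export
contact_config <- function(distance_cutoff = 4.5,
                           interface_fraction_threshold = 0.30,
                           burial_threshold = 0.25,
                           ligand_codes = c("HEM", "HEC", "BLA")) {
  abort_if(distance_cutoff <= 0, "distance cutoff must be positive")
  abort_if(interface_fraction_threshold <= 0 ||
             interface_fraction_threshold >= 1,
           "interface fraction threshold must lie in (0, 1)")
  structure(list(distance_cutoff = distance_cutoff,
                 interface_fraction_threshold = interface_fraction_threshold,
                 burial_threshold = burial_threshold,
                 ligand_codes = ligand_codes),
            class = "contact_config")
}

# any point of A within cutoff of any point of B, per row of A
any_within <- function(A, B, cutoff) {
  # squared-distance matrix via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  apply(d2 <= cutoff^2, 1, any)
}

#' Residues in contact with another chain
#'
#' A polymer residue is flagged when any of its heavy atoms lies within
#' the cutoff of any heavy atom belonging to a residue of a different
#' chain (hetero-residues are not considered subunits). Contact is
#' symmetric by construction.
#'
#' @param structure A [read_structure()] object.
#' @param cutoff Distance cutoff, Angstrom (default 4.5).
#' @return Data frame of flagged residues: `chain`, `resno`.
#' @export
interchain_contacts <- function(structure, cutoff = 4.5) {
  at <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  empty <- data.frame(chain = character(0), resno = integer(0),
                      stringsAsFactors = FALSE)
  chains <- unique(at$chain)
  if (length(chains) < 2 || nrow(at) == 0) return(empty)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  flagged <- logical(nrow(at))
  for (ch in chains) {
    own <- at$chain == ch
    hit <- any_within(xyz[own, , drop = FALSE],
                      xyz[!own, , drop = FALSE], cutoff)
    flagged[which(own)[hit]] <- TRUE
  }
  res <- unique(at[flagged, c("chain", "resno")])
  rownames(res) <- NULL
  res
}

#' Fraction of a chain's residues at an inter-chain interface
#'
#' @param structure A [read_structure()] object.
#' @param chain Chain identifier.
#' @param cutoff Distance cutoff, Angstrom.
#' @return Fraction in [0, 1]: flagged residues of the chain divided by
#'   its residue count.
#' @export
interface_fraction <- function(structure, chain, cutoff = 4.5) {
  abort_if(!(chain %in% names(structure$chains)),
           "chain '%s' not in structure", chain)
  n_res <- nrow(structure$chains[[chain]])
  abort_if(n_res == 0, "chain '%s' has no residues", chain)
  flags <- interchain_contacts(structure, cutoff)
  sum(flags$chain == chain) / n_res
}

#' Residues in contact with selected ligands
#'
#' Flags polymer residues with any heavy atom within the cutoff of any
#' atom of a hetero-residue whose code is in `ligand_codes`.
#'
#' @param structure A [read_structure()] object.
#' @param ligand_codes Character vector of hetero-residue codes.
#' @param cutoff Distance cutoff, Angstrom.
#' @return Data frame of flagged residues: `chain`, `resno`.
#' @export
ligand_contacts <- function(structure, ligand_codes = c("HEM", "HEC", "BLA"),
                            cutoff = 4.5) {
  at <- structure$atoms
  poly <- at[!at$het, , drop = FALSE]
  lig <- at[at$het & at$resid %in% ligand_codes, , drop = FALSE]
  empty <- data.frame(chain = character(0), resno = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(lig) == 0 || nrow(poly) == 0 || cutoff <= 0) return(empty)
  hit <- any_within(as.matrix(poly[, c("x", "y", "z")]),
                    as.matrix(lig[, c("x", "y", "z")]), cutoff)
  res <- unique(poly[hit, c("chain", "resno")])
  rownames(res) <- NULL
  res
}

#' Reference maximum accessible surface areas (theoretical, A^2)
#'
#' Residue-type maxima used to normalize DSSP absolute ASA into relative
#' ASA (Tien et al. 2013, theoretical values).
#'
#' @format Named numeric vector over the 20 one-letter codes.
#' @export
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225,
             E = 223, G = 104, H = 224, I = 197, L = 201, K = 236,
             M = 224, F = 240, P = 159, S = 155, T = 172, W = 285,
             Y = 263, V = 174)

# collapse the 8 DSSP states onto 3 classes
ss8_to_ss3 <- function(ss) {
  out <- rep("coil", length(ss))
  out[ss %in% c("H", "G", "I")] <- "helix"
  out[ss %in% c("E", "B")] <- "strand"
  out
}

#' Parse classic-format DSSP output
#'
#' Reads the per-residue block of a classic (fixed-column) DSSP file:
#' PDB residue number, chain, amino acid, 8-state secondary structure
#' and absolute accessible surface area. DSSP itself is an external
#' tool; this package only consumes its output.
#'
#' @param path Path to a DSSP output file.
#' @return Data frame: `chain`, `resno`, `aa`, `ss8`, `acc`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  abort_if(length(start) == 0, "not a classic DSSP file: %s", path)
  body <- lines[(start[1] + 1):length(lines)]
  body <- body[nchar(body) >= 38]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]  # chain breaks
  data.frame(
    chain = substr(body, 12, 12),
    resno = as.integer(substr(body, 6, 10)),
    aa = substr(body, 14, 14),
    ss8 = trimws(substr(body, 17, 17)),
    acc = as.numeric(substr(body, 35, 38)),
    stringsAsFactors = FALSE
  )
}

#' Annotate residues with burial and secondary structure from DSSP
#'
#' Joins DSSP output onto the structure's polymer residues. Relative ASA
#' is the DSSP absolute ASA divided by the residue type's reference
#' maximum, clipped to [0, 1]; the 8 DSSP states are collapsed to
#' helix ({H, G, I}), strand ({E, B}) and coil (rest). Residues present
#' in the structure but absent from the DSSP output are annotated as
#' unknown (`NA`) and counted in the `n_unknown` attribute, so that
#' stratified metrics can exclude them explicitly.
#'
#' @param structure A [read_structure()] object.
#' @param dssp Path to a DSSP file, or a parsed [read_dssp()] frame.
#' @param config A [contact_config()] (supplies the burial threshold).
#' @return Data frame: `chain`, `resno`, `rel_asa`, `ss3`, `buried`;
#'   attribute `n_unknown`.
#' @export
annotate_burial_ss <- function(structure, dssp,
                               config = contact_config()) {
  if (is.character(dssp)) dssp <- read_dssp(dssp)
  res <- do.call(rbind, lapply(names(structure$chains), function(ch) {
    d <- structure$chains[[ch]]
    data.frame(chain = ch, resno = d$resno, aa1 = d$aa1,
               stringsAsFactors = FALSE)
  }))
  key_s <- paste(res$chain, res$resno)
  key_d <- paste(dssp$chain, dssp$resno)
  idx <- match(key_s, key_d)
  rel <- rep(NA_real_, nrow(res))
  ss3 <- rep(NA_character_, nrow(res))
  found <- !is.na(idx)
  maxa <- MAX_ASA[res$aa1[found]]
  rel[found] <- pmin(dssp$acc[idx[found]] / maxa, 1)
  ss3[found] <- ss8_to_ss3(dssp$ss8[idx[found]])
  out <- data.frame(chain = res$chain, resno = res$resno,
                    rel_asa = rel, ss3 = ss3,
                    buried = rel < config$burial_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "n_unknown") <- sum(!found)
  out
}

#' Full residue annotation of a structure
#'
#' Convenience assembly of the per-residue annotation table: interface
#' and ligand-contact flags from the coordinate-based detectors, plus
#' burial and secondary structure when DSSP output is supplied.
#'
#' @param structure A [read_structure()] object.
#' @param dssp Optional DSSP file or parsed frame.
#' @param config A [contact_config()].
#' @return Data frame: `chain`, `resno`, `rel_asa`, `ss3`, `buried`,
#'   `interface`, `ligand_contact`.
#' @export
annotate_structure <- function(structure, dssp = NULL,
                               config = contact_config()) {
  base <- if (!is.null(dssp)) annotate_burial_ss(structure, dssp, config)
  else {
    res <- do.call(rbind, lapply(names(structure$chains), function(ch)
      data.frame(chain = ch, resno = structure$chains[[ch]]$resno,
                 rel_asa = NA_real_, ss3 = NA_character_, buried = NA,
                 stringsAsFactors = FALSE)))
    res
  }
  iface <- interchain_contacts(structure, config$distance_cutoff)
  ligc <- ligand_contacts(structure, config$ligand_codes,
                          config$distance_cutoff)
  key <- paste(base$chain, base$resno)
  base$interface <- key %in% paste(iface$chain, iface$resno)
  base$ligand_contact <- key %in% paste(ligc$chain, ligc$resno)
  base
}

#' Metrics within structure-derived strata
#'
#' Computes Pearson r, RMSE and MAE separately within each stratum of a
#' labelling (e.g. buried/exposed, helix/strand/coil,
#' interface/non-interface). Records with an `NA` label are reported
#' under `"unknown"` and excluded from the labelled strata; strata with
#' fewer than two records are flagged insufficient. The union of all
#' strata (including unknown) is always the full input — partition
#' conservation.
#'
#' @param predictions,targets Equal-length numeric vectors.
#' @param strata Vector of stratum labels, same length (NA = unknown).
#' @return Named list per stratum: either an [eval_metrics()] result or
#'   `list(n = ..., insufficient = TRUE)`.
#' @export
stratified_metrics <- function(predictions, targets, strata) {
  abort_if(length(predictions) != length(targets) ||
             length(targets) != length(strata),
           "predictions, targets and strata must have equal length")
  lab <- ifelse(is.na(strata), "unknown", as.character(strata))
  out <- lapply(split(seq_along(lab), lab), function(idx) {
    if (length(idx) < 2)
      return(list(n = length(idx), insufficient = TRUE))
    m <- suppressWarnings(eval_metrics(predictions[idx], targets[idx]))
    m$insufficient <- FALSE
    m
  })
  out
}
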