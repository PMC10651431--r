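# Independent brute-force oracles: nested loops, no indexing structures,
# written against the rule statements only.

# full curation oracle: returns kept ids with means, and dropped ids
# with reasons, for the five-step aggregation
oracle_curate <- function(records, ph_std = 7, t_std = 25,
                          ph_win = 0.5, t_win = 10, var_thr_kj = 5) {
  id <- paste(records$pdb_id, records$chain, records$mut_code, sep = "_")
  has <- !is.na(records$ph) & !is.na(records$temp)

  # step 2: core per ID among condition-bearing records
  core_of <- list()
  for (u in unique(id[has])) {
    cand <- which(id == u & has)
    best <- NA
    for (i in cand) {
      if (is.na(best)) { best <- i; next }
      di <- sqrt(((records$ph[i] - ph_std) / ph_win)^2 +
                   ((records$temp[i] - t_std) / t_win)^2)
      db <- sqrt(((records$ph[best] - ph_std) / ph_win)^2 +
                   ((records$temp[best] - t_std) / t_win)^2)
      if (di < db - 1e-12) best <- i
      else if (abs(di - db) <= 1e-12) {
        devi <- abs(records$ph[i] - ph_std)
        devb <- abs(records$ph[best] - ph_std)
        if (devi < devb - 1e-12) best <- i
        else if (abs(devi - devb) <= 1e-12 &&
                 records$ph[i] < records$ph[best] - 1e-12) best <- i
      }
    }
    core_of[[u]] <- best
  }

  # steps 3-4: members per ID
  members <- list()
  for (u in names(core_of)) {
    ci <- core_of[[u]]
    mem <- records$ddg[ci]
    for (i in which(id == u & has)) {
      if (i == ci) next
      if (abs(records$ph[i] - records$ph[ci]) <= ph_win &&
          abs(records$temp[i] - records$temp[ci]) <= t_win)
        mem <- c(mem, records$ddg[i])
    }
    members[[u]] <- mem
  }
  for (u in unique(id[!has])) {
    in_group1 <- FALSE
    for (i in which(id == u)) if (has[i]) in_group1 <- TRUE
    if (!in_group1) members[[u]] <- records$ddg[id == u & !has]
  }

  # step 5: conflict filter (variance compared in kJ/mol units)
  kept <- c(); means <- c(); dropped <- c(); reasons <- c()
  for (u in names(members)) {
    mem <- members[[u]]
    pos <- FALSE; neg <- FALSE
    for (v in mem) { if (v > 0) pos <- TRUE; if (v < 0) neg <- TRUE }
    vr <- if (length(mem) < 2) 0 else var(mem * 4.184)
    if (pos && neg) {
      dropped <- c(dropped, u); reasons <- c(reasons, "opposite signs")
    } else if (vr > var_thr_kj) {
      dropped <- c(dropped, u)
      reasons <- c(reasons, "variance above threshold")
    } else {
      kept <- c(kept, u); means <- c(means, mean(mem))
    }
  }
  list(kept = setNames(means, kept),
       dropped = setNames(reasons, dropped),
       members = members)
}

# brute-force all-atom-pairs interchain contact scan
oracle_interchain <- function(structure, cutoff) {
  at <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  flagged <- character(0)
  for (i in seq_len(nrow(at))) {
    for (j in seq_len(nrow(at))) {
      if (at$chain[i] == at$chain[j]) next
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (d <= cutoff) flagged <- c(flagged, paste(at$chain[i], at$resno[i]))
    }
  }
  sort(unique(flagged))
}

# brute-force ligand-contact scan
oracle_ligand <- function(structure, codes, cutoff) {
  at <- structure$atoms
  poly <- which(!at$het)
  lig <- which(at$het & at$resid %in% codes)
  flagged <- character(0)
  for (i in poly) {
    for (j in lig) {
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (cutoff > 0 && d <= cutoff)
        flagged <- c(flagged, paste(at$chain[i], at$resno[i]))
    }
  }
  sort(unique(flagged))
}
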