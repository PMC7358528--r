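# Cross-isoform comparison of contact maps and energy profiles, and the
# rule-based mutation design: toxin residues whose polar contacts exist only
# with off-target isoforms are mutated to Ala; acidic residues repelled by
# every isoform get a charge reversal (Arg by default).

POLAR_KINDS <- c("hbond", "salt_bridge", "cation_pi")

#' Bundle per-isoform contact maps and energy profiles
#'
#' @param entries named list, one element per channel isoform (e.g.
#'   `"Kv1.1"`), each a list with components `contacts` (a contact map data
#'   frame as from [contact_occupancy()]) and `energy` (a
#'   `toxsel_energyprofile`, or its `residues` data frame).
#' @param target the isoform whose affinity must be preserved; all other
#'   labels are off-target.
#' @return an object of class `toxsel_isoform_set`.
#' @export
isoform_set <- function(entries, target) {
  if (length(entries) < 2L) stop("need at least 2 isoforms")
  if (is.null(names(entries)) || any(names(entries) == "")) {
    stop("entries must be named by isoform")
  }
  if (!target %in% names(entries)) {
    stop("target isoform '", target, "' missing from entries")
  }
  for (lab in names(entries)) {
    en <- entries[[lab]]$energy
    if (inherits(en, "toxsel_energyprofile")) {
      entries[[lab]]$energy <- en$residues
    }
  }
  structure(list(entries = entries, target = target,
                 off_target = setdiff(names(entries), target)),
            class = "toxsel_isoform_set")
}

# polar contacts at/above the occupancy threshold for one isoform
polar_contacts_at <- function(cm, occupancy_threshold) {
  cm <- as.data.frame(cm)
  cm[cm$kind %in% POLAR_KINDS & cm$occupancy >= occupancy_threshold, ,
     drop = FALSE]
}

#' Isoform-specific polar contacts
#'
#' Flags toxin residues that form polar contacts (hydrogen bond, salt
#' bridge, cation-pi) with at least one off-target isoform at occupancy
#' >= `occupancy_threshold` while forming no polar contact at all with the
#' target isoform. These are exactly the residues whose substitution should
#' cost off-target affinity but spare the target.
#'
#' @param set a `toxsel_isoform_set`.
#' @param occupancy_threshold minimal occupancy for a contact to "exist"
#'   (default 0.10).
#' @return data frame of the triggering off-target contacts: `toxin_res`,
#'   `toxin_resname`, `toxin_resno`, `isoform`, `channel_res`,
#'   `channel_resname`, `channel_resno`, `kind`, `occupancy`.
#' @export
differential_contacts <- function(set, occupancy_threshold = 0.10) {
  stopifnot(inherits(set, "toxsel_isoform_set"))
  target_cm <- polar_contacts_at(set$entries[[set$target]]$contacts,
                                 occupancy_threshold)
  target_res <- unique(target_cm$toxin_res)
  out <- list()
  for (iso in set$off_target) {
    cm <- polar_contacts_at(set$entries[[iso]]$contacts, occupancy_threshold)
    if (nrow(cm) == 0L) next
    cm <- cm[!(cm$toxin_res %in% target_res), , drop = FALSE]
    if (nrow(cm) == 0L) next
    cm$isoform <- iso
    out[[iso]] <- cm[, c("toxin_res", "toxin_resname", "toxin_resno",
                         "isoform", "channel_res", "channel_resname",
                         "channel_resno", "kind", "occupancy")]
  }
  if (length(out) == 0L) {
    res <- data.frame(toxin_res = character(0), toxin_resname = character(0),
                      toxin_resno = integer(0), isoform = character(0),
                      channel_res = character(0), channel_resname = character(0),
                      channel_resno = integer(0), kind = character(0),
                      occupancy = numeric(0), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$toxin_resno, res$isoform, res$kind), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "occupancy_threshold") <- occupancy_threshold
  attr(res, "target") <- set$target
  res
}

#' Toxin residues repelled by every isoform
#'
#' Returns toxin residues whose mean total interaction energy is above
#' `energy_sign_threshold` (default 0 kJ/mol, i.e. net repulsive) in every
#' isoform of the set. The magnitude relative to the per-frame sd is
#' reported (`min_mean_over_sd`) but deliberately not thresholded:
#' significance is for the analyst to judge.
#'
#' @param set a `toxsel_isoform_set`.
#' @param energy_sign_threshold kJ/mol.
#' @return data frame with one row per repulsive residue: `toxin_res`,
#'   `resname`, `resno`, per-isoform mean totals (`mean_total_<isoform>`),
#'   and `min_mean_over_sd`.
#' @export
repulsive_residues <- function(set, energy_sign_threshold = 0) {
  stopifnot(inherits(set, "toxsel_isoform_set"))
  isoforms <- names(set$entries)
  profiles <- lapply(isoforms, function(iso) set$entries[[iso]]$energy)
  base <- profiles[[1L]][, c("toxin_res", "resname", "resno")]
  means <- sapply(profiles, function(p)
    p$mean_total[match(base$toxin_res, p$toxin_res)])
  sds <- sapply(profiles, function(p)
    p$sd_total[match(base$toxin_res, p$toxin_res)])
  means <- matrix(means, nrow = nrow(base))
  sds <- matrix(sds, nrow = nrow(base))
  if (anyNA(means)) stop("energy profiles do not share toxin residues")
  keep <- apply(means > energy_sign_threshold, 1L, all)
  res <- base[keep, , drop = FALSE]
  for (j in seq_along(isoforms)) {
    res[[paste0("mean_total_", isoforms[j])]] <- means[keep, j]
  }
  ratio <- means[keep, , drop = FALSE] /
    pmax(sds[keep, , drop = FALSE], .Machine$double.eps)
  res$min_mean_over_sd <- if (nrow(res)) apply(ratio, 1L, min) else numeric(0)
  res <- res[order(res$resno), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Propose selectivity-switching substitutions
#'
#' Applies the design rules: every toxin residue carrying off-target-specific
#' polar contacts is substituted by Ala (abolishing the hydrogen bond / salt
#' bridge / cation-pi it makes with off-target isoforms); every acidic
#' residue (Asp/Glu) repelled by all isoforms gets a charge reversal to
#' `charge_reversal_to` (Arg by default, turning the electrostatic repulsion
#' with the conserved vestibule aspartate into attraction). If the same
#' residue triggers both rules it receives a single Ala substitution with a
#' combined rationale (Ala also removes the repelling charge). Cysteines are
#' never proposed. Output is deterministic, ordered by position.
#'
#' @param specific output of [differential_contacts()].
#' @param repulsive output of [repulsive_residues()].
#' @param sequence one-letter toxin sequence string (positions are residue
#'   numbers 1..nchar).
#' @param charge_reversal_to `"R"` (default) or `"K"`.
#' @return a `toxsel_mutation_proposal`: data frame with `position`, `from`,
#'   `to`, `rationale`.
#' @export
propose_mutations <- function(specific, repulsive, sequence,
                              charge_reversal_to = c("R", "K")) {
  charge_reversal_to <- match.arg(charge_reversal_to)
  sequence <- toupper(sequence)
  seq_chars <- strsplit(sequence, "")[[1L]]
  check_pos <- function(pos, from3) {
    if (pos < 1L || pos > length(seq_chars)) {
      stop("position ", pos, " outside sequence of length ", length(seq_chars))
    }
    expected <- AA_THREE_TO_ONE[from3]
    if (!is.na(expected) && seq_chars[pos] != expected) {
      stop(sprintf("sequence has %s at position %d, contacts say %s",
                   seq_chars[pos], pos, expected))
    }
  }
  rows <- list()
  for (pos in unique(specific$toxin_resno)) {
    hits <- specific[specific$toxin_resno == pos, , drop = FALSE]
    check_pos(pos, hits$toxin_resname[1L])
    why <- paste(sprintf("%s %s with %s (occ %.2f)", hits$isoform, hits$kind,
                         residue_label(hits$channel_resname,
                                       hits$channel_resno),
                         hits$occupancy), collapse = "; ")
    rows[[as.character(pos)]] <- data.frame(
      position = pos, from = seq_chars[pos], to = "A",
      rationale = paste0("off-target-specific polar contact(s): ", why),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(repulsive))) {
    pos <- repulsive$resno[i]
    check_pos(pos, repulsive$resname[i])
    if (!seq_chars[pos] %in% c("D", "E")) next  # reversal targets acids only
    iso_cols <- grep("^mean_total_", names(repulsive), value = TRUE)
    why <- paste0("repulsive in every isoform (",
                  paste(sprintf("%s %+.1f kJ/mol", sub("^mean_total_", "",
                                                       iso_cols),
                                as.numeric(repulsive[i, iso_cols])),
                        collapse = ", "), ")")
    key <- as.character(pos)
    if (!is.null(rows[[key]])) {
      # rule collision: keep the single Ala substitution, merge rationales
      rows[[key]]$rationale <- paste(rows[[key]]$rationale, why, sep = "; ")
    } else {
      rows[[key]] <- data.frame(position = pos, from = seq_chars[pos],
                                to = charge_reversal_to,
                                rationale = paste0("charge reversal: ", why),
                                stringsAsFactors = FALSE)
    }
  }
  prop <- if (length(rows) == 0L) {
    data.frame(position = integer(0), from = character(0), to = character(0),
               rationale = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  prop <- prop[prop$from != "C", , drop = FALSE]  # never touch the scaffold
  prop <- prop[order(prop$position), , drop = FALSE]
  prop <- prop[prop$from != prop$to, , drop = FALSE]
  rownames(prop) <- NULL
  class(prop) <- c("toxsel_mutation_proposal", class(prop))
  prop
}

#' Apply a mutation proposal to a sequence
#'
#' @param sequence one-letter sequence string.
#' @param proposal a `toxsel_mutation_proposal` (or data frame with
#'   `position`, `from`, `to`).
#' @return mutated sequence string, same length. Errors if a `from` residue
#'   does not match the sequence or if a substitution targets a cysteine.
#' @export
apply_mutations <- function(sequence, proposal) {
  seq_chars <- strsplit(toupper(sequence), "")[[1L]]
  for (i in seq_len(nrow(proposal))) {
    pos <- proposal$position[i]
    if (pos < 1L || pos > length(seq_chars)) {
      stop("substitution position ", pos, " outside sequence")
    }
    if (seq_chars[pos] != toupper(proposal$from[i])) {
      stop(sprintf("position %d is %s, proposal expects %s", pos,
                   seq_chars[pos], proposal$from[i]))
    }
    if (seq_chars[pos] == "C") {
      stop("refusing to substitute cysteine at position ", pos,
           " (disulfide scaffold)")
    }
    seq_chars[pos] <- toupper(proposal$to[i])
  }
  paste(seq_chars, collapse = "")
}

AA_THREE_TO_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                     GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                     LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                     SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Human-readable residue label (e.g. `Lys15`)
#' @param resname 3-letter code(s).
#' @param resno residue number(s).
#' @return character vector like `"Glu353"`.
#' @export
residue_label <- function(resname, resno) {
  paste0(substr(resname, 1L, 1L), tolower(substr(resname, 2L, 3L)), resno)
}

# ---- curated contact ledger ----------------------------------------------

#' Read a contact ledger
#'
#' A ledger is a curated table of isoform-specific interface facts: one row
#' per (toxin residue, isoform, channel residue) with the contact kinds
#' observed (comma-separated among hbond, salt_bridge, cation_pi, stacking,
#' hydrophobic) or, for `kinds = "repulsion"`, the sign of the residue's
#' energy contribution.
#'
#' @param path TSV with columns `toxin_resname`, `toxin_resno`, `isoform`,
#'   `channel_resname`, `channel_resno`, `kinds`.
#' @return a `toxsel_contact_ledger` data frame.
#' @export
read_contact_ledger <- function(path) {
  led <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("toxin_resname", "toxin_resno", "isoform", "channel_resname",
                "channel_resno", "kinds")
  if (!all(required %in% names(led))) {
    stop("ledger lacks column(s): ",
         paste(setdiff(required, names(led)), collapse = ", "))
  }
  class(led) <- c("toxsel_contact_ledger", class(led))
  led
}

#' Write a ledger as YAML / read it back
#' @param ledger a `toxsel_contact_ledger`.
#' @param path YAML file.
#' @export
write_ledger_yaml <- function(ledger, path) {
  yaml::write_yaml(lapply(seq_len(nrow(ledger)), function(i)
    as.list(as.data.frame(ledger)[i, ])), path)
  invisible(path)
}

#' @rdname write_ledger_yaml
#' @export
read_ledger_yaml <- function(path) {
  rows <- yaml::read_yaml(path)
  led <- do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  led$toxin_resno <- as.integer(led$toxin_resno)
  led$channel_resno <- as.integer(led$channel_resno)
  class(led) <- c("toxsel_contact_ledger", class(led))
  led
}

#' Expand a ledger into an isoform set
#'
#' Builds, for each isoform named in the ledger (plus any listed in
#' `isoforms` with no rows), a contact map in which every curated contact
#' has occupancy 1 and an energy profile over the toxin residues named in
#' the ledger. Rows with `kinds = "repulsion"` plant a positive mean total
#' (+5 kJ/mol stand-in; only the sign is consumed downstream) for that
#' toxin residue in that isoform; all other ledger residues get a small
#' attractive placeholder (-5 kJ/mol).
#'
#' @param ledger a `toxsel_contact_ledger`.
#' @param target target isoform label.
#' @param isoforms isoform universe; default the labels present in the
#'   ledger.
#' @return a `toxsel_isoform_set`.
#' @export
ledger_to_isoform_set <- function(ledger, target,
                                  isoforms = unique(ledger$isoform)) {
  isoforms <- union(isoforms, target)
  tox <- unique(ledger[, c("toxin_resname", "toxin_resno")])
  tox <- tox[order(tox$toxin_resno), , drop = FALSE]
  tox_key <- paste0("T:", tox$toxin_resno)
  entries <- list()
  for (iso in isoforms) {
    rows <- ledger[ledger$isoform == iso, , drop = FALSE]
    crows <- rows[rows$kinds != "repulsion", , drop = FALSE]
    cm <- do.call(rbind, c(list(NULL), lapply(seq_len(nrow(crows)), function(i) {
      kinds <- strsplit(crows$kinds[i], ",")[[1L]]
      data.frame(toxin_res = paste0("T:", crows$toxin_resno[i]),
                 toxin_resname = crows$toxin_resname[i],
                 toxin_resno = crows$toxin_resno[i],
                 channel_res = paste0(iso, ":", crows$channel_resno[i]),
                 channel_resname = crows$channel_resname[i],
                 channel_resno = crows$channel_resno[i],
                 kind = trimws(kinds), count = 1L, occupancy = 1,
                 stringsAsFactors = FALSE)
    })))
    if (is.null(cm)) {
      cm <- data.frame(toxin_res = character(0), toxin_resname = character(0),
                       toxin_resno = integer(0), channel_res = character(0),
                       channel_resname = character(0),
                       channel_resno = integer(0), kind = character(0),
                       count = integer(0), occupancy = numeric(0),
                       stringsAsFactors = FALSE)
    }
    rep_res <- unique(rows$toxin_resno[rows$kinds == "repulsion"])
    energy <- data.frame(toxin_res = tox_key, resname = tox$toxin_resname,
                         resno = tox$toxin_resno,
                         mean_coulomb = ifelse(tox$toxin_resno %in% rep_res, 5, -5),
                         mean_lj = 0,
                         mean_total = ifelse(tox$toxin_resno %in% rep_res, 5, -5),
                         sd_total = 1, stringsAsFactors = FALSE)
    entries[[iso]] <- list(contacts = cm, energy = energy)
  }
  isoform_set(entries, target = target)
}
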