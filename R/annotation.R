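# Chemical annotation: hydrogen-bond donors/acceptors, charged groups,
# aromatic rings and apolar carbons, from a per-residue template rule set.

#' Default residue annotation rules
#'
#' Returns the bundled per-residue template rule set used by
#' [annotate_chemistry()]. For each 3-letter residue name it lists hydrogen
#' bond donor pairs (heavy donor atom D with its attached hydrogen H),
#' acceptor atoms A, charged groups (sign and member atoms, e.g. Lys NZ
#' cationic, Asp/Glu carboxylate anionic), aromatic rings (>= 5 ring atoms,
#' Phe/Tyr/His/Trp) and apolar carbons for hydrophobic-contact detection.
#'
#' Histidine protonation is a configuration, not a guess: `his` selects the
#' N-epsilon tautomer (`"HIE"`, default: donor NE2-HE2, acceptor ND1), the
#' N-delta tautomer (`"HID"`: donor ND1-HD1 where present, acceptor NE2) or
#' the doubly protonated cation (`"HIP"`: cationic \{ND1, NE2\}).
#'
#' Atom rosters match the reduced residue templates of the synthetic
#' generator (backbone N, H, CA, C, O plus abridged side chains); atoms a
#' structure does not contain are silently dropped during annotation.
#'
#' @param his histidine protonation model, one of `"HIE"`, `"HID"`, `"HIP"`.
#' @return a named list of per-residue rule entries.
#' @export
default_annotation_rules <- function(his = c("HIE", "HID", "HIP")) {
  his <- match.arg(his)
  bb <- function(side_donors = list(), side_acceptors = character(0),
                 charged = list(), rings = list(), apolar = character(0),
                 backbone_donor = TRUE) {
    donors <- if (backbone_donor) c(list(c("N", "H")), side_donors) else side_donors
    list(donors = donors, acceptors = c("O", side_acceptors),
         charged = charged, rings = rings, apolar = apolar)
  }
  his_rule <- switch(his,
    HIE = bb(side_donors = list(c("NE2", "HE2")), side_acceptors = "ND1",
             rings = list(c("CG", "ND1", "CE1", "NE2", "CD2")), apolar = "CB"),
    HID = bb(side_donors = list(c("ND1", "HD1")), side_acceptors = "NE2",
             rings = list(c("CG", "ND1", "CE1", "NE2", "CD2")), apolar = "CB"),
    HIP = bb(charged = list(list(sign = 1L, atoms = c("ND1", "NE2"))),
             rings = list(c("CG", "ND1", "CE1", "NE2", "CD2")), apolar = "CB"))
  rules <- list(
    GLY = bb(),
    ALA = bb(apolar = "CB"),
    SER = bb(side_donors = list(c("OG", "HG")), side_acceptors = "OG"),
    THR = bb(side_donors = list(c("OG1", "HG1")), side_acceptors = "OG1",
             apolar = "CG2"),
    CYS = bb(apolar = "CB"),
    VAL = bb(apolar = c("CB", "CG1", "CG2")),
    LEU = bb(apolar = c("CB", "CG", "CD1", "CD2")),
    ILE = bb(apolar = c("CB", "CG1", "CG2", "CD1")),
    MET = bb(apolar = c("CB", "CG", "CE")),
    PRO = bb(backbone_donor = FALSE, apolar = c("CB", "CG", "CD")),
    PHE = bb(rings = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
             apolar = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    TYR = bb(side_donors = list(c("OH", "HH")), side_acceptors = "OH",
             rings = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
             apolar = c("CB", "CG", "CD1", "CD2", "CE1", "CE2")),
    TRP = bb(side_donors = list(c("NE1", "HE1")),
             rings = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                          c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
             apolar = c("CB", "CZ2", "CH2", "CZ3", "CE3")),
    HIS = his_rule,
    LYS = bb(side_donors = list(c("NZ", "HZ1"), c("NZ", "HZ2"), c("NZ", "HZ3")),
             charged = list(list(sign = 1L, atoms = "NZ")), apolar = "CB"),
    ARG = bb(side_donors = list(c("NH1", "HH11"), c("NH1", "HH12"),
                                c("NH2", "HH21"), c("NH2", "HH22")),
             charged = list(list(sign = 1L, atoms = c("NH1", "NH2"))),
             apolar = "CB"),
    ASP = bb(side_acceptors = c("OD1", "OD2"),
             charged = list(list(sign = -1L, atoms = c("OD1", "OD2"))),
             apolar = "CB"),
    GLU = bb(side_acceptors = c("OE1", "OE2"),
             charged = list(list(sign = -1L, atoms = c("OE1", "OE2"))),
             apolar = "CB"),
    ASN = bb(side_donors = list(c("ND2", "HD21"), c("ND2", "HD22")),
             side_acceptors = "OD1", apolar = "CB"),
    GLN = bb(side_donors = list(c("NE2", "HE21"), c("NE2", "HE22")),
             side_acceptors = "OE1", apolar = "CB")
  )
  attr(rules, "his") <- his
  rules
}

#' Read / write annotation rules as YAML
#'
#' Serialization of a rule set in the same shape as
#' [default_annotation_rules()].
#'
#' @param rules a rule set list.
#' @param path YAML file path.
#' @return `read_annotation_rules` returns the rule set list.
#' @export
write_annotation_rules <- function(rules, path) {
  his <- attr(rules, "his")
  yaml::write_yaml(list(his = his, residues = rules), path)
  invisible(path)
}

#' @rdname write_annotation_rules
#' @export
read_annotation_rules <- function(path) {
  obj <- yaml::read_yaml(path)
  rules <- obj$residues
  # yaml collapses length-1 character vectors; normalize donors to pairs
  for (rn in names(rules)) {
    rules[[rn]]$donors <- lapply(rules[[rn]]$donors, as.character)
    rules[[rn]]$acceptors <- as.character(rules[[rn]]$acceptors)
    rules[[rn]]$apolar <- as.character(rules[[rn]]$apolar)
    rules[[rn]]$rings <- lapply(rules[[rn]]$rings, as.character)
    rules[[rn]]$charged <- lapply(rules[[rn]]$charged, function(g)
      list(sign = as.integer(g$sign), atoms = as.character(g$atoms)))
  }
  attr(rules, "his") <- obj$his
  rules
}

#' Annotate donor/acceptor/charge/ring/apolar chemistry of a structure
#'
#' Deterministically maps the per-residue template rules onto a structure.
#' Annotation is strictly per residue (the structure annotation equals the
#' union of residue annotations); hydrogens must be explicit for donors to
#' be found. A residue name absent from the rule set yields a warning and an
#' empty annotation for that residue.
#'
#' @param s a `toxsel_structure` with its entity map set.
#' @param rules rule set, default [default_annotation_rules()].
#' @return an object of class `toxsel_annotation`: per-residue atom indices
#'   into the structure's atom table for donors (D, H pairs), acceptors,
#'   charged groups, aromatic rings and apolar carbons.
#' @export
annotate_chemistry <- function(s, rules = default_annotation_rules()) {
  stopifnot(inherits(s, "toxsel_structure"))
  if (is.null(s$entity_map)) stop("structure needs an entity map (set_entities)")
  keys <- residue_keys(s)
  ukeys <- unique(keys)
  ent <- atom_entities(s)
  res <- vector("list", length(ukeys))
  names(res) <- ukeys
  unknown <- character(0)
  for (k in ukeys) {
    idx <- which(keys == k)
    rn <- s$atoms$resname[idx[1L]]
    entry <- list(resname = rn, chain = s$atoms$chain[idx[1L]],
                  resno = s$atoms$resno[idx[1L]], entity = ent[idx[1L]],
                  donors = matrix(integer(0), ncol = 2L,
                                  dimnames = list(NULL, c("D", "H"))),
                  acceptors = integer(0), charged = list(),
                  rings = list(), apolar = integer(0))
    rule <- rules[[rn]]
    if (is.null(rule)) {
      unknown <- c(unknown, rn)
      res[[k]] <- entry
      next
    }
    find <- function(nm) idx[match(nm, s$atoms$name[idx])]
    dn <- do.call(rbind, lapply(rule$donors, function(p) {
      d <- find(p[1L]); h <- find(p[2L])
      if (anyNA(c(d, h))) NULL else c(d, h)
    }))
    if (!is.null(dn)) {
      entry$donors <- matrix(dn, ncol = 2L, dimnames = list(NULL, c("D", "H")))
    }
    acc <- find(rule$acceptors)
    entry$acceptors <- acc[!is.na(acc)]
    entry$charged <- Filter(Negate(is.null), lapply(rule$charged, function(g) {
      a <- find(g$atoms)
      a <- a[!is.na(a)]
      if (length(a) == 0L) NULL else list(sign = g$sign, atoms = a)
    }))
    entry$rings <- Filter(Negate(is.null), lapply(rule$rings, function(r) {
      a <- find(r)
      if (anyNA(a) || length(a) < 5L) NULL else a
    }))
    ap <- find(rule$apolar)
    entry$apolar <- ap[!is.na(ap)]
    res[[k]] <- entry
  }
  if (length(unknown) > 0L) {
    warning("no annotation rule for residue(s): ",
            paste(unique(unknown), collapse = ", "), "; left unannotated")
  }
  structure(list(residues = res, n_atoms = nrow(s$atoms)),
            class = "toxsel_annotation")
}
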