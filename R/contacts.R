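# Frame-wise geometric detection of interface contacts and their occupancy
# over a trajectory.

#' Geometric contact criteria
#'
#' The hydrogen-bond thresholds (donor-acceptor distance <= 0.35 nm, D-H-A
#' angle at the hydrogen >= 150 degrees) follow the GROMACS `hbond`
#' convention. The remaining thresholds are explicit, tunable conventions
#' (no single literature standard exists): minimal N/O-N/O distance
#' <= 0.40 nm between opposite-sign charged groups for salt bridges;
#' cation-to-ring-centroid <= 0.60 nm with ring-normal angle <= 45 degrees
#' for cation-pi; ring-centroid distance <= 0.55 nm with interplanar angle
#' <= 30 degrees (parallel) or 60-90 degrees (T-shaped) for stacking; any
#' apolar carbon-carbon pair <= 0.45 nm for hydrophobic contacts. All
#' comparisons are inclusive.
#'
#' @param hbond_da_max,saltbridge_max,cationpi_max,stacking_centroid_max,hydrophobic_cc_max
#'   distance thresholds, nm (> 0).
#' @param hbond_dha_min,cationpi_angle_max,stacking_parallel_max,stacking_tshape_min,stacking_tshape_max
#'   angle thresholds, degrees in \[0, 180\].
#' @return an object of class `toxsel_criteria`.
#' @export
contact_criteria <- function(hbond_da_max = 0.35, hbond_dha_min = 150,
                             saltbridge_max = 0.40,
                             cationpi_max = 0.60, cationpi_angle_max = 45,
                             stacking_centroid_max = 0.55,
                             stacking_parallel_max = 30,
                             stacking_tshape_min = 60,
                             stacking_tshape_max = 90,
                             hydrophobic_cc_max = 0.45) {
  cr <- list(hbond_da_max = hbond_da_max, hbond_dha_min = hbond_dha_min,
             saltbridge_max = saltbridge_max, cationpi_max = cationpi_max,
             cationpi_angle_max = cationpi_angle_max,
             stacking_centroid_max = stacking_centroid_max,
             stacking_parallel_max = stacking_parallel_max,
             stacking_tshape_min = stacking_tshape_min,
             stacking_tshape_max = stacking_tshape_max,
             hydrophobic_cc_max = hydrophobic_cc_max)
  dists <- cr[grep("_max$|saltbridge", names(cr))]
  if (any(unlist(cr[c("hbond_da_max", "saltbridge_max", "cationpi_max",
                      "stacking_centroid_max", "hydrophobic_cc_max")]) <= 0)) {
    stop("distance thresholds must be positive")
  }
  angles <- unlist(cr[c("hbond_dha_min", "cationpi_angle_max",
                        "stacking_parallel_max", "stacking_tshape_min",
                        "stacking_tshape_max")])
  if (any(angles < 0 | angles > 180)) stop("angles must lie in [0, 180]")
  class(cr) <- "toxsel_criteria"
  cr
}

empty_contacts <- function() {
  data.frame(kind = character(0), toxin_res = character(0),
             toxin_resname = character(0), toxin_resno = integer(0),
             channel_res = character(0), channel_resname = character(0),
             channel_resno = integer(0), atoms = character(0),
             distance = numeric(0), angle = numeric(0),
             stringsAsFactors = FALSE)
}

contact_row <- function(kind, tox, cha, atoms = "", distance = NA_real_,
                        angle = NA_real_) {
  data.frame(kind = kind,
             toxin_res = paste(tox$chain, tox$resno, sep = ":"),
             toxin_resname = tox$resname, toxin_resno = tox$resno,
             channel_res = paste(cha$chain, cha$resno, sep = ":"),
             channel_resname = cha$resname, channel_resno = cha$resno,
             atoms = atoms, distance = distance, angle = angle,
             stringsAsFactors = FALSE)
}

# split annotation residues by entity, orienting every pair toxin/channel
entity_split <- function(annotation) {
  ent <- vapply(annotation$residues, function(r) r$entity, character(1))
  list(toxin = annotation$residues[ent == "toxin"],
       channel = annotation$residues[ent == "channel"])
}

vec_angle_deg <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

ring_geometry <- function(coords, ring_idx) {
  pts <- coords[ring_idx, , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  if (sv$d[2L] < 1e-9) stop("degenerate (collinear) aromatic ring")
  list(centroid = ctr, normal = sv$v[, 3L])
}

check_frame <- function(annotation, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != annotation$n_atoms || ncol(coords) != 3L) {
    stop("coordinate matrix does not match the annotated structure")
  }
  coords
}

#' Detect interface hydrogen bonds in one frame
#'
#' A hydrogen bond D-H...A is scored when the donor-acceptor distance
#' satisfies D-A <= `hbond_da_max` and the angle at the hydrogen satisfies
#' D-H-A >= `hbond_dha_min`. Only cross-entity (toxin vs channel) pairs are
#' considered; donors require explicit hydrogens.
#'
#' @param annotation a `toxsel_annotation`.
#' @param coords n x 3 coordinate matrix for the frame (nm).
#' @param criteria a `toxsel_criteria`.
#' @return contact data frame (one row per (D,H,A) triple found).
#' @export
detect_hbonds <- function(annotation, coords, criteria = contact_criteria()) {
  coords <- check_frame(annotation, coords)
  es <- entity_split(annotation)
  out <- list()
  scan <- function(donor_res, acceptor_res, tox, cha) {
    if (nrow(donor_res$donors) == 0L || length(acceptor_res$acceptors) == 0L) {
      return()
    }
    for (di in seq_len(nrow(donor_res$donors))) {
      d <- donor_res$donors[di, "D"]
      h <- donor_res$donors[di, "H"]
      if (anyNA(coords[h, ])) stop("donor hydrogen has no coordinates")
      for (a in acceptor_res$acceptors) {
        da <- sqrt(sum((coords[d, ] - coords[a, ])^2))
        if (da > criteria$hbond_da_max) next
        ang <- vec_angle_deg(coords[d, ] - coords[h, ], coords[a, ] - coords[h, ])
        if (ang < criteria$hbond_dha_min) next
        out[[length(out) + 1L]] <<- contact_row("hbond", tox, cha,
          atoms = paste0(donor_res$resname, ":", di, "->", acceptor_res$resname),
          distance = da, angle = ang)
      }
    }
  }
  for (tr in es$toxin) for (cr in es$channel) {
    scan(tr, cr, tox = tr, cha = cr)   # toxin donates
    scan(cr, tr, tox = tr, cha = cr)   # channel donates
  }
  if (length(out) == 0L) empty_contacts() else do.call(rbind, out)
}

#' Detect interface salt bridges in one frame
#'
#' Opposite-sign charged groups across the interface form a salt bridge when
#' the minimal distance between their nitrogen/oxygen atoms is
#' <= `saltbridge_max`.
#'
#' @inheritParams detect_hbonds
#' @return contact data frame.
#' @export
detect_salt_bridges <- function(annotation, coords,
                                criteria = contact_criteria()) {
  coords <- check_frame(annotation, coords)
  es <- entity_split(annotation)
  out <- list()
  for (tr in es$toxin) for (cr in es$channel) {
    for (g1 in tr$charged) for (g2 in cr$charged) {
      if (g1$sign * g2$sign >= 0L) next
      dmin <- min(as.matrix(stats::dist(rbind(
        coords[g1$atoms, , drop = FALSE],
        coords[g2$atoms, , drop = FALSE])))[seq_along(g1$atoms),
          length(g1$atoms) + seq_along(g2$atoms), drop = FALSE])
      if (dmin <= criteria$saltbridge_max) {
        out[[length(out) + 1L]] <- contact_row("salt_bridge", tr, cr,
          atoms = sprintf("%+d/%+d", g1$sign, g2$sign), distance = dmin)
      }
    }
  }
  if (length(out) == 0L) empty_contacts() else do.call(rbind, out)
}

#' Detect interface cation-pi contacts in one frame
#'
#' A cationic group and an aromatic ring across the interface are in contact
#' when the cation-to-ring-centroid distance is <= `cationpi_max` and the
#' angle between the ring normal and the centroid-to-cation vector (folded
#' to \[0, 90\]) is <= `cationpi_angle_max`, i.e. the cation sits over the
#' ring face rather than in its plane.
#'
#' @inheritParams detect_hbonds
#' @return contact data frame.
#' @export
detect_cation_pi <- function(annotation, coords,
                             criteria = contact_criteria()) {
  coords <- check_frame(annotation, coords)
  es <- entity_split(annotation)
  out <- list()
  pair <- function(cat_res, ring_res, tox, cha) {
    for (g in cat_res$charged) {
      if (g$sign <= 0L) next
      cat_pos <- colMeans(coords[g$atoms, , drop = FALSE])
      for (ring in ring_res$rings) {
        geo <- ring_geometry(coords, ring)
        v <- cat_pos - geo$centroid
        dist <- sqrt(sum(v^2))
        if (dist > criteria$cationpi_max) next
        ang <- vec_angle_deg(geo$normal, v)
        ang <- min(ang, 180 - ang)
        if (ang > criteria$cationpi_angle_max) next
        out[[length(out) + 1L]] <<- contact_row("cation_pi", tox, cha,
          atoms = paste0("cation@", cat_res$resname, "->ring@", ring_res$resname),
          distance = dist, angle = ang)
      }
    }
  }
  for (tr in es$toxin) for (cr in es$channel) {
    pair(tr, cr, tox = tr, cha = cr)   # toxin cation on channel ring
    pair(cr, tr, tox = tr, cha = cr)   # channel cation on toxin ring
  }
  if (length(out) == 0L) empty_contacts() else do.call(rbind, out)
}

#' Detect interface aromatic stacking in one frame
#'
#' Ring pairs across the interface stack when their centroid distance is
#' <= `stacking_centroid_max` and the interplanar angle (between ring
#' normals, folded to \[0, 90\]) falls in the parallel window
#' (<= `stacking_parallel_max`) or the T-shaped window
#' (`stacking_tshape_min`-`stacking_tshape_max`).
#'
#' @inheritParams detect_hbonds
#' @return contact data frame; the `atoms` column records `parallel` or
#'   `t-shaped`.
#' @export
detect_stacking <- function(annotation, coords,
                            criteria = contact_criteria()) {
  coords <- check_frame(annotation, coords)
  es <- entity_split(annotation)
  out <- list()
  for (tr in es$toxin) for (cr in es$channel) {
    for (r1 in tr$rings) for (r2 in cr$rings) {
      g1 <- ring_geometry(coords, r1)
      g2 <- ring_geometry(coords, r2)
      dist <- sqrt(sum((g1$centroid - g2$centroid)^2))
      if (dist > criteria$stacking_centroid_max) next
      ang <- vec_angle_deg(g1$normal, g2$normal)
      ang <- min(ang, 180 - ang)
      mode <- if (ang <= criteria$stacking_parallel_max) "parallel"
        else if (ang >= criteria$stacking_tshape_min &&
                 ang <= criteria$stacking_tshape_max) "t-shaped"
        else next
      out[[length(out) + 1L]] <- contact_row("stacking", tr, cr,
        atoms = mode, distance = dist, angle = ang)
    }
  }
  if (length(out) == 0L) empty_contacts() else do.call(rbind, out)
}

#' Detect interface hydrophobic contacts in one frame
#'
#' A toxin residue and a channel residue are in hydrophobic contact when any
#' pair of their apolar carbons is <= `hydrophobic_cc_max` apart; at most
#' one contact is reported per residue pair per frame.
#'
#' @inheritParams detect_hbonds
#' @return contact data frame.
#' @export
detect_hydrophobic <- function(annotation, coords,
                               criteria = contact_criteria()) {
  coords <- check_frame(annotation, coords)
  es <- entity_split(annotation)
  out <- list()
  for (tr in es$toxin) for (cr in es$channel) {
    if (length(tr$apolar) == 0L || length(cr$apolar) == 0L) next
    a <- coords[tr$apolar, , drop = FALSE]
    b <- coords[cr$apolar, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    dmin <- sqrt(max(0, min(d2)))
    if (dmin <= criteria$hydrophobic_cc_max) {
      out[[length(out) + 1L]] <- contact_row("hydrophobic", tr, cr,
        atoms = "apolar C-C", distance = dmin)
    }
  }
  if (length(out) == 0L) empty_contacts() else do.call(rbind, out)
}

#' All interface contacts in one frame
#'
#' Runs the five detectors and binds their results.
#'
#' @inheritParams detect_hbonds
#' @return contact data frame.
#' @export
frame_contacts <- function(annotation, coords, criteria = contact_criteria()) {
  rbind(detect_hbonds(annotation, coords, criteria),
        detect_salt_bridges(annotation, coords, criteria),
        detect_cation_pi(annotation, coords, criteria),
        detect_stacking(annotation, coords, criteria),
        detect_hydrophobic(annotation, coords, criteria))
}

#' Contact occupancy over a trajectory
#'
#' Detects contacts in every frame after `burn_in` and reports, per
#' (toxin residue, channel residue, contact kind), the fraction of analyzed
#' frames in which the contact is present. Pairs never detected are absent
#' from the map (occupancy 0 by convention).
#'
#' @param traj a `toxsel_trajectory`.
#' @param annotation a `toxsel_annotation` of the trajectory topology.
#' @param criteria a `toxsel_criteria`.
#' @param burn_in number of leading frames to discard (must leave at least
#'   one frame).
#' @return a `toxsel_contactmap`: data frame with residue labels, `kind`,
#'   `count` and `occupancy`; attributes `n_frames` (frames analyzed) and
#'   `criteria`.
#' @export
contact_occupancy <- function(traj, annotation, criteria = contact_criteria(),
                              burn_in = 0L) {
  stopifnot(inherits(traj, "toxsel_trajectory"))
  nf <- length(traj$frames)
  if (burn_in >= nf) stop("burn_in must leave at least one frame")
  use <- seq.int(burn_in + 1L, nf)
  tallies <- new.env(parent = emptyenv())
  rows <- new.env(parent = emptyenv())
  for (m in use) {
    cc <- frame_contacts(annotation, traj$frames[[m]], criteria)
    if (nrow(cc) == 0L) next
    keys <- unique(paste(cc$toxin_res, cc$channel_res, cc$kind, sep = "|"))
    for (k in keys) {
      tallies[[k]] <- (if (is.null(tallies[[k]])) 0L else tallies[[k]]) + 1L
      if (is.null(rows[[k]])) {
        rows[[k]] <- cc[match(k, paste(cc$toxin_res, cc$channel_res, cc$kind,
                                       sep = "|")), ]
      }
    }
  }
  keys <- sort(ls(tallies))
  if (length(keys) == 0L) {
    cm <- empty_contacts()[, c("toxin_res", "toxin_resname", "toxin_resno",
                               "channel_res", "channel_resname",
                               "channel_resno", "kind")]
    cm$count <- integer(0)
    cm$occupancy <- numeric(0)
  } else {
    cm <- do.call(rbind, lapply(keys, function(k) rows[[k]]))
    cm <- cm[, c("toxin_res", "toxin_resname", "toxin_resno", "channel_res",
                 "channel_resname", "channel_resno", "kind")]
    cm$count <- vapply(keys, function(k) tallies[[k]], integer(1))
    cm$occupancy <- cm$count / length(use)
    rownames(cm) <- NULL
  }
  attr(cm, "n_frames") <- length(use)
  attr(cm, "burn_in") <- burn_in
  attr(cm, "criteria") <- criteria
  class(cm) <- c("toxsel_contactmap", class(cm))
  cm
}

#' Write / read a contact map as TSV
#'
#' @param cm a `toxsel_contactmap`.
#' @param path TSV file.
#' @return `read_contact_map` returns the data frame (criteria metadata is
#'   written alongside as JSON with extension `.meta.json`).
#' @export
write_contact_map <- function(cm, path) {
  utils::write.table(as.data.frame(cm), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(n_frames = attr(cm, "n_frames"), burn_in = attr(cm, "burn_in"),
               criteria = unclass(attr(cm, "criteria")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  cm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(cm, "n_frames") <- meta$n_frames
    attr(cm, "burn_in") <- meta$burn_in
    attr(cm, "criteria") <- do.call(contact_criteria, as.list(meta$criteria))
  }
  class(cm) <- c("toxsel_contactmap", class(cm))
  cm
}
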