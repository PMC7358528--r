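# Rigid-body superposition (Kabsch) and toxin-on-scaffold grafting.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' mapped atom pairs, mobile onto reference. At least 3 non-collinear pairs
#' are required.
#'
#' @param mobile n x 3 coordinate matrix (nm).
#' @param reference n x 3 coordinate matrix (nm).
#' @param mapping optional 2-column integer matrix pairing rows of `mobile`
#'   (column 1) with rows of `reference` (column 2); default pairs row i
#'   with row i. No duplicate atoms allowed on either side.
#' @return a `toxsel_transform`: `rotation` (3 x 3, det +1), `translation`
#'   (nm), `rmsd_before` and `rmsd_after` (nm) over the mapped pairs.
#' @export
kabsch_superpose <- function(mobile, reference, mapping = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (is.null(mapping)) {
    if (nrow(mobile) != nrow(reference)) {
      stop("without a mapping, mobile and reference need equal atom counts")
    }
    mapping <- cbind(seq_len(nrow(mobile)), seq_len(nrow(mobile)))
  }
  mapping <- as.matrix(mapping)
  if (nrow(mapping) < 3L) stop("mapping needs at least 3 atom pairs")
  if (anyDuplicated(mapping[, 1L]) || anyDuplicated(mapping[, 2L])) {
    stop("mapping has duplicate atoms")
  }
  P <- mobile[mapping[, 1L], , drop = FALSE]      # mobile
  Q <- reference[mapping[, 2L], , drop = FALSE]   # reference
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  sv <- svd(crossprod(Pc, Qc))  # 3x3 covariance P^T Q
  if (sv$d[2L] < 1e-12) stop("mapped atoms are collinear; superposition is degenerate")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)   # x' = R x
  t <- cq - as.vector(R %*% cp)
  fitted <- sweep(Pc %*% t(R), 2L, cq, "+")
  rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
  structure(list(rotation = R, translation = t,
                 rmsd_before = rmsd(P, Q), rmsd_after = rmsd(fitted, Q)),
            class = "toxsel_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix (nm).
#' @param tf a `toxsel_transform`.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, tf) {
  stopifnot(inherits(tf, "toxsel_transform"))
  sweep(as.matrix(coords) %*% t(tf$rotation), 2L, tf$translation, "+")
}

#' @export
print.toxsel_transform <- function(x, ...) {
  cat(sprintf("<toxsel_transform> rmsd %.4g -> %.4g nm\n",
              x$rmsd_before, x$rmsd_after))
  invisible(x)
}

#' Count inter-entity steric clashes
#'
#' Diagnostic only: number of heavy-atom pairs across the toxin/channel
#' interface closer than `threshold` (default 0.2 nm). Never auto-repaired;
#' a grafted pose is expected to be relaxed by downstream refinement.
#'
#' @param s a `toxsel_structure` with entity map.
#' @param threshold nm.
#' @return integer clash count.
#' @export
count_clashes <- function(s, threshold = 0.2) {
  ent <- atom_entities(s)
  heavy <- !is_hydrogen(s$atoms$element)
  xyz <- coords_matrix(s)
  it <- which(ent == "toxin" & heavy)
  ic <- which(ent == "channel" & heavy)
  if (length(it) == 0L || length(ic) == 0L) return(0L)
  d2 <- outer(rowSums(xyz[it, , drop = FALSE]^2),
              rowSums(xyz[ic, , drop = FALSE]^2), "+") -
    2 * xyz[it, , drop = FALSE] %*% t(xyz[ic, , drop = FALSE])
  sum(d2 < threshold^2)
}

#' Graft a toxin onto a channel-bound scaffold
#'
#' Builds a new complex by superposing `new_toxin` onto the scaffold toxin
#' chain of `complex` (Kabsch on a user-supplied residue correspondence) and
#' replacing the scaffold with the transformed toxin. Channel chains are
#' passed through untouched, byte for byte. The returned object reports the
#' post-graft inter-entity heavy-atom clash count (< 0.2 nm), a diagnostic
#' that is never auto-repaired.
#'
#' @param complex a `toxsel_structure` whose entity map labels the scaffold
#'   chain as `"toxin"` and the remaining chains as `"channel"`.
#' @param new_toxin a single-chain `toxsel_structure` to graft in.
#' @param scaffold_chain chain id of the scaffold toxin inside `complex`.
#' @param residue_map 2-column data frame / matrix of residue numbers:
#'   column 1 in `new_toxin`, column 2 in the scaffold. The paper-style
#'   construction gives no canonical correspondence between a toxin and a
#'   scaffold of different length, so this is a required input.
#' @param atoms which mapped atoms to superpose on: `"CA"` (default) or
#'   `"backbone"` (N, CA, C, O).
#' @param clash_threshold nm, heavy-atom clash diagnostic cutoff.
#' @return list with `structure` (the grafted complex), `transform`
#'   (the `toxsel_transform` used) and `n_clashes`.
#' @export
graft_ligand <- function(complex, new_toxin, scaffold_chain, residue_map,
                         atoms = c("CA", "backbone"), clash_threshold = 0.2) {
  atoms <- match.arg(atoms)
  stopifnot(inherits(complex, "toxsel_structure"),
            inherits(new_toxin, "toxsel_structure"))
  if (is.null(complex$entity_map)) stop("complex needs an entity map")
  if (!scaffold_chain %in% complex$atoms$chain) {
    stop("scaffold chain '", scaffold_chain, "' absent from complex")
  }
  atom_names <- if (atoms == "CA") "CA" else c("N", "CA", "C", "O")
  residue_map <- as.matrix(residue_map)
  scaf <- complex$atoms$chain == scaffold_chain
  pairs <- NULL
  for (i in seq_len(nrow(residue_map))) {
    for (an in atom_names) {
      im <- which(new_toxin$atoms$resno == residue_map[i, 1L] &
                    new_toxin$atoms$name == an)
      ir <- which(scaf & complex$atoms$resno == residue_map[i, 2L] &
                    complex$atoms$name == an)
      if (length(im) == 1L && length(ir) == 1L) pairs <- rbind(pairs, c(im, ir))
    }
  }
  if (is.null(pairs) || nrow(pairs) < 3L) {
    stop("residue correspondence yields fewer than 3 mapped atoms")
  }
  tf <- kabsch_superpose(coords_matrix(new_toxin), coords_matrix(complex),
                         mapping = pairs)
  placed <- set_coords(new_toxin, apply_transform(coords_matrix(new_toxin), tf))
  toxin_chain <- unique(placed$atoms$chain)
  if (length(toxin_chain) != 1L) stop("new_toxin must be a single chain")
  if (toxin_chain %in% setdiff(unique(complex$atoms$chain), scaffold_chain)) {
    stop("toxin chain id collides with a channel chain id")
  }
  keep <- complex$atoms[!scaf, , drop = FALSE]
  merged <- rbind(keep, placed$atoms)
  merged$serial <- seq_len(nrow(merged))
  emap <- c(complex$entity_map[setdiff(names(complex$entity_map), scaffold_chain)],
            stats::setNames("toxin", toxin_chain))
  out <- new_structure(merged, entity_map = emap)
  list(structure = out, transform = tf,
       n_clashes = count_clashes(out, clash_threshold))
}
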