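# Local atomic coordinate frames.
#
# Transferred multipole populations are only meaningful in a frame tied
# to the atom's bonded environment; the same chemical rule applied to any
# rigidly moved copy of a structure yields a rigidly co-rotated frame,
# which is what makes downstream energies invariant under rigid motion.

# neighbor priority: higher Z first, then shorter bond, then lower serial
.neighbor_priority <- function(i, nbrs, snapshot) {
  a <- snapshot$atoms
  d <- sqrt(rowSums((snapshot$xyz[nbrs, , drop = FALSE] -
                       matrix(snapshot$xyz[i, ], length(nbrs), 3,
                              byrow = TRUE))^2))
  nbrs[order(-a$Z[nbrs], d, a$serial[nbrs])]
}

#' Build the local coordinate frame of one atom
#'
#' Deterministic frame from bonded neighbors: the z-axis points toward
#' the highest-priority neighbor (priority: higher nuclear charge, then
#' shorter bond, then lower serial); the x-axis lies in the plane of the
#' next-priority neighbor; y completes a right-handed system. For a
#' terminal atom the secondary reference is taken from the neighbors of
#' its single neighbor. References closer than 5 degrees to the z-axis
#' are skipped; if no usable reference remains, the global axis least
#' aligned with z is used (with a warning). An isolated atom gets the
#' identity frame with a warning.
#'
#' @param iatom 1-based atom index.
#' @param snapshot a `pa_snapshot`.
#' @param bonds a `pa_bonds` from [infer_connectivity()].
#' @return list with `R` (3x3 rotation, columns = local axes in global
#'   coordinates, det = +1) and `definition` (indices used for z and x).
#' @export
build_local_frame <- function(iatom, snapshot, bonds) {
  xyz <- snapshot$xyz
  nbrs <- bonds$neighbors[[iatom]]
  if (!length(nbrs)) {
    warning("atom ", iatom, " has no bonded neighbor; identity frame")
    return(list(R = diag(3), definition = list(z = NA, x = NA)))
  }
  nbrs <- .neighbor_priority(iatom, nbrs, snapshot)
  zi <- nbrs[1]
  ez <- xyz[zi, ] - xyz[iatom, ]
  ez <- ez / sqrt(sum(ez^2))
  cand <- nbrs[-1]
  if (!length(cand)) {
    # terminal atom: borrow references from the neighbor's neighbors
    nn <- setdiff(bonds$neighbors[[zi]], iatom)
    if (length(nn)) cand <- .neighbor_priority(zi, nn, snapshot)
  }
  xi <- NA
  ex <- NULL
  for (j in cand) {
    v <- xyz[j, ] - xyz[iatom, ]
    v <- v / sqrt(sum(v^2))
    if (abs(sum(v * ez)) > cos(5 * pi / 180)) next  # collinear with z
    ex <- v - sum(v * ez) * ez
    ex <- ex / sqrt(sum(ex^2))
    xi <- j
    break
  }
  if (is.null(ex)) {
    warning("atom ", iatom,
            ": no non-collinear frame reference; using a global axis")
    ax <- diag(3)[, which.min(abs(ez))]
    ex <- ax - sum(ax * ez) * ez
    ex <- ex / sqrt(sum(ex^2))
  }
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  list(R = cbind(ex, ey, ez, deparse.level = 0),
       definition = list(z = zi, x = xi))
}
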