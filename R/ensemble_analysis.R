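# Ensemble-level analysis: run the energy pipeline over every snapshot
# of a multi-model structure, average residue-level matrices, format
# mean(SD) values in the crystallographic style, profile hydrogen bonds
# and flag directly contacting residue pairs by their penetration energy.

#' Run the energy pipeline over a snapshot ensemble
#'
#' Transfers bank parameters onto every snapshot (shared topology:
#' connectivity and atom types are derived from the first snapshot),
#' optionally normalizes the total charge of the evaluated selection,
#' and computes the hybrid interaction energy matrix between two atom
#' groups for each snapshot.
#'
#' @param ensemble a `pa_ensemble`.
#' @param bank a `pa_bank`.
#' @param group_a,group_b disjoint integer atom-index vectors.
#' @param cutoff inner-region cutoff, angstrom.
#' @param level aggregation level, `"residue"` or `"chain"`.
#' @param fallback transfer fallback policy, see [transfer_parameters()].
#' @param normalize if `TRUE` (default), rescale valence populations so
#'   the union of the two groups carries `target_charge`.
#' @param target_charge formal total charge of the evaluated selection.
#' @param tol exact-integral tolerance, hartree.
#' @return list with `matrices` (one `pa_energy_matrix` per snapshot),
#'   `interactions` (per-snapshot `pa_interaction`), `bonds`, `types`.
#' @export
ensemble_energies <- function(ensemble, bank, group_a, group_b,
                              cutoff = 4.5, level = "residue",
                              fallback = "strict", normalize = TRUE,
                              target_charge = 0, tol = 1e-5) {
  stopifnot(inherits(ensemble, "pa_ensemble"))
  bonds <- infer_connectivity(get_snapshot(ensemble, 1L),
                              extra = ensemble$conect)
  types <- assign_atom_types(get_snapshot(ensemble, 1L), bonds)
  nsnap <- n_snapshots(ensemble)
  matrices <- vector("list", nsnap)
  interactions <- vector("list", nsnap)
  sel <- union(group_a, group_b)
  for (k in seq_len(nsnap)) {
    snap <- get_snapshot(ensemble, k)
    param <- tryCatch(
      transfer_parameters(snap, bonds, bank, fallback = fallback),
      error = function(e) stop("parameter transfer failed on snapshot ",
                               k, ": ", conditionMessage(e), call. = FALSE))
    if (normalize)
      param <- normalize_charge(param, group = sel, target = target_charge)
    inter <- epmm_interaction(param, group_a, group_b, cutoff = cutoff,
                              tol = tol)
    interactions[[k]] <- inter
    matrices[[k]] <- aggregate_energy(inter, snap, level = level)
  }
  list(matrices = matrices, interactions = interactions, bonds = bonds,
       types = types)
}

#' Entry-wise mean and standard deviation of energy matrices
#'
#' Computes the per-entry mean and sample standard deviation (n-1
#' denominator; snapshots are treated as a sample of the trajectory)
#' of the Ees and Epen matrices across snapshots. With a single
#' snapshot the SD is 0.
#'
#' @param matrices list of `pa_energy_matrix` with identical shapes and
#'   labels.
#' @return object of class `pa_profile`: list with `n`, `row_labels`,
#'   `col_labels`, `ees_mean`, `ees_sd`, `epen_mean`, `epen_sd`.
#' @export
profile_mean_sd <- function(matrices) {
  if (!length(matrices)) stop("need at least one matrix")
  ref <- matrices[[1]]
  for (m in matrices) {
    if (!identical(dim(m$ees), dim(ref$ees)) ||
        !identical(m$row_labels, ref$row_labels) ||
        !identical(m$col_labels, ref$col_labels))
      stop("matrix shapes/labels differ across snapshots")
  }
  n <- length(matrices)
  stack <- function(field) {
    arr <- vapply(matrices, function(m) m[[field]], ref$ees)
    dim(arr) <- c(dim(ref$ees), n)
    arr
  }
  msd <- function(field) {
    arr <- stack(field)
    mean_ <- apply(arr, c(1, 2), mean)
    sd_ <- if (n > 1) apply(arr, c(1, 2), stats::sd) else
      array(0, dim(ref$ees))
    dimnames(mean_) <- dimnames(sd_) <- dimnames(ref$ees)
    list(mean = mean_, sd = sd_)
  }
  ees <- msd("ees"); epen <- msd("epen")
  structure(list(n = n, row_labels = ref$row_labels,
                 col_labels = ref$col_labels,
                 ees_mean = ees$mean, ees_sd = ees$sd,
                 epen_mean = epen$mean, epen_sd = epen$sd),
            class = "pa_profile")
}

#' Format a value as mean(SD) in the crystallographic style
#'
#' The SD is expressed in units of the last reported digit of the mean,
#' e.g. mean -76.3, SD 23.1 with `digits = 0` gives `"-76(23)"`, and
#' with `digits = 1` gives `"-76.3(231)"`.
#'
#' @param mean_,sd_ numeric vectors (recycled).
#' @param digits decimal places used for the mean (default 0).
#' @return character vector.
#' @seealso [parse_mean_sd()]
#' @export
format_mean_sd <- function(mean_, sd_, digits = 0) {
  sprintf("%.*f(%.0f)", digits, mean_, round(abs(sd_) * 10^digits))
}

#' Parse a mean(SD) string back to numbers
#'
#' Inverse of [format_mean_sd()]: the digit count of the mean's decimal
#' part determines the scale of the parenthesized SD.
#'
#' @param s character vector like `"-76(23)"` or `"-7.6(23)"`.
#' @return data.frame with columns `mean` and `sd`.
#' @export
parse_mean_sd <- function(s) {
  m <- regmatches(s, regexec("^\\s*(-?[0-9]*\\.?[0-9]+)\\(([0-9]+)\\)\\s*$", s))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("unparsable mean(SD) string: ",
                     paste(s[bad], collapse = ", "))
  mean_ <- vapply(m, function(x) as.numeric(x[2]), numeric(1))
  dec <- vapply(m, function(x) {
    dot <- regmatches(x[2], regexec("\\.([0-9]+)$", x[2]))[[1]]
    if (length(dot) == 2L) nchar(dot[2]) else 0L
  }, integer(1))
  sd_ <- vapply(m, function(x) as.numeric(x[3]), numeric(1)) / 10^dec
  data.frame(mean = mean_, sd = sd_)
}

#' Detect hydrogen bonds in one snapshot
#'
#' Geometric criterion: donor D in {N, O, S} covalently bonded to H,
#' acceptor A in {N, O, S} not covalently bonded to D, donor-acceptor
#' distance at most `d_max` and D-H...A angle at least `theta_min`.
#' The defaults (3.5 angstrom, 120 degrees) are conventional and
#' deliberately adjustable, since reported contacts can be slightly
#' longer than commonly accepted donor-acceptor distances.
#'
#' @param snapshot a `pa_snapshot`.
#' @param bonds a `pa_bonds`.
#' @param d_max maximum D...A distance, angstrom.
#' @param theta_min minimum D-H...A angle, degrees.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`
#'   (1-based atom indices), `d_da` (angstrom), `angle` (degrees).
#' @export
detect_hbonds <- function(snapshot, bonds, d_max = 3.5, theta_min = 120) {
  a <- snapshot$atoms
  xyz <- snapshot$xyz
  dh_elems <- c("N", "O", "S")
  out <- list()
  hyd <- which(a$elem == "H")
  for (h in hyd) {
    dn <- bonds$neighbors[[h]]
    dn <- dn[a$elem[dn] %in% dh_elems]
    if (length(dn) != 1L) next
    d <- dn[1]
    acc <- which(a$elem %in% dh_elems)
    acc <- setdiff(acc, c(d, bonds$neighbors[[d]]))
    for (ac in acc) {
      dda <- sqrt(sum((xyz[d, ] - xyz[ac, ])^2))
      if (dda > d_max) next
      v1 <- xyz[d, ] - xyz[h, ]
      v2 <- xyz[ac, ] - xyz[h, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < theta_min) next
      out[[length(out) + 1L]] <-
        data.frame(donor = d, hydrogen = h, acceptor = ac,
                   d_da = dda, angle = ang)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), d_da = numeric(),
                      angle = numeric()))
  do.call(rbind, out)
}

#' Hydrogen-bond occupancy across an ensemble
#'
#' Detects hydrogen bonds in every snapshot and reports, per unique
#' (donor, hydrogen, acceptor) triple, the fraction of snapshots in
#' which it is present plus the mean geometry over the snapshots where
#' it is present.
#'
#' @param ensemble a `pa_ensemble`.
#' @param bonds a `pa_bonds` (shared topology).
#' @param d_max,theta_min criteria passed to [detect_hbonds()].
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `donor_label`, `acceptor_label`, `occupancy`, `mean_d_da`,
#'   `mean_angle`, `n_present`, `n_snapshots` and `mask` (presence
#'   string, one character per snapshot). Sorted by decreasing
#'   occupancy, ties by labels.
#' @export
hbond_occupancy <- function(ensemble, bonds, d_max = 3.5,
                            theta_min = 120) {
  nsnap <- n_snapshots(ensemble)
  per <- vector("list", nsnap)
  for (k in seq_len(nsnap))
    per[[k]] <- detect_hbonds(get_snapshot(ensemble, k), bonds,
                              d_max = d_max, theta_min = theta_min)
  keys <- unique(do.call(rbind, lapply(per, function(d)
    d[, c("donor", "hydrogen", "acceptor")])))
  if (is.null(keys) || !nrow(keys))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), donor_label = character(),
                      acceptor_label = character(), occupancy = numeric(),
                      mean_d_da = numeric(), mean_angle = numeric(),
                      n_present = integer(), n_snapshots = integer(),
                      mask = character()))
  a <- ensemble$atoms
  lab <- function(i) paste0(a$chain[i], ":", a$resno[i], ":", a$resid[i],
                            ":", a$name[i])
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    d <- keys$donor[r]; h <- keys$hydrogen[r]; ac <- keys$acceptor[r]
    pres <- logical(nsnap); dd <- numeric(0); an <- numeric(0)
    for (k in seq_len(nsnap)) {
      hit <- per[[k]]$donor == d & per[[k]]$hydrogen == h &
        per[[k]]$acceptor == ac
      if (any(hit)) {
        pres[k] <- TRUE
        dd <- c(dd, per[[k]]$d_da[hit][1])
        an <- c(an, per[[k]]$angle[hit][1])
      }
    }
    data.frame(donor = d, hydrogen = h, acceptor = ac,
               donor_label = lab(d), acceptor_label = lab(ac),
               occupancy = mean(pres), mean_d_da = mean(dd),
               mean_angle = mean(an), n_present = sum(pres),
               n_snapshots = nsnap,
               mask = paste(ifelse(pres, "1", "0"), collapse = ""))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$occupancy, tab$donor_label, tab$acceptor_label), ]
  rownames(tab) <- NULL
  tab
}

#' Identify directly contacting residue pairs by penetration energy
#'
#' Residue pairs whose mean charge-penetration energy exceeds a
#' threshold in magnitude are in direct (overlapping-density) contact:
#' Epen is exactly zero for pairs whose atoms never enter the
#' inner/exact region, so a small positive threshold (default 0.1
#' kJ/mol, above quadrature noise) isolates true contacts.
#'
#' @param profile a `pa_profile` from [profile_mean_sd()].
#' @param epen_threshold magnitude threshold, kJ/mol; must be > 0.
#' @return data.frame with columns `row`, `col` (labels), `epen_mean`,
#'   `ees_mean`, sorted by decreasing |epen_mean|, ties by label order.
#' @export
direct_contacts <- function(profile, epen_threshold = 0.1) {
  stopifnot(inherits(profile, "pa_profile"))
  if (epen_threshold <= 0)
    stop("epen_threshold must be > 0 (exact zeros below quadrature ",
         "noise are not meaningful contacts)")
  idx <- which(abs(profile$epen_mean) > epen_threshold, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(row = character(), col = character(),
                      epen_mean = numeric(), ees_mean = numeric()))
  out <- data.frame(row = profile$row_labels[idx[, 1]],
                    col = profile$col_labels[idx[, 2]],
                    epen_mean = profile$epen_mean[idx],
                    ees_mean = profile$ees_mean[idx])
  out <- out[order(-abs(out$epen_mean), out$row, out$col), ]
  rownames(out) <- NULL
  out
}
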