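# Pseudoatom parameter bank: a versioned, human-readable text format
# standing in for transferable multipole databanks. One entry per block:
#
#   FORMAT PABANK 1
#   BANK <name> <version>
#   ENTRY <atom-type key>
#   PC <core population>
#   PV <valence population>
#   KAPPA <kappa> <kappa'>
#   CORE <c> <n> <zeta>        (repeatable; coefficients sum to 1)
#   VALENCE <c> <n> <zeta>     (repeatable)
#   DEF <l> <n> <zeta> <2l+1 populations, m = -l..l>
#   END
#
# Atom-type keys encode element and bonded environment:
# "O|H2" (oxygen bonded to two hydrogens), "N|CH2|p" (3-connected
# nitrogen bonded to C,H,H, planar), "CL|" (isolated chlorine).

#' Load a pseudoatom parameter bank
#'
#' @param path path to a bank file in the PABANK text format.
#' @return object of class `pa_bank`: list with `name`, `version`,
#'   `entries` (named list of entry templates).
#' @export
load_databank <- function(path) {
  if (!file.exists(path)) stop("no such bank file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- lapply(lines, function(s) strsplit(trimws(s), "[[:space:]]+")[[1]])
  nonempty <- which(lengths(toks) > 0)
  if (!length(nonempty)) stop("empty bank file: ", path)
  first <- toks[[nonempty[1]]]
  if (length(first) < 3 || first[1] != "FORMAT" || first[2] != "PABANK")
    stop("bank file must start with a 'FORMAT PABANK <version>' header")
  if (first[3] != "1")
    stop("unknown PABANK format version: ", first[3])

  bank <- list(name = "unnamed", version = "0", entries = list())
  cur <- NULL; curkey <- NULL
  num <- function(x, ln) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("malformed numeric field at line ", ln, ": ",
                       paste(x, collapse = " "))
    v
  }
  flush_entry <- function() {
    if (is.null(cur)) return()
    stop("entry '", curkey, "' not closed with END")
  }
  for (ln in nonempty[-1]) {
    tk <- toks[[ln]]
    kw <- tk[1]
    if (kw == "BANK") {
      bank$name <- if (length(tk) >= 2) tk[2] else "unnamed"
      bank$version <- if (length(tk) >= 3) tk[3] else "0"
    } else if (kw == "ENTRY") {
      if (!is.null(cur)) flush_entry()
      curkey <- tk[2]
      if (curkey %in% names(bank$entries))
        stop("duplicate bank key: ", curkey)
      cur <- list(Pc = 0, Pv = 0, kappa = 1, kappap = 1,
                   core = data.frame(c = numeric(), n = integer(),
                                     zeta = numeric()),
                   valence = data.frame(c = numeric(), n = integer(),
                                        zeta = numeric()),
                   def = list())
    } else if (is.null(cur)) {
      stop("line ", ln, ": '", kw, "' outside an ENTRY block")
    } else if (kw == "PC") {
      cur$Pc <- num(tk[2], ln)
    } else if (kw == "PV") {
      cur$Pv <- num(tk[2], ln)
    } else if (kw == "KAPPA") {
      v <- num(tk[2:3], ln)
      if (any(v <= 0)) stop("line ", ln, ": kappa values must be positive")
      cur$kappa <- v[1]; cur$kappap <- v[2]
    } else if (kw %in% c("CORE", "VALENCE")) {
      v <- num(tk[2:4], ln)
      if (v[3] <= 0) stop("line ", ln, ": Slater exponent must be positive")
      row <- data.frame(c = v[1], n = as.integer(v[2]), zeta = v[3])
      if (kw == "CORE") cur$core <- rbind(cur$core, row)
      else cur$valence <- rbind(cur$valence, row)
    } else if (kw == "DEF") {
      l <- as.integer(num(tk[2], ln))
      v <- num(tk[-(1:2)], ln)
      if (length(v) != 2 + 2 * l + 1)
        stop("line ", ln, ": DEF ", l, " needs n, zeta and ", 2 * l + 1,
             " populations")
      if (v[2] <= 0) stop("line ", ln, ": Slater exponent must be positive")
      cur$def[[length(cur$def) + 1L]] <-
        list(l = l, n = as.integer(v[1]), zeta = v[2], P = v[-(1:2)])
    } else if (kw == "END") {
      # validate by instantiating on a matching-size nucleus
      elem <- sub("\\|.*$", "", curkey)
      Zc <- tryCatch(element_to_Z(elem), error = function(e) NA_integer_)
      if (!is.na(Zc)) {
        tryCatch(
          hansen_atom(Zc, cur$Pc, cur$Pv, cur$kappa, cur$kappap,
                      cur$core, cur$valence, cur$def),
          error = function(e) stop("invalid entry '", curkey, "': ",
                                   conditionMessage(e), call. = FALSE))
      }
      bank$entries[[curkey]] <- cur
      cur <- NULL; curkey <- NULL
    } else {
      stop("line ", ln, ": unknown keyword '", kw, "'")
    }
  }
  if (!is.null(cur)) stop("entry '", curkey, "' not closed with END")
  structure(bank, class = "pa_bank")
}

#' Write a pseudoatom parameter bank
#'
#' Inverse of [load_databank()]; output is deterministic (entries in
#' their stored order, fixed numeric formatting).
#'
#' @param bank a `pa_bank`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_databank <- function(bank, path) {
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.10f", x))
  out <- c("FORMAT PABANK 1",
           paste("BANK", bank$name, bank$version))
  for (key in names(bank$entries)) {
    e <- bank$entries[[key]]
    out <- c(out, paste("ENTRY", key),
             paste("PC", fmt(e$Pc)), paste("PV", fmt(e$Pv)),
             paste("KAPPA", fmt(e$kappa), fmt(e$kappap)))
    for (k in seq_len(nrow(e$core)))
      out <- c(out, paste("CORE", fmt(e$core$c[k]), e$core$n[k],
                          fmt(e$core$zeta[k])))
    for (k in seq_len(nrow(e$valence)))
      out <- c(out, paste("VALENCE", fmt(e$valence$c[k]), e$valence$n[k],
                          fmt(e$valence$zeta[k])))
    for (d in e$def)
      out <- c(out, paste("DEF", d$l, d$n, fmt(d$zeta),
                          paste(fmt(d$P), collapse = " ")))
    out <- c(out, "END")
  }
  writeLines(out, path)
  invisible(path)
}

#' Assign connectivity-based atom types
#'
#' The atom-type key is the canonical text form of (element, multiset of
#' bonded-neighbor elements, planarity for 3-connected atoms):
#' element and alphabetically sorted neighbor elements with counts, e.g.
#' `"C|H3O"`, plus a planarity flag `"p"`/`"np"` for atoms with exactly
#' three neighbors (the atom and its neighbors coplanar within 0.1
#' angstrom by least-squares plane fit). This captures the sp2/sp3
#' distinction that dominates parameter transferability; it does not
#' attempt full local site-symmetry classification.
#'
#' @param snapshot a `pa_snapshot`.
#' @param bonds a `pa_bonds`.
#' @return character vector of atom-type keys, one per atom.
#' @export
assign_atom_types <- function(snapshot, bonds) {
  a <- snapshot$atoms
  n <- nrow(a)
  keys <- character(n)
  for (i in seq_len(n)) {
    nbrs <- bonds$neighbors[[i]]
    if (!length(nbrs) && a$Z[i] > 1)
      warning("isolated heavy atom at index ", i, " (", a$elem[i], ")")
    nbstr <- ""
    if (length(nbrs)) {
      tab <- table(a$elem[nbrs])
      tab <- tab[order(names(tab))]
      nbstr <- paste(mapply(function(el, ct) {
        if (ct > 1) paste0(el, ct) else el
      }, names(tab), as.integer(tab)), collapse = "")
    }
    key <- paste(a$elem[i], nbstr, sep = "|")
    if (length(nbrs) == 3L) {
      pts <- rbind(snapshot$xyz[i, ], snapshot$xyz[nbrs, ])
      key <- paste(key, if (.max_plane_residual(pts) <= 0.1) "p" else "np",
                   sep = "|")
    }
    keys[i] <- key
  }
  keys
}

# largest orthogonal distance of a point set from its least-squares plane
.max_plane_residual <- function(pts) {
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  max(abs(sweep(pts, 2, ctr) %*% s$v[, 3]))
}

# crude neutral spherical stand-in used by the element-spherical
# fallback policy: core-count electrons in a 1s-like shell, the rest in
# a diffuse valence shell
.default_spherical_entry <- function(Z) {
  Pc <- .core_electrons(Z)
  zv <- c(2.4, 3.4, 0.9, 1.4, 2.2, 3.2, 3.8, 4.4, 5.0, 5.6,
          1.0, 1.3, 1.6, 1.9, 2.2, 2.5, 2.8, 3.1)[min(Z, 18L)]
  list(Pc = Pc, Pv = Z - Pc, kappa = 1, kappap = 1,
       core = if (Pc > 0)
         data.frame(c = 1, n = 0L, zeta = 2 * Z) else
           data.frame(c = numeric(), n = integer(), zeta = numeric()),
       valence = data.frame(c = 1, n = if (Z <= 2) 0L else 2L, zeta = zv),
       def = list())
}

#' Transfer bank parameters onto a structure
#'
#' Looks up each atom's connectivity-derived type key in the bank and
#' instantiates a Hansen-Coppens pseudoatom for it, together with its
#' local coordinate frame and the multipole populations rotated into the
#' global frame. With `fallback = "element-spherical"`, atoms whose key
#' is missing from the bank receive a neutral spherical pseudoatom
#' (Pv = Z - Pc, no multipoles) and a warning; with `fallback = "strict"`
#' any missing key is an error listing all unmatched types.
#'
#' @param snapshot a `pa_snapshot`.
#' @param bonds a `pa_bonds`.
#' @param bank a `pa_bank`.
#' @param fallback `"strict"` or `"element-spherical"`.
#' @param charges optional numeric vector of per-atom point charges (e),
#'   for the point-charge reference model.
#' @return object of class `pa_param`: list with `snapshot`, `bonds`,
#'   `types`, `hansen` (list of [hansen_atom()]), `frames`, `plm_global`
#'   (per-atom per-l population lists in the global frame), `charges`,
#'   `unmatched`.
#' @export
transfer_parameters <- function(snapshot, bonds, bank,
                                fallback = c("strict", "element-spherical"),
                                charges = NULL) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(bank, "pa_bank"))
  a <- snapshot$atoms
  types <- assign_atom_types(snapshot, bonds)
  missing_keys <- unique(types[!(types %in% names(bank$entries))])
  if (length(missing_keys) && fallback == "strict")
    stop("unmatched atom type(s): ", paste(missing_keys, collapse = ", "))
  hansen <- vector("list", nrow(a))
  frames <- vector("list", nrow(a))
  plm_global <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    e <- bank$entries[[types[i]]]
    if (is.null(e)) {
      warning("atom ", i, " (", types[i],
              "): element-spherical fallback applied")
      e <- .default_spherical_entry(a$Z[i])
    }
    hansen[[i]] <- hansen_atom(a$Z[i], e$Pc, e$Pv, e$kappa, e$kappap,
                               e$core, e$valence, e$def)
    lmax <- hansen[[i]]$lmax
    plm <- lapply(0:lmax, function(l) numeric(2L * l + 1L))
    for (d in e$def) plm[[d$l + 1L]] <- d$P
    if (any(unlist(plm) != 0)) {
      frames[[i]] <- build_local_frame(i, snapshot, bonds)
      plm_global[[i]] <- rotate_multipoles(plm, frames[[i]]$R)
    } else {
      # spherical atom: orientation is irrelevant, skip frame perception
      frames[[i]] <- list(R = diag(3), definition = list(z = NA, x = NA))
      plm_global[[i]] <- plm
    }
  }
  if (!is.null(charges) && length(charges) != nrow(a))
    stop("charges must have one value per atom")
  structure(list(snapshot = snapshot, bonds = bonds, types = types,
                 hansen = hansen, frames = frames,
                 plm_global = plm_global, charges = charges,
                 unmatched = missing_keys),
            class = "pa_param")
}

#' Net atomic charges of a parametrized structure
#'
#' @param param a `pa_param`.
#' @return numeric vector of q_i = Z_i - Pc_i - Pv_i (e). The l = 0
#'   deformation population, if any, is not included (it is part of the
#'   aspherical description, not of the spherical charge bookkeeping used
#'   for normalization and the point-charge reduction).
#' @export
net_atomic_charges <- function(param) {
  vapply(param$hansen, function(h) h$Z - h$Pc - h$Pv, numeric(1))
}

#' Normalize the total charge of an atom group
#'
#' Transferred banks never sum exactly to the formal charge of a
#' molecule. This applies the conventional uniform valence scaling:
#' Pv_i <- Pv_i * (sum Pv + delta)/(sum Pv), with delta the charge excess,
#' after which sum(Z - Pc - Pv) over the group equals `target` exactly.
#'
#' @param param a `pa_param`.
#' @param group integer atom indices (default: all atoms).
#' @param target target net charge of the group (e).
#' @return the modified `pa_param`.
#' @export
normalize_charge <- function(param, group = NULL, target = 0) {
  stopifnot(inherits(param, "pa_param"))
  if (is.null(group)) group <- seq_along(param$hansen)
  if (!length(group)) stop("empty normalization group")
  pv <- vapply(param$hansen[group], function(h) h$Pv, numeric(1))
  spv <- sum(pv)
  if (spv <= 0) stop("group has no valence population to scale")
  q <- sum(vapply(param$hansen[group],
                  function(h) h$Z - h$Pc - h$Pv, numeric(1)))
  delta <- q - target
  fac <- (spv + delta) / spv
  if (any(pv * fac < 0))
    stop("charge normalization would make a valence population negative")
  for (i in group) param$hansen[[i]]$Pv <- param$hansen[[i]]$Pv * fac
  param
}
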