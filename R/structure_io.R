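#' @importFrom bio3d read.pdb write.pdb
#' @importFrom stats dist
NULL

#' Read a multi-model PDB file into a snapshot ensemble
#'
#' Parses a PDB file with one or more MODEL blocks (a file without MODEL
#' records is treated as a single implicit model) and returns an ensemble:
#' a shared atom table plus one coordinate matrix per snapshot. All models
#' must share the same atoms in the same order (names, residue numbers,
#' residue names and chain ids); a mismatch raises a topology error.
#'
#' Alternate locations are resolved by keeping, per atom, the altloc with
#' the highest occupancy (ties broken by the alphabetically earliest
#' altloc id). Elements are taken from the PDB element column when
#' present, otherwise guessed from the leading letters of the atom name
#' with a warning. Waters and ions are retained; selection helpers exclude
#' them from energy groups by default (see [select_atoms()]).
#'
#' @param path path to a PDB file.
#' @return object of class `pa_ensemble`: list with `atoms` (data.frame:
#'   serial, name, elem, Z, resno, resid, chain, occ), `xyz` (list of
#'   n_atoms x 3 coordinate matrices, angstrom), `conect` (2-column matrix
#'   of bonded serial pairs from CONECT records, possibly empty) and
#'   `source`.
#' @export
read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) != length(ends))
    stop("format error: unbalanced MODEL/ENDMDL records in ", path)
  chunks <- if (length(starts) == 0L) list(lines) else
    Map(function(s, e) lines[(s + 1L):(e - 1L)], starts, ends)

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  models <- lapply(seq_along(chunks), function(k) {
    writeLines(c(chunks[[k]], "END"), tmp)
    pdb <- tryCatch(
      bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE,
                      hex = TRUE, rm.alt = FALSE),
      error = function(e) stop("format error in model ", k, " of ", path,
                               ": ", conditionMessage(e), call. = FALSE))
    .resolve_altloc(pdb$atom)
  })

  ref <- models[[1]]
  sig <- function(a) paste(a$elety, a$resid, a$chain, a$resno, sep = "\r")
  for (k in seq_along(models)) {
    if (nrow(models[[k]]) != nrow(ref) ||
        !identical(sig(models[[k]]), sig(ref)))
      stop("topology mismatch: model ", k, " does not share the atom set ",
           "of model 1 in ", path)
  }

  elem <- .element_from_columns(ref)
  atoms <- data.frame(
    serial = ref$eleno,
    name = ref$elety,
    elem = elem,
    Z = element_to_Z(elem),
    resno = ref$resno,
    resid = ref$resid,
    chain = ifelse(is.na(ref$chain), "", ref$chain),
    occ = ifelse(is.na(ref$o), 1, ref$o),
    stringsAsFactors = FALSE
  )
  xyz <- lapply(models, function(a) {
    m <- cbind(a$x, a$y, a$z)
    if (any(!is.finite(m))) stop("non-finite coordinates in ", path)
    dimnames(m) <- NULL
    m
  })
  conect <- .parse_conect(lines)
  structure(list(atoms = atoms, xyz = xyz, conect = conect, source = path),
            class = "pa_ensemble")
}

# keep highest-occupancy altloc per (chain, resno, resid, name);
# ties -> earliest altloc id
.resolve_altloc <- function(a) {
  alt <- ifelse(is.na(a$alt), "", a$alt)
  if (all(alt == "")) return(a)
  key <- paste(a$chain, a$resno, a$resid, a$elety, sep = "\r")
  occ <- ifelse(is.na(a$o), 1, a$o)
  ord <- order(key, -occ, alt)
  keep <- !duplicated(key[ord])
  a[sort(ord[keep]), , drop = FALSE]
}

.element_from_columns <- function(a) {
  elem <- toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy)))
  miss <- elem == "" | is.na(match(elem, .ELEMENTS$symbol))
  if (any(miss)) {
    guess <- toupper(gsub("[^A-Za-z].*$", "", trimws(a$elety[miss])))
    # two-letter symbols only when the name matches one (CL, NA, BR, ...)
    guess <- ifelse(substr(guess, 1, 2) %in% .ELEMENTS$symbol,
                    substr(guess, 1, 2), substr(guess, 1, 1))
    warning("element column missing/unknown for ", sum(miss),
            " atom(s); guessed from atom names")
    elem[miss] <- guess
  }
  elem
}

.parse_conect <- function(lines) {
  cl <- grep("^CONECT", lines, value = TRUE)
  if (!length(cl)) return(matrix(integer(), ncol = 2))
  out <- list()
  for (s in cl) {
    f <- suppressWarnings(as.integer(substring(
      s, c(7, 12, 17, 22, 27), c(11, 16, 21, 26, 31))))
    f <- f[!is.na(f)]
    if (length(f) >= 2)
      out[[length(out) + 1L]] <- cbind(f[1], f[-1])
  }
  e <- do.call(rbind, out)
  t(apply(e, 1, sort))
}

#' Extract one snapshot from an ensemble
#'
#' @param ensemble a `pa_ensemble`.
#' @param model 1-based model index.
#' @return object of class `pa_snapshot`: list with `atoms` and `xyz`
#'   (n x 3 matrix, angstrom).
#' @export
get_snapshot <- function(ensemble, model = 1L) {
  stopifnot(inherits(ensemble, "pa_ensemble"),
            model >= 1L, model <= length(ensemble$xyz))
  structure(list(atoms = ensemble$atoms, xyz = ensemble$xyz[[model]],
                 model = as.integer(model)),
            class = "pa_snapshot")
}

#' Number of snapshots in an ensemble
#' @param ensemble a `pa_ensemble`.
#' @return integer count.
#' @export
n_snapshots <- function(ensemble) length(ensemble$xyz)

#' Build an ensemble from a snapshot and coordinate list
#'
#' @param atoms atom table as in [read_pdb_models()] (columns serial,
#'   name, elem, resno, resid, chain at minimum; Z and occ filled if
#'   missing).
#' @param xyz list of n x 3 coordinate matrices (angstrom).
#' @param source provenance string.
#' @return a `pa_ensemble`.
#' @export
make_ensemble_object <- function(atoms, xyz, source = "in-memory") {
  if (!length(xyz)) stop("empty ensemble")
  if (is.null(atoms$Z)) atoms$Z <- element_to_Z(atoms$elem)
  if (is.null(atoms$occ)) atoms$occ <- 1
  for (m in xyz) {
    if (!is.matrix(m) || nrow(m) != nrow(atoms) || ncol(m) != 3)
      stop("each xyz entry must be an n_atoms x 3 matrix")
  }
  structure(list(atoms = atoms, xyz = lapply(xyz, function(m) {
    dimnames(m) <- NULL
    m
  }), conect = matrix(integer(), ncol = 2), source = source),
  class = "pa_ensemble")
}

#' Write an ensemble to a multi-model PDB file
#'
#' Coordinates are written in the fixed PDB columns (3 decimal places); a
#' read-back therefore reproduces coordinates to 1e-3 angstrom and all
#' atom/residue identifiers exactly.
#'
#' @param ensemble a `pa_ensemble`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb_models <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "pa_ensemble"))
  if (!length(ensemble$xyz)) stop("refusing to write an empty ensemble")
  a <- ensemble$atoms
  xyz <- do.call(rbind, lapply(ensemble$xyz, function(m) as.numeric(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   eleno = a$serial, elety = a$name, resid = a$resid,
                   chain = a$chain, resno = a$resno, o = a$occ,
                   b = rep(0, nrow(a)), elesy = a$elem, end = TRUE)
  invisible(path)
}

#' Infer covalent connectivity from interatomic distances
#'
#' Bonds atom pairs whose distance does not exceed the sum of their
#' covalent radii plus a tolerance. CONECT-record bonds carried by the
#' ensemble the snapshot came from can be merged in via `extra`.
#' Hydrogens with zero or more than one neighbor are reported in the
#' `diagnostics` attribute and trigger a warning.
#'
#' @param snapshot a `pa_snapshot`.
#' @param tolerance distance slack in angstrom (default 0.4).
#' @param extra optional 2-column matrix of additional bonded pairs given
#'   as PDB serial numbers (e.g. the `conect` field of an ensemble).
#' @return object of class `pa_bonds`: list with `edges` (2-column matrix
#'   of 1-based atom indices, i < j), `neighbors` (list of integer
#'   vectors) and attribute `diagnostics`.
#' @export
infer_connectivity <- function(snapshot, tolerance = 0.4, extra = NULL) {
  stopifnot(inherits(snapshot, "pa_snapshot"))
  a <- snapshot$atoms
  n <- nrow(a)
  rc <- covalent_radius(a$elem)
  d <- as.matrix(stats::dist(snapshot$xyz))
  thr <- outer(rc, rc, "+") + tolerance
  adj <- d <= thr
  diag(adj) <- FALSE
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- unname(cbind(edges[, 1], edges[, 2]))
  if (!is.null(extra) && nrow(extra)) {
    idx <- cbind(match(extra[, 1], a$serial), match(extra[, 2], a$serial))
    if (anyNA(idx)) stop("CONECT serial not present in atom table")
    idx <- t(apply(idx, 1, sort))
    edges <- unique(rbind(edges, idx))
  }
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  neighbors <- rep(list(integer()), n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    neighbors[[i]] <- c(neighbors[[i]], j)
    neighbors[[j]] <- c(neighbors[[j]], i)
  }
  deg <- lengths(neighbors)
  badH <- which(a$elem == "H" & deg != 1L)
  diag_rec <- list(hydrogen_valence = badH)
  if (length(badH))
    warning("hydrogen(s) with ", paste(unique(deg[badH]), collapse = "/"),
            " neighbors at atom index: ", paste(badH, collapse = ", "))
  structure(list(edges = edges, neighbors = neighbors),
            class = "pa_bonds", diagnostics = diag_rec)
}

#' @export
print.pa_ensemble <- function(x, ...) {
  cat("pseudoatom ensemble:", length(x$xyz), "snapshot(s),",
      nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  cat("source:", x$source, "\n")
  invisible(x)
}
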