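# Atom-group selection mini-language: the smallest expressive form
# covering ligand-vs-chain and chain-vs-chain groupings:
#   "A"          all atoms of chain A
#   "B:25-30"    chain B, residues 25..30 (comma-separated ranges OK)
#   "LIG"        all residues named LIG (when no chain matches)
# Waters and monatomic ions are excluded from bare-chain selections by
# default (structures keep them on read); selecting a residue number or
# a residue name explicitly always includes it.

.SOLVENT_RESNAMES <- c("HOH", "WAT", "TIP3", "SOL", "DOD",
                       "NA", "CL", "K", "MG", "CA", "ZN",
                       "SOD", "CLA", "POT")

#' Select atoms by chain/residue expression
#'
#' @param snapshot a `pa_snapshot` or `pa_ensemble` (the shared atom
#'   table is used).
#' @param expr character vector of selection expressions (results are
#'   united).
#' @param keep_solvent include water/ion residues in bare-chain
#'   selections (default FALSE).
#' @return sorted integer vector of 1-based atom indices.
#' @export
select_atoms <- function(snapshot, expr, keep_solvent = FALSE) {
  a <- snapshot$atoms
  hit <- logical(nrow(a))
  for (e in expr) {
    e <- trimws(e)
    if (grepl(":", e, fixed = TRUE)) {
      parts <- strsplit(e, ":", fixed = TRUE)[[1]]
      ch <- parts[1]
      resnos <- unlist(lapply(strsplit(parts[2], ",")[[1]], function(rg) {
        b <- as.integer(strsplit(rg, "-")[[1]])
        if (anyNA(b)) stop("bad residue range in selection: ", e)
        if (length(b) == 2L) seq(b[1], b[2]) else b
      }))
      hit <- hit | (a$chain == ch & a$resno %in% resnos)
    } else if (e %in% a$chain) {
      sel <- a$chain == e
      if (!keep_solvent)
        sel <- sel & !(toupper(a$resid) %in% .SOLVENT_RESNAMES)
      hit <- hit | sel
    } else if (e %in% a$resid) {
      hit <- hit | a$resid == e
    } else {
      stop("selection '", e, "' matches no chain or residue name")
    }
  }
  which(hit)
}
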