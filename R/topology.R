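#' System topology
#'
#' Per-particle records of a simulated system: particle (atom/bead) names,
#' residue names and 1-based residue ids, plus a map from each lipid residue
#' to its single phosphate particle. Leaflet assignment and the flip-flop
#' collective variable are defined on phosphate positions, so the phosphate
#' map is the central piece of bookkeeping.
#'
#' Phosphates are recognised by particle name: "PO4" (coarse-grained beads)
#' or "P" (atomistic phosphorus).
#'
#' @param name character vector of particle names
#' @param resname character vector of residue names
#' @param resid integer vector of 1-based residue ids
#' @return an object of class "sk_topology" with fields `name`, `resname`,
#'   `resid`, `n` (particle count) and `phosphate_map` (named integer vector:
#'   lipid residue id -> 1-based particle index of its phosphate)
#' @export
system_topology <- function(name, resname, resid) {
  n <- length(name)
  if (length(resname) != n || length(resid) != n) {
    stop("name, resname and resid must have equal length")
  }
  resid <- as.integer(resid)
  if (anyNA(resid)) stop("residue ids must be integers")
  top <- structure(
    list(name = as.character(name), resname = as.character(resname),
         resid = resid, n = n),
    class = "sk_topology"
  )
  top$phosphate_map <- build_phosphate_map(top)
  top
}

# One phosphate per lipid residue; residues without any phosphate particle
# (water, protein, ions) are simply absent from the map.
build_phosphate_map <- function(top) {
  is_p <- top$name %in% c("PO4", "P")
  idx <- which(is_p)
  if (length(idx) == 0L) return(integer(0))
  rid <- top$resid[idx]
  if (anyDuplicated(rid)) {
    dup <- unique(rid[duplicated(rid)])
    stop("residue(s) ", paste(dup, collapse = ", "),
         " carry more than one phosphate particle; expected exactly one per lipid")
  }
  stats::setNames(idx, rid)
}

#' @export
print.sk_topology <- function(x, ...) {
  cat("<sk_topology> ", x$n, " particles, ",
      length(unique(x$resid)), " residues, ",
      length(x$phosphate_map), " lipid phosphates\n", sep = "")
  invisible(x)
}

#' Number of particles in a topology
#' @param top an sk_topology
#' @return integer particle count
#' @export
n_particles <- function(top) top$n
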