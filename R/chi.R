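# Chi dihedral definitions and side-chain torsion extraction.

.rotbh_env <- new.env(parent = emptyenv())

#' Canonical chi dihedral definitions
#'
#' Returns the table of heavy-atom chi dihedral definitions shipped with
#' the package: one row per chi, giving the residue three-letter code,
#' the chi index (1-4) and the four atom names.  The three histidine
#' protonation states (HID, HIE, HIP) share one chi topology.
#'
#' @return A data frame with columns `resid`, `chi`, `a1`..`a4`.
#' @export
chi_definitions <- function() {
  if (is.null(.rotbh_env$chi_defs)) {
    path <- system.file("extdata", "chi_definitions.tsv", package = "rotbh")
    .rotbh_env$chi_defs <- utils::read.table(path, header = TRUE, sep = "\t",
                                             comment.char = "#",
                                             stringsAsFactors = FALSE)
  }
  .rotbh_env$chi_defs
}

#' Number of chi dihedrals of a residue type
#'
#' @param resid Residue three-letter code (e.g. "SER").  Generic "HIS"
#'   resolves to the delta-protonated topology.
#' @return Integer chi count; 0 for residues without chi dihedrals
#'   (e.g. ALA, GLY) or unknown codes.
#' @export
sidechain_chi_count <- function(resid) {
  defs <- chi_definitions()
  vapply(toupper(resid), function(r) sum(defs$resid == r), integer(1L),
         USE.NAMES = FALSE)
}

#' A single conformation: coordinates plus atom naming
#'
#' Light container pairing a coordinate matrix with the residue/atom
#' naming needed to locate chi dihedrals.
#'
#' @param xyz Coordinate matrix (n_atoms x 3), Angstrom.
#' @param atoms Data frame with columns `resno` (residue number),
#'   `resid` (three-letter code) and `elety` (atom name).
#' @return An object of class `"conformation"`.
#' @export
conformation <- function(xyz, atoms) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == nrow(atoms),
            all(c("resno", "resid", "elety") %in% names(atoms)))
  structure(list(xyz = xyz, atoms = atoms), class = "conformation")
}

#' Extract side-chain chi dihedrals of one residue
#'
#' Computes the chi angles of the residue in canonical order (chi1,
#' chi2, ...) from Cartesian coordinates, using the canonical heavy-atom
#' quadruples.  Residues without chi dihedrals (alanine, glycine) are an
#' error, as are missing atoms.
#'
#' @param conf A [conformation()] object.
#' @param residue Residue number (`resno`) to extract.
#' @return Numeric vector of chi angles in degrees, (-180, 180].
#' @export
extract_sidechain_torsions <- function(conf, residue) {
  stopifnot(inherits(conf, "conformation"))
  at <- conf$atoms
  sel <- at$resno == residue
  if (!any(sel)) stop("no atoms for residue number ", residue)
  resid <- toupper(unique(at$resid[sel]))
  if (length(resid) != 1L)
    stop("residue ", residue, " has inconsistent residue names")
  defs <- chi_definitions()
  cd <- defs[defs$resid == resid, , drop = FALSE]
  if (nrow(cd) == 0L)
    stop("residue ", resid, " ", residue,
         " has no chi dihedrals (side chain too simple or unknown type)")
  cd <- cd[order(cd$chi), , drop = FALSE]
  idx_of <- function(name) {
    i <- which(sel & at$elety == name)
    if (length(i) != 1L)
      stop("residue ", resid, " ", residue, ": atom ", name,
           if (length(i) == 0L) " missing" else " duplicated")
    i
  }
  vapply(seq_len(nrow(cd)), function(r) {
    q <- vapply(c(cd$a1[r], cd$a2[r], cd$a3[r], cd$a4[r]), idx_of, integer(1L))
    dihedral_angle(conf$xyz[q[1L], ], conf$xyz[q[2L], ],
                   conf$xyz[q[3L], ], conf$xyz[q[4L], ])
  }, numeric(1L))
}

#' Build an idealized side-chain fragment for a residue type
#'
#' Constructs synthetic Cartesian coordinates for the atoms appearing in
#' a residue's chi definitions, chained with ideal bond lengths and
#' tetrahedral-like angles, with each chi dihedral set to a requested
#' value.  Intended for generating test fixtures and synthetic PDB
#' ensembles; the geometry is idealized, not force-field optimized.
#'
#' @param resid Residue three-letter code with at least one chi.
#' @param chi Numeric vector of chi angles in degrees (one per chi of
#'   the residue type).
#' @param resno Residue number to assign.
#' @param bond Bond length used for all placed bonds (Angstrom).
#' @param angle Bond angle used for all placements (degrees).
#' @return A [conformation()] object containing the fragment.
#' @export
build_sidechain_fragment <- function(resid, chi, resno = 1L,
                                     bond = 1.53, angle = 111) {
  resid <- toupper(resid)
  defs <- chi_definitions()
  cd <- defs[defs$resid == resid, , drop = FALSE]
  if (nrow(cd) == 0L) stop("residue type ", resid, " has no chi dihedrals")
  cd <- cd[order(cd$chi), , drop = FALSE]
  if (length(chi) != nrow(cd))
    stop(resid, " has ", nrow(cd), " chi dihedrals, got ", length(chi))
  # atom chain: the four atoms of chi1, then the last atom of each
  # following chi (consecutive quadruples overlap in three atoms)
  names_chain <- c(cd$a1[1L], cd$a2[1L], cd$a3[1L], cd$a4[1L])
  if (nrow(cd) > 1L) names_chain <- c(names_chain, cd$a4[-1L])
  n <- length(names_chain)
  xyz <- matrix(0, n, 3L)
  ang <- angle * pi / 180
  xyz[2L, ] <- c(bond, 0, 0)
  xyz[3L, ] <- xyz[2L, ] + bond * c(-cos(ang), sin(ang), 0)
  for (i in 4L:n)
    xyz[i, ] <- place_atom(xyz[i - 3L, ], xyz[i - 2L, ], xyz[i - 1L, ],
                           bond, angle, chi[i - 3L])
  conformation(xyz, data.frame(resno = resno, resid = resid,
                               elety = names_chain,
                               stringsAsFactors = FALSE))
}
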