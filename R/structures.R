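# Structure ingestion and contact geometry: which of the 9 peptide
# positions touch the TCR/antibody, via hydrophobic (van der Waals) contact
# or hydrogen bond.

#' Bondi-style van der Waals radii
#'
#' Element-to-radius table (Angstrom) used for hydrophobic-contact and
#' clash detection. Override entries via the \code{vdwRadii} field of
#' [geometryConfig()] if a different radius set is preferred; contact calls
#' are sensitive to it.
#'
#' @return Named numeric vector, element symbol to radius in Angstrom.
#' @export
bondiRadii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

#' Geometry thresholds for contact analysis
#'
#' \itemize{
#'   \item \code{vdwGapMin}, \code{vdwGapMax}: a hydrophobic contact exists
#'     when the signed surface gap d - r1 - r2 lies in
#'     [\code{vdwGapMin}, \code{vdwGapMax}] Angstrom (defaults 0.0-0.4,
#'     bounds inclusive).
#'   \item \code{hbondDaMax}: donor-acceptor distance must be strictly
#'     below this (default 4.0 Angstrom).
#'   \item \code{hbondAngleDevMax}: when explicit hydrogens are present,
#'     the donor-H-acceptor geometry must deviate from linearity by at most
#'     this many degrees (default 30, i.e. angle >= 150 degrees). A literal
#'     D-H-A angle below 30 degrees is geometrically impossible for a
#'     hydrogen bond, so the criterion is interpreted as
#'     deviation-from-linearity. Without hydrogens the distance criterion
#'     alone applies (crystal structures usually lack hydrogens and we do
#'     not invent their placement).
#'   \item \code{clashOverlap}: two atoms from different chains clash when
#'     their radii overlap by strictly more than this (default 0.6
#'     Angstrom).
#'   \item \code{vdwRadii}: element radius table, see [bondiRadii()].
#' }
#'
#' @param vdwGapMin,vdwGapMax,hbondDaMax,hbondAngleDevMax,clashOverlap
#'   Numeric thresholds as described above.
#' @param vdwRadii Named numeric vector of element radii.
#' @return A list of class \code{GeometryConfig}.
#' @export
geometryConfig <- function(vdwGapMin = 0.0, vdwGapMax = 0.4,
                           hbondDaMax = 4.0, hbondAngleDevMax = 30,
                           clashOverlap = 0.6, vdwRadii = bondiRadii()) {
  stopifnot(vdwGapMin <= vdwGapMax, hbondDaMax > 0, hbondAngleDevMax >= 0,
            clashOverlap >= 0, is.numeric(vdwRadii), !is.null(names(vdwRadii)))
  structure(list(vdwGapMin = vdwGapMin, vdwGapMax = vdwGapMax,
                 hbondDaMax = hbondDaMax, hbondAngleDevMax = hbondAngleDevMax,
                 clashOverlap = clashOverlap, vdwRadii = vdwRadii),
            class = "GeometryConfig")
}

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.elementFromName <- function(name) {
  # strip digits/primes, take the leading letter(s); two-letter elements we
  # care about (CL, BR, SE) keep both letters
  n <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(n, 1, 2)
  ifelse(two %in% c("CL", "BR", "SE"), two, substr(n, 1, 1))
}

#' Construct a ComplexStructure from an atom table
#'
#' @param atoms \code{data.frame} with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{atom}, \code{element}, \code{x}, \code{y},
#'   \code{z}.
#' @param structureId Identifier string.
#' @param peptideChain,hlaChains,partnerChains Chain role assignment.
#' @return A \linkS4class{ComplexStructure}.
#' @export
ComplexStructure <- function(atoms, structureId, peptideChain,
                             hlaChains = character(0), partnerChains) {
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  new("ComplexStructure", structureId = as.character(structureId),
      atoms = as.data.frame(atoms), peptideChain = as.character(peptideChain),
      hlaChains = as.character(hlaChains),
      partnerChains = as.character(partnerChains))
}

#' Parse a PDB or mmCIF structure into a ComplexStructure
#'
#' Reads ATOM/HETATM records (via bio3d) and assigns chain roles. If
#' \code{peptideChain} is not given, the unique chain with exactly 9
#' residues is auto-detected as the peptide (an error is raised when
#' several chains qualify). If HLA/partner roles are not given and exactly
#' two other chains remain, the chain with more residues is taken as the
#' HLA (class I heavy chains are far longer than a toy or single-domain
#' partner) with a message; otherwise the roles must be supplied, e.g. from
#' a chain manifest ([readChainManifest()]).
#'
#' @param file Path to a \code{.pdb} or \code{.cif} file.
#' @param structureId Identifier; defaults to the file base name.
#' @param peptideChain,hlaChains,partnerChains Optional chain roles.
#' @return A \linkS4class{ComplexStructure}.
#' @export
parseStructure <- function(file, structureId = NULL, peptideChain = NULL,
                           hlaChains = NULL, partnerChains = NULL) {
  if (is.null(structureId))
    structureId <- sub("\\.[^.]+$", "", basename(file))
  pdb <- if (grepl("\\.(cif|mmcif)$", file, ignore.case = TRUE))
    bio3d::read.cif(file) else bio3d::read.pdb(file)
  a <- pdb$atom
  element <- a$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  element[blank] <- .elementFromName(a$elety[blank])
  element <- toupper(trimws(element))
  if (any(!nzchar(element)))
    stop("could not resolve element for atom(s): ",
         paste(utils::head(a$elety[!nzchar(element)], 5L), collapse = ", "),
         call. = FALSE)
  atoms <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                      atom = a$elety, element = element,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)

  chains <- unique(atoms$chain)
  nres <- vapply(chains, function(ch)
    length(unique(atoms$resno[atoms$chain == ch])), integer(1))
  if (is.null(peptideChain)) {
    nine <- chains[nres == 9L]
    if (length(nine) == 0L)
      stop(sprintf("structure '%s': no 9-residue chain found", structureId),
           call. = FALSE)
    if (length(nine) > 1L)
      stop(sprintf("structure '%s': ambiguous peptide chain (%s all have 9 residues); supply a chain manifest",
                   structureId, paste(nine, collapse = ", ")), call. = FALSE)
    peptideChain <- nine
  } else if (nres[match(peptideChain, chains)] != 9L) {
    stop(sprintf("structure '%s': peptide chain '%s' has %d residues, not 9",
                 structureId, peptideChain,
                 nres[match(peptideChain, chains)]), call. = FALSE)
  }
  if (is.null(partnerChains)) {
    others <- setdiff(chains, c(peptideChain, hlaChains))
    if (length(others) == 1L) {
      partnerChains <- others
      if (is.null(hlaChains)) hlaChains <- character(0)
    } else if (is.null(hlaChains) && length(others) == 2L) {
      o <- others[order(-nres[match(others, chains)])]
      hlaChains <- o[1]
      partnerChains <- o[2]
      message(sprintf(
        "structure '%s': no chain manifest; assuming HLA = '%s' (larger), partner = '%s'",
        structureId, hlaChains, partnerChains))
    } else {
      stop(sprintf("structure '%s': cannot infer chain roles; supply hlaChains/partnerChains",
                   structureId), call. = FALSE)
    }
  }
  if (is.null(hlaChains)) hlaChains <- character(0)
  ComplexStructure(atoms, structureId, peptideChain, hlaChains, partnerChains)
}

#' Read a chain-role manifest
#'
#' TSV with columns \code{structure_id}, \code{peptide_chain},
#' \code{hla_chains}, \code{partner_chains} (multi-chain fields
#' comma-joined).
#'
#' @param path Path to the TSV.
#' @return \code{data.frame} with list columns resolved to character
#'   vectors on use.
#' @export
readChainManifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("structure_id", "peptide_chain", "hla_chains", "partner_chains")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    stop("chain manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m
}

# residue-number -> position 1..9 map for the peptide chain
.peptidePositions <- function(struct) {
  pep <- struct@atoms[struct@atoms$chain == struct@peptideChain, ]
  sort(unique(pep$resno))
}

.radiiFor <- function(element, cfg) {
  r <- cfg$vdwRadii[element]
  if (any(is.na(r)))
    stop("no vdW radius configured for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "), call. = FALSE)
  unname(r)
}

.crossDist <- function(a, b) {
  # pairwise distances between two xyz matrices
  sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
}

#' Peptide positions in hydrophobic contact with the partner
#'
#' Position i is in hydrophobic contact when any side-chain atom of peptide
#' residue i (backbone N, CA, C, O and OXT excluded) lies at a van der
#' Waals surface gap d - r1 - r2 within
#' [\code{vdwGapMin}, \code{vdwGapMax}] of any atom in a partner
#' (TCR/antibody) chain. HLA-chain atoms never count as partners.
#'
#' @param struct A \linkS4class{ComplexStructure}.
#' @param cfg A [geometryConfig()].
#' @return Sorted integer vector, subset of 1..9.
#' @export
hydrophobicContactPositions <- function(struct, cfg = geometryConfig()) {
  atoms <- struct@atoms
  pep <- atoms[atoms$chain == struct@peptideChain &
                 !(atoms$atom %in% .BACKBONE_ATOMS), , drop = FALSE]
  par <- atoms[atoms$chain %in% struct@partnerChains, , drop = FALSE]
  if (nrow(pep) == 0L || nrow(par) == 0L) return(integer(0))
  resmap <- .peptidePositions(struct)
  d <- .crossDist(as.matrix(pep[, c("x", "y", "z")]),
                  as.matrix(par[, c("x", "y", "z")]))
  gap <- d - outer(.radiiFor(pep$element, cfg), .radiiFor(par$element, cfg), "+")
  # 1e-9 guard so distances landing exactly on a configured bound are not
  # decided by floating-point representation
  hit <- gap >= cfg$vdwGapMin - 1e-9 & gap <= cfg$vdwGapMax + 1e-9
  pos <- match(pep$resno[rowSums(hit) > 0], resmap)
  sort(unique(pos))
}

#' Peptide positions hydrogen-bonded to the partner
#'
#' Donors and acceptors are N/O atoms. Position i is included when a
#' donor-acceptor pair between peptide residue i and a partner chain has
#' D-A distance strictly below \code{hbondDaMax}. When the structure
#' carries no explicit hydrogens (the usual case for crystal structures)
#' the distance criterion alone decides. When explicit hydrogens are
#' present, only atoms with an attached hydrogen can donate, and some
#' attached hydrogen must keep the D-H-A geometry within
#' \code{hbondAngleDevMax} degrees of linearity; donors are tried on both
#' sides of the interface.
#'
#' @inheritParams hydrophobicContactPositions
#' @return Sorted integer vector, subset of 1..9.
#' @export
hydrogenBondPositions <- function(struct, cfg = geometryConfig()) {
  atoms <- struct@atoms
  pep <- atoms[atoms$chain == struct@peptideChain &
                 atoms$element %in% c("N", "O"), , drop = FALSE]
  par <- atoms[atoms$chain %in% struct@partnerChains &
                 atoms$element %in% c("N", "O"), , drop = FALSE]
  if (nrow(pep) == 0L || nrow(par) == 0L) return(integer(0))
  resmap <- .peptidePositions(struct)
  hall <- atoms[atoms$element == "H", , drop = FALSE]
  hasH <- nrow(hall) > 0L

  attachedH <- function(row) {
    h <- hall[hall$chain == row$chain, , drop = FALSE]
    if (nrow(h) == 0L) return(h)
    dx <- sqrt((h$x - row$x)^2 + (h$y - row$y)^2 + (h$z - row$z)^2)
    h[dx < 1.3, , drop = FALSE]
  }
  devFromLinear <- function(D, H, A) {
    v1 <- D - H; v2 <- A - H
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }
  donates <- function(donor, acceptor) {
    hs <- attachedH(donor)
    if (nrow(hs) == 0L) return(FALSE)  # no attached H: cannot donate
    D <- c(donor$x, donor$y, donor$z)
    A <- c(acceptor$x, acceptor$y, acceptor$z)
    for (k in seq_len(nrow(hs))) {
      H <- c(hs$x[k], hs$y[k], hs$z[k])
      if (devFromLinear(D, H, A) <= cfg$hbondAngleDevMax) return(TRUE)
    }
    FALSE
  }

  d <- .crossDist(as.matrix(pep[, c("x", "y", "z")]),
                  as.matrix(par[, c("x", "y", "z")]))
  close <- which(d < cfg$hbondDaMax - 1e-9, arr.ind = TRUE)
  pos <- integer(0)
  for (r in seq_len(nrow(close))) {
    pa <- pep[close[r, 1], , drop = FALSE]
    pb <- par[close[r, 2], , drop = FALSE]
    ok <- if (!hasH) TRUE else donates(pa, pb) || donates(pb, pa)
    if (ok) pos <- c(pos, match(pa$resno, resmap))
  }
  sort(unique(pos))
}

#' Contact pattern of one structure
#'
#' The 9-element boolean importance vector: position i is important iff it
#' makes a hydrophobic contact or a hydrogen bond with the TCR/antibody.
#' Deterministic given geometry and configuration, and invariant to atom
#' ordering and rigid motions of the whole structure.
#'
#' @inheritParams hydrophobicContactPositions
#' @return Named logical vector of length 9 (\code{P1}..\code{P9}) with
#'   attribute \code{structureId}.
#' @export
contactPattern <- function(struct, cfg = geometryConfig()) {
  imp <- union(hydrophobicContactPositions(struct, cfg),
               hydrogenBondPositions(struct, cfg))
  v <- seq_len(9L) %in% imp
  names(v) <- paste0("P", 1:9)
  attr(v, "structureId") <- struct@structureId
  v
}

#' Detect steric clashes between chains
#'
#' TRUE when any pair of atoms from different chains overlaps by strictly
#' more than \code{clashOverlap} Angstrom, i.e.
#' d < r1 + r2 - \code{clashOverlap}. Used to discard badly modeled
#' structures.
#'
#' @inheritParams hydrophobicContactPositions
#' @return Single logical.
#' @export
detectClashes <- function(struct, cfg = geometryConfig()) {
  atoms <- struct@atoms
  chains <- unique(atoms$chain)
  if (length(chains) < 2L) return(FALSE)
  for (i in seq_len(length(chains) - 1L)) {
    a <- atoms[atoms$chain == chains[i], , drop = FALSE]
    ra <- .radiiFor(a$element, cfg)
    for (j in seq.int(i + 1L, length(chains))) {
      b <- atoms[atoms$chain == chains[j], , drop = FALSE]
      rb <- .radiiFor(b$element, cfg)
      d <- .crossDist(as.matrix(a[, c("x", "y", "z")]),
                      as.matrix(b[, c("x", "y", "z")]))
      overlap <- outer(ra, rb, "+") - d
      if (any(overlap > cfg$clashOverlap + 1e-9)) return(TRUE)
    }
  }
  FALSE
}

#' Write a ComplexStructure as a minimal PDB file
#'
#' Single-model ATOM records (fixed-width PDB dialect) with element
#' symbols; chains separated by TER. Round-trips through
#' [parseStructure()].
#'
#' @param struct A \linkS4class{ComplexStructure}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeStructurePDB <- function(struct, path) {
  a <- struct@atoms
  lines <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      el <- sub$element[i]
      nm <- sub$atom[i]
      namefield <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, namefield, sub$resid[i], ch, sub$resno[i],
        sub$x[i], sub$y[i], sub$z[i], 1.0, 0.0, el))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
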