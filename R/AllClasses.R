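#' @import methods
NULL

## ---------------------------------------------------------------------------
## StructureModel
## ---------------------------------------------------------------------------

#' Atomic model container
#'
#' Holds an atomic model as a flat atom table plus optional crystal frame
#' (cell and space group).  The unit for homologue templates, polyalanine
#' fragments and simulated ground-truth structures.
#'
#' @slot atoms data.frame with columns `element`, `name`, `resno` (integer),
#'   `resname`, `chain`, `ins` (insertion code, "" when none), `x`, `y`, `z`
#'   (Cartesian angstroms), `occ` (occupancy in `[0,1]`) and `b`
#'   (isotropic B factor, square angstroms).
#' @slot cell numeric length-6 `(a,b,c,alpha,beta,gamma)` or length-0 when
#'   the model has no crystal frame.
#' @slot spacegroup Hermann-Mauguin symbol, or `NA_character_`.
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", cell = "numeric",
                 spacegroup = "character"),
  prototype(atoms = data.frame(), cell = numeric(0),
            spacegroup = NA_character_)
)

.atomCols <- c("element", "name", "resno", "resname", "chain", "ins",
               "x", "y", "z", "occ", "b")

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msgs <- character(0)
  if (nrow(a)) {
    miss <- setdiff(.atomCols, names(a))
    if (length(miss)) {
      return(paste("atoms table missing columns:", paste(miss, collapse = ", ")))
    }
    if (!all(is.finite(as.matrix(a[, c("x", "y", "z")])))) {
      msgs <- c(msgs, "non-finite atom coordinates")
    }
    if (any(a$occ < 0 | a$occ > 1)) msgs <- c(msgs, "occupancies outside [0,1]")
    if (any(a$b < 0)) msgs <- c(msgs, "negative B factors")
    for (ch in unique(a$chain)) {
      rn <- a$resno[a$chain == ch]
      runs <- rle(rn)$values
      if (any(diff(runs) <= 0)) {
        msgs <- c(msgs, sprintf("residue numbers not strictly increasing in chain '%s'", ch))
        break
      }
    }
  }
  if (length(object@cell) && length(object@cell) != 6) {
    msgs <- c(msgs, "cell must have length 0 or 6")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a StructureModel
#'
#' @param atoms atom data.frame (see \linkS4class{StructureModel}); missing
#'   `ins`, `occ`, `b` columns are filled with defaults.
#' @param cell optional cell parameters.
#' @param spacegroup optional space-group symbol.
#' @return a \linkS4class{StructureModel}.
#' @export
StructureModel <- function(atoms, cell = numeric(0), spacegroup = NA_character_) {
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 10
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms[, .atomCols],
      cell = as.numeric(cell), spacegroup = spacegroup)
}

## ---------------------------------------------------------------------------
## ReflectionSet
## ---------------------------------------------------------------------------

#' Reflection data container
#'
#' One row per symmetry-unique reflection (Friedel pairs merged), carrying
#' whatever columns a stage has produced: `I`, `sigI`, `F`, `phase`
#' (degrees), `E`, plus the always-present `h`, `k`, `l`, `d`, `centric`,
#' `epsilon`.
#'
#' @slot cell numeric length-6 cell parameters.
#' @slot spacegroup Hermann-Mauguin symbol.
#' @slot dmin,dmax resolution limits in angstroms.
#' @slot records data.frame of reflection records.
#' @export
setClass("ReflectionSet",
  representation(cell = "numeric", spacegroup = "character",
                 dmin = "numeric", dmax = "numeric", records = "data.frame")
)

setValidity("ReflectionSet", function(object) {
  r <- object@records
  msgs <- character(0)
  if (length(object@cell) != 6) msgs <- c(msgs, "cell must have length 6")
  need <- c("h", "k", "l", "d", "centric", "epsilon")
  miss <- setdiff(need, names(r))
  if (length(miss)) {
    return(paste("records missing columns:", paste(miss, collapse = ", ")))
  }
  if (nrow(r)) {
    if (anyDuplicated(r[, c("h", "k", "l")])) {
      msgs <- c(msgs, "duplicate reflections after reduction")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a ReflectionSet
#'
#' @param records reflection data.frame (needs `h`, `k`, `l`, `d`,
#'   `centric`, `epsilon`; further columns pass through).
#' @param cell,spacegroup crystal frame.
#' @param dmin,dmax resolution limits (taken from the records if absent).
#' @return a \linkS4class{ReflectionSet}.
#' @export
ReflectionSet <- function(records, cell, spacegroup, dmin = NA_real_,
                          dmax = NA_real_) {
  rownames(records) <- NULL
  if (is.na(dmin) && nrow(records)) dmin <- min(records$d)
  if (is.na(dmax) && nrow(records)) dmax <- max(records$d)
  new("ReflectionSet", cell = as.numeric(cell),
      spacegroup = normalizeSgSymbol(spacegroup),
      dmin = dmin, dmax = dmax, records = records)
}

## ---------------------------------------------------------------------------
## Fragments
## ---------------------------------------------------------------------------

#' Polyalanine fragment
#'
#' @slot id fragment identifier.
#' @slot parentId identifier of the template the fragment came from.
#' @slot spans data.frame with columns `chain`, `first`, `last` (inclusive
#'   residue ranges).
#' @slot model polyalanine \linkS4class{StructureModel}.
#' @slot mode generation mode: `sequential_extract`, `sequential_omit` or
#'   `spherical`.
#' @export
setClass("Fragment",
  representation(id = "character", parentId = "character",
                 spans = "data.frame", model = "StructureModel",
                 mode = "character")
)

setValidity("Fragment", function(object) {
  s <- object@spans
  if (!nrow(s)) return("empty spans")
  if (any(s$first > s$last)) return("span with first > last")
  for (ch in unique(s$chain)) {
    ss <- s[s$chain == ch, , drop = FALSE]
    ss <- ss[order(ss$first), , drop = FALSE]
    if (nrow(ss) > 1 && any(ss$first[-1] <= ss$last[-nrow(ss)])) {
      return("overlapping spans")
    }
  }
  want <- sort(unlist(Map(seq, s$first, s$last)))
  have <- sort(unique(object@model@atoms$resno))
  if (!identical(as.integer(want), as.integer(have))) {
    return("model residues do not equal the union of spans")
  }
  TRUE
})

#' Construct a Fragment
#'
#' @param id,parentId identifiers.
#' @param spans spans data.frame (`chain`, `first`, `last`).
#' @param model polyalanine \linkS4class{StructureModel}.
#' @param mode generation mode.
#' @return a \linkS4class{Fragment}.
#' @export
Fragment <- function(id, parentId, spans, model, mode) {
  new("Fragment", id = id, parentId = parentId, spans = spans,
      model = model, mode = mode)
}

#' Library of fragments
#'
#' @slot templateId identifier of the source template.
#' @slot mode generation mode of the library.
#' @slot fragments list of \linkS4class{Fragment} objects.
#' @export
setClass("FragmentLibrary",
  representation(templateId = "character", mode = "character",
                 fragments = "list")
)

#' Construct a FragmentLibrary
#'
#' @param templateId source template identifier.
#' @param mode library generation mode.
#' @param fragments list of \linkS4class{Fragment} objects.
#' @return a \linkS4class{FragmentLibrary}.
#' @export
FragmentLibrary <- function(templateId, mode, fragments) {
  new("FragmentLibrary", templateId = templateId, mode = mode,
      fragments = fragments)
}

## ---------------------------------------------------------------------------
## Pre-merge observations
## ---------------------------------------------------------------------------

#' Per-crystal, per-frame observations
#'
#' Integrated intensities of one crystal before merging, with the frame
#' index retained for radiation-damage modelling.
#'
#' @slot id crystal identifier.
#' @slot frames data.frame with columns `frame`, `h`, `k`, `l`, `I`, `sigI`.
#' @slot scale linear scale applied (1 = unscaled).
#' @slot bRel relative B factor applied, square angstroms.
#' @export
setClass("CrystalSeries",
  representation(id = "character", frames = "data.frame",
                 scale = "numeric", bRel = "numeric"),
  prototype(scale = 1, bRel = 0)
)

setValidity("CrystalSeries", function(object) {
  f <- object@frames
  need <- c("frame", "h", "k", "l", "I", "sigI")
  miss <- setdiff(need, names(f))
  if (length(miss)) return(paste("frames missing:", paste(miss, collapse = ", ")))
  if (nrow(f) && any(f$sigI <= 0)) return("sigI must be positive")
  if (nrow(f) && is.unsorted(f$frame)) return("frame indices must be non-decreasing")
  TRUE
})

#' Construct a CrystalSeries
#'
#' @param id crystal identifier.
#' @param frames observations data.frame (`frame`, `h`, `k`, `l`, `I`,
#'   `sigI`); sorted by frame.
#' @param scale,bRel scaling state.
#' @return a \linkS4class{CrystalSeries}.
#' @export
CrystalSeries <- function(id, frames, scale = 1, bRel = 0) {
  frames <- frames[order(frames$frame), , drop = FALSE]
  rownames(frames) <- NULL
  new("CrystalSeries", id = id, frames = frames, scale = scale, bRel = bRel)
}

#' Merge result
#'
#' @slot merged merged \linkS4class{ReflectionSet}.
#' @slot ccHalf half-dataset correlation (overall).
#' @slot meanIoverSig mean I/sigma of the merged data.
#' @slot completeness percentage of theoretical unique reflections observed.
#' @slot multiplicity observations per unique reflection.
#' @slot nCrystals number of crystals merged.
#' @slot shells per-resolution-shell statistics.
#' @export
setClass("MergeResult",
  representation(merged = "ReflectionSet", ccHalf = "numeric",
                 meanIoverSig = "numeric", completeness = "numeric",
                 multiplicity = "numeric", nCrystals = "integer",
                 shells = "data.frame")
)

## ---------------------------------------------------------------------------
## Placements and phases
## ---------------------------------------------------------------------------

#' A placed fragment with its scores
#'
#' The placement maps model Cartesian coordinates `r` (centred on `center`)
#' to fractional coordinates `x = Minv R (r - center) + translation`.
#'
#' @slot fragmentId fragment identifier.
#' @slot rotation 3x3 rotation matrix (Cartesian).
#' @slot translation fractional translation of the fragment centroid.
#' @slot center Cartesian centroid of the unplaced fragment.
#' @slot rfScore rotation-function score.
#' @slot tfz translation-function Z-score.
#' @slot cc amplitude correlation, percent.
#' @slot llg likelihood-gain-style score.
#' @export
setClass("Placement",
  representation(fragmentId = "character", rotation = "matrix",
                 translation = "numeric", center = "numeric",
                 rfScore = "numeric", tfz = "numeric", cc = "numeric",
                 llg = "numeric"),
  prototype(rfScore = NA_real_, tfz = NA_real_, cc = NA_real_,
            llg = NA_real_)
)

setValidity("Placement", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-6) return("rotation determinant must be +1")
  if (!is.na(object@cc) && (object@cc < -100 || object@cc > 100)) {
    return("cc outside [-100, 100]")
  }
  TRUE
})

Placement <- function(fragmentId, rotation, translation, center,
                      rfScore = NA_real_, tfz = NA_real_, cc = NA_real_,
                      llg = NA_real_) {
  if (!is.na(cc)) cc <- max(-100, min(100, cc))  # guard rounding overshoot
  new("Placement", fragmentId = fragmentId, rotation = rotation,
      translation = as.numeric(translation), center = as.numeric(center),
      rfScore = rfScore, tfz = tfz, cc = cc, llg = llg)
}

#' A set of phases with figures of merit
#'
#' @slot cell cell parameters.
#' @slot spacegroup Hermann-Mauguin symbol.
#' @slot records data.frame with columns `h`, `k`, `l`, `phase`
#'   (degrees in `[0, 360)`) and `fom` (figure of merit in `[0,1]`).
#' @export
setClass("PhaseSet",
  representation(cell = "numeric", spacegroup = "character",
                 records = "data.frame")
)

setValidity("PhaseSet", function(object) {
  r <- object@records
  need <- c("h", "k", "l", "phase", "fom")
  miss <- setdiff(need, names(r))
  if (length(miss)) return(paste("records missing:", paste(miss, collapse = ", ")))
  if (nrow(r) && (any(r$phase < 0) || any(r$phase >= 360))) {
    return("phases must lie in [0, 360)")
  }
  if (nrow(r) && (any(r$fom < 0) || any(r$fom > 1))) {
    return("figures of merit must lie in [0, 1]")
  }
  TRUE
})

#' Construct a PhaseSet
#'
#' @param records data.frame with `h`, `k`, `l`, `phase` (degrees) and
#'   optionally `fom` (defaults to 1).
#' @param cell,spacegroup crystal frame.
#' @return a \linkS4class{PhaseSet}.
#' @export
PhaseSet <- function(records, cell, spacegroup) {
  if (is.null(records$fom)) records$fom <- 1
  records$phase <- records$phase %% 360
  rownames(records) <- NULL
  new("PhaseSet", cell = as.numeric(cell),
      spacegroup = normalizeSgSymbol(spacegroup), records = records)
}

#' Real-space map on a cell-covering grid
#'
#' @slot values 3-dimensional numeric array; `values[i,j,k]` is the density
#'   at fractional coordinate `((i-1)/n1, (j-1)/n2, (k-1)/n3)`.  Maps are
#'   standardized to sigma units (mean 0, sd 1).
#' @slot cell cell parameters.
#' @slot spacegroup Hermann-Mauguin symbol.
#' @export
setClass("MapGrid",
  representation(values = "array", cell = "numeric", spacegroup = "character")
)

## ---------------------------------------------------------------------------
## Superposition
## ---------------------------------------------------------------------------

#' Result of a rigid-body superposition
#'
#' @slot rotation 3x3 rotation (det +1) applied to the mobile model.
#' @slot translation Cartesian translation applied after rotation.
#' @slot rmsd C-alpha r.m.s.d. after the transform, angstroms (core atoms).
#' @slot nAligned number of C-alpha pairs used in the initial fit.
#' @slot nCore number of pairs retained after core trimming.
#' @export
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAligned = "integer", nCore = "integer")
)

setValidity("Superposition", function(object) {
  if (abs(det(object@rotation) - 1) > 1e-6) return("rotation determinant must be +1")
  if (object@rmsd < 0) return("rmsd must be non-negative")
  TRUE
})
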