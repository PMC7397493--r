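#' @include AllClasses.R
NULL

#' Atom table of a model
#' @param x a \linkS4class{StructureModel} or \linkS4class{Fragment}.
#' @return data.frame of atoms.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Cell parameters
#' @param x an object carrying a crystal frame.
#' @return numeric length-6 `(a,b,c,alpha,beta,gamma)`.
#' @export
setGeneric("cellParams", function(x) standardGeneric("cellParams"))

#' Space-group symbol
#' @param x an object carrying a crystal frame.
#' @return Hermann-Mauguin symbol.
#' @export
setGeneric("spaceGroupSymbol", function(x) standardGeneric("spaceGroupSymbol"))

#' Reflection records
#' @param x a \linkS4class{ReflectionSet} or \linkS4class{MergeResult}.
#' @return data.frame of reflection records.
#' @export
setGeneric("reflections", function(x) standardGeneric("reflections"))

#' Fragments of a library
#' @param x a \linkS4class{FragmentLibrary}.
#' @return list of \linkS4class{Fragment} objects.
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' Number of residues
#' @param x a \linkS4class{StructureModel} or \linkS4class{Fragment}.
#' @return integer count of distinct residues.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

## ---- methods --------------------------------------------------------------

#' @rdname atoms
setMethod("atoms", "StructureModel", function(x) x@atoms)
#' @rdname atoms
setMethod("atoms", "Fragment", function(x) x@model@atoms)

#' @rdname cellParams
setMethod("cellParams", "StructureModel", function(x) x@cell)
#' @rdname cellParams
setMethod("cellParams", "ReflectionSet", function(x) x@cell)
#' @rdname cellParams
setMethod("cellParams", "PhaseSet", function(x) x@cell)

#' @rdname spaceGroupSymbol
setMethod("spaceGroupSymbol", "StructureModel", function(x) x@spacegroup)
#' @rdname spaceGroupSymbol
setMethod("spaceGroupSymbol", "ReflectionSet", function(x) x@spacegroup)
#' @rdname spaceGroupSymbol
setMethod("spaceGroupSymbol", "PhaseSet", function(x) x@spacegroup)

#' @rdname reflections
setMethod("reflections", "ReflectionSet", function(x) x@records)
#' @rdname reflections
setMethod("reflections", "MergeResult", function(x) x@merged@records)

#' @rdname fragments
setMethod("fragments", "FragmentLibrary", function(x) x@fragments)

#' @rdname nResidues
setMethod("nResidues", "StructureModel", function(x) {
  a <- x@atoms
  if (!nrow(a)) return(0L)
  nrow(unique(a[, c("chain", "resno", "ins")]))
})
#' @rdname nResidues
setMethod("nResidues", "Fragment", function(x) nResidues(x@model))

#' Number of fragments in a library
#' @param x a \linkS4class{FragmentLibrary}.
#' @export
setMethod("length", "FragmentLibrary", function(x) length(x@fragments))

#' @describeIn fragments extract one fragment by position or id.
#' @param i index or fragment id.
#' @export
setMethod("[[", "FragmentLibrary", function(x, i) {
  if (is.character(i)) {
    ids <- vapply(x@fragments, function(f) f@id, character(1))
    i <- match(i, ids)
  }
  x@fragments[[i]]
})

## ---- show -----------------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel:", nrow(a), "atoms,", nResidues(object), "residues,",
      length(unique(a$chain)), "chain(s)\n")
  if (length(object@cell)) {
    cat("  cell:", paste(signif(object@cell, 6), collapse = " "),
        " sg:", object@spacegroup, "\n")
  }
})

setMethod("show", "ReflectionSet", function(object) {
  r <- object@records
  cat("ReflectionSet:", nrow(r), "unique reflections,",
      sprintf("%.2f-%.2f A,", object@dmax, object@dmin),
      object@spacegroup, "\n")
  cat("  columns:", paste(names(r), collapse = " "), "\n")
})

setMethod("show", "Fragment", function(object) {
  sp <- apply(object@spans, 1, function(s)
    sprintf("%s:%s-%s", s[["chain"]], s[["first"]], s[["last"]]))
  cat(sprintf("Fragment %s (%s): %d residues [%s]\n", object@id,
              object@mode, nResidues(object), paste(sp, collapse = ", ")))
})

setMethod("show", "FragmentLibrary", function(object) {
  sizes <- vapply(object@fragments, nResidues, numeric(1))
  cat(sprintf("FragmentLibrary (%s) from '%s': %d fragments, %d-%d residues\n",
              object@mode, object@templateId, length(object@fragments),
              if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L))
})

setMethod("show", "CrystalSeries", function(object) {
  cat(sprintf("CrystalSeries '%s': %d frames, %d observations (scale %.3g, B %.3g)\n",
              object@id, length(unique(object@frames$frame)),
              nrow(object@frames), object@scale, object@bRel))
})

setMethod("show", "MergeResult", function(object) {
  cat(sprintf(paste0("MergeResult: %d crystals, %d unique reflections\n",
                     "  completeness %.2f%%, multiplicity %.2f, ",
                     "<I/sig> %.2f, CC1/2 %.3f\n"),
              object@nCrystals, nrow(object@merged@records),
              object@completeness, object@multiplicity,
              object@meanIoverSig, object@ccHalf))
})

setMethod("show", "Placement", function(object) {
  eul <- matrixToEuler(object@rotation)
  cat(sprintf(paste0("Placement of %s: euler (%.1f, %.1f, %.1f) deg, ",
                     "t (%.3f, %.3f, %.3f)\n",
                     "  rf %.4f, TFZ %.2f, CC %.1f%%, LLG %.1f\n"),
              object@fragmentId, eul[1], eul[2], eul[3],
              object@translation[1], object@translation[2],
              object@translation[3], object@rfScore, object@tfz,
              object@cc, object@llg))
})

setMethod("show", "PhaseSet", function(object) {
  cat(sprintf("PhaseSet: %d reflections, %s, mean FOM %.2f\n",
              nrow(object@records), object@spacegroup,
              mean(object@records$fom)))
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition: rmsd %.3f A over %d core of %d aligned C-alpha\n",
              object@rmsd, object@nCore, object@nAligned))
})

setMethod("show", "MapGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("MapGrid: %d x %d x %d, sigma-scaled (min %.2f, max %.2f)\n",
              d[1], d[2], d[3], min(object@values), max(object@values)))
})
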