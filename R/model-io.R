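## Coordinate-model input/output, polyalanine conversion and Kabsch
## superposition with core trimming.

.aaResnames <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE", "SEC", "PYL")

#' Read a coordinate model
#'
#' Reads a PDB or mmCIF coordinate file into a
#' \linkS4class{StructureModel}.  All ATOM/HETATM records are kept,
#' insertion codes are preserved and alternate locations are resolved to
#' the conformer with the highest occupancy (ties go to the first seen).
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by extension, default).
#' @return a \linkS4class{StructureModel}.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path)),
    error = function(e) {
      stop("cannot parse ", path, " as ", format, ": ",
           conditionMessage(e), call. = FALSE)
    })
  at <- parsed$atom
  if (is.null(at) || !nrow(at)) stop("empty model in ", path, call. = FALSE)
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    el <- substring(gsub("[^A-Za-z].*", "", at$elety), 1, 1)
  }
  el[is.na(el) | el == ""] <- substring(at$elety[is.na(el) | el == ""], 1, 1)
  atoms <- data.frame(
    element = vapply(el, normalizeElement, character(1), USE.NAMES = FALSE),
    name = at$elety,
    resno = as.integer(at$resno),
    resname = at$resid,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    ins = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, pmax(at$b, 0)),
    stringsAsFactors = FALSE
  )
  alt <- at$alt
  if (!is.null(alt)) {
    alt[is.na(alt)] <- ""
    atoms <- resolveAltlocs(atoms, alt)
  }
  cellsg <- readCellFromFile(path, format)
  StructureModel(atoms, cell = cellsg$cell, spacegroup = cellsg$sg)
}

## keep the highest-occupancy conformer per (chain, resno, ins, name)
resolveAltlocs <- function(atoms, alt) {
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occ, alt)
  atoms <- atoms[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  atoms <- atoms[keep, , drop = FALSE]
  ## restore file order
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

readCellFromFile <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  cell <- numeric(0); sg <- NA_character_
  if (format == "pdb") {
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (length(cr)) {
      cr <- cr[1]
      cell <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24),
                           substr(cr, 25, 33), substr(cr, 34, 40),
                           substr(cr, 41, 47), substr(cr, 48, 54)))
      sg <- trimws(substr(cr, 56, 66))
      if (!nzchar(sg)) sg <- NA_character_
    }
  } else {
    getv <- function(tag) {
      ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
      if (!length(ln)) return(NA)
      trimws(sub(paste0("^", tag, "\\s+"), "", ln[1]))
    }
    v <- suppressWarnings(as.numeric(c(
      getv("_cell\\.length_a"), getv("_cell\\.length_b"),
      getv("_cell\\.length_c"), getv("_cell\\.angle_alpha"),
      getv("_cell\\.angle_beta"), getv("_cell\\.angle_gamma"))))
    if (all(is.finite(v))) cell <- v
    s <- getv("_symmetry\\.space_group_name_H-M")
    if (!is.na(s)) sg <- gsub("['\"]", "", s)
  }
  if (length(cell) && !all(is.finite(cell))) cell <- numeric(0)
  list(cell = cell, sg = sg)
}

#' Write a model as PDB
#'
#' Writes coordinates in PDB v3.3 fixed format (with a CRYST1 record when
#' the model carries a cell).
#'
#' @param model a \linkS4class{StructureModel}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(model, path) {
  a <- atoms(model)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(
    pdb = NULL, file = tmp,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)), resno = a$resno, resid = a$resname,
    eleno = seq_len(nrow(a)), elety = a$name, chain = a$chain,
    insert = ifelse(a$ins == "", NA, a$ins), o = a$occ, b = a$b,
    elesy = toupper(a$element)
  )
  body <- readLines(tmp, warn = FALSE)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (length(model@cell) == 6) {
    sg <- if (is.na(model@spacegroup)) "P 1" else model@spacegroup
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                       model@cell[1], model@cell[2], model@cell[3],
                       model@cell[4], model@cell[5], model@cell[6], sg), con)
  }
  writeLines(body, con)
  invisible(path)
}

#' Convert a model to polyalanine
#'
#' Strips a protein model to its backbone plus C-beta: every amino-acid
#' residue retains exactly N, CA, C, O and CB (CB is built at ideal
#' tetrahedral geometry for glycine, and O is rebuilt when absent).
#' Residue names become ALA; waters, ligands and ions are removed.
#' Residues missing any of N, CA or C are dropped with a warning.
#'
#' @param model a \linkS4class{StructureModel} containing amino acids.
#' @return a polyalanine \linkS4class{StructureModel}.
#' @export
toPolyalanine <- function(model) {
  a <- atoms(model)
  a <- a[a$resname %in% .aaResnames, , drop = FALSE]
  if (!nrow(a)) stop("model contains no amino-acid residues", call. = FALSE)
  key <- paste(a$chain, a$resno, a$ins, sep = "\r")
  out <- vector("list", length(unique(key)))
  dropped <- character(0)
  ukeys <- unique(key)
  byres <- split(a, factor(key, levels = ukeys))
  getAtom <- function(res, nm) {
    i <- which(res$name == nm)
    if (!length(i)) return(NULL)
    as.numeric(res[i[1], c("x", "y", "z")])
  }
  for (i in seq_along(ukeys)) {
    res <- byres[[i]]
    N <- getAtom(res, "N"); CA <- getAtom(res, "CA"); C <- getAtom(res, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) {
      dropped <- c(dropped, sprintf("%s %s%d", res$resname[1], res$chain[1],
                                    res$resno[1]))
      next
    }
    O <- getAtom(res, "O")
    if (is.null(O)) {
      nextres <- if (i < length(ukeys)) byres[[i + 1]] else NULL
      nextN <- if (!is.null(nextres) && nextres$chain[1] == res$chain[1])
        getAtom(nextres, "N") else NULL
      O <- constructO(N, CA, C, nextN)
    }
    CB <- getAtom(res, "CB")
    if (is.null(CB)) CB <- constructCB(N, CA, C)
    xyz <- rbind(N, CA, C, O, CB)
    out[[i]] <- data.frame(
      element = c("N", "C", "C", "O", "C"),
      name = c("N", "CA", "C", "O", "CB"),
      resno = res$resno[1], resname = "ALA", chain = res$chain[1],
      ins = res$ins[1], x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = 1, b = res$b[match("CA", res$name)],
      stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped), " residue(s) missing backbone atoms: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) {
    stop("no residues with complete backbone", call. = FALSE)
  }
  StructureModel(out, cell = model@cell, spacegroup = model@spacegroup)
}

## ---------------------------------------------------------------------------
## superposition
## ---------------------------------------------------------------------------

caCoords <- function(model) {
  a <- atoms(model)
  ca <- a[a$name == "CA", , drop = FALSE]
  list(xyz = as.matrix(ca[, c("x", "y", "z")]),
       key = paste(ca$chain, ca$resno, ca$ins, sep = "\r"))
}

## least-squares rotation (Kabsch, via SVD) mapping mobile onto target;
## both already centred
kabschRotation <- function(mob, tar) {
  H <- t(mob) %*% tar
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Superpose two models on C-alpha atoms
#'
#' Least-squares rigid superposition (Kabsch) of paired C-alpha atoms,
#' followed by iterative core trimming: pairs deviating by more than
#' `coreCutoff` after the fit are discarded and the fit repeated until
#' stable.  The reported r.m.s.d. is over the retained core pairs.
#'
#' @param mobile,target \linkS4class{StructureModel} objects.
#' @param pairing "by_residue_number" (pairs share chain + residue number)
#'   or "sequence_alignment" (residues paired in order of appearance,
#'   chain by chain).
#' @param coreCutoff core-trimming distance in angstroms; `Inf` disables
#'   trimming.
#' @return a \linkS4class{Superposition}.
#' @export
superposeModels <- function(mobile, target,
                            pairing = c("by_residue_number",
                                        "sequence_alignment"),
                            coreCutoff = 3.0) {
  pairing <- match.arg(pairing)
  cm <- caCoords(mobile); ct <- caCoords(target)
  if (pairing == "by_residue_number") {
    idx <- match(cm$key, ct$key)
    sel <- which(!is.na(idx))
    A <- cm$xyz[sel, , drop = FALSE]
    B <- ct$xyz[idx[sel], , drop = FALSE]
  } else {
    n <- min(nrow(cm$xyz), nrow(ct$xyz))
    A <- cm$xyz[seq_len(n), , drop = FALSE]
    B <- ct$xyz[seq_len(n), , drop = FALSE]
  }
  nAligned <- nrow(A)
  if (nAligned < 3) {
    stop("insufficient C-alpha pairs for superposition (need >= 3, got ",
         nAligned, ")", call. = FALSE)
  }
  keep <- rep(TRUE, nAligned)
  iter <- 0
  repeat {
    iter <- iter + 1
    mA <- colMeans(A[keep, , drop = FALSE])
    mB <- colMeans(B[keep, , drop = FALSE])
    R <- kabschRotation(sweep(A[keep, , drop = FALSE], 2, mA),
                        sweep(B[keep, , drop = FALSE], 2, mB))
    moved <- sweep(A, 2, mA) %*% R
    dev <- sqrt(rowSums((sweep(moved, 2, mB, "+") - B)^2))
    newKeep <- dev <= coreCutoff
    if (sum(newKeep) < 3 || all(newKeep == keep) || iter >= 20) break
    keep <- newKeep
  }
  rmsd <- sqrt(mean(dev[keep]^2))
  tvec <- mB - as.numeric(mA %*% R)
  new("Superposition", rotation = t(R), translation = tvec, rmsd = rmsd,
      nAligned = as.integer(nAligned), nCore = as.integer(sum(keep)))
}

#' Apply a superposition to a model
#'
#' @param model a \linkS4class{StructureModel}.
#' @param sup a \linkS4class{Superposition}.
#' @return the transformed model.
#' @export
applySuperposition <- function(model, sup) {
  a <- atoms(model)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(sup@rotation)
  xyz <- sweep(xyz, 2, sup@translation, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  StructureModel(a, cell = model@cell, spacegroup = model@spacegroup)
}
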