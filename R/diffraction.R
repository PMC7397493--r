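## Symmetry-aware reflection generation, electron structure factors,
## normalized intensities and the twinning L-test.

#' Generate symmetry-unique reflection indices
#'
#' Enumerates one representative per symmetry-unique reflection (Friedel
#' pairs merged) with `dmin <= d <= dmax`, excluding systematic absences,
#' and flags centric reflections and epsilon factors from the operator
#' table.
#'
#' @param cell numeric length-6 cell.
#' @param spacegroup Hermann-Mauguin symbol (see [supportedSpaceGroups()]).
#' @param dmin,dmax resolution limits in angstroms, `dmin < dmax` (equal
#'   limits give a degenerate single-shell or empty set).
#' @return a \linkS4class{ReflectionSet} with index columns only.
#' @export
generateReflections <- function(cell, spacegroup, dmin, dmax = Inf) {
  sg <- spaceGroupInfo(spacegroup)
  stopifnot(dmin > 0, dmin <= dmax)
  M <- cellOrthMatrix(cell)
  alen <- sqrt(colSums(M^2))
  hmax <- pmin(ceiling(alen / dmin) + 1L, 512L)
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                   l = -hmax[3]:hmax[3])
  hkl <- as.matrix(g)
  hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
  d <- dSpacing(hkl, cell)
  inres <- d >= dmin & d <= dmax
  hkl <- hkl[inres, , drop = FALSE]
  d <- d[inres]
  if (!nrow(hkl)) {
    return(ReflectionSet(
      data.frame(h = integer(0), k = integer(0), l = integer(0),
                 d = numeric(0), centric = logical(0), epsilon = integer(0)),
      cell, sg$symbol, dmin, dmax))
  }
  can <- canonicalHKL(hkl, sg)
  keep <- !duplicated(can)
  hkl <- can[keep, , drop = FALSE]
  d <- d[keep]
  cls <- .reflClass(hkl, sg)
  ok <- !cls$absent
  rec <- data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                    l = as.integer(hkl[, 3]), d = d,
                    centric = cls$centric, epsilon = cls$epsilon)[ok, ]
  rec <- rec[order(-rec$d, rec$h, rec$k, rec$l), ]
  ReflectionSet(rec, cell, sg$symbol, dmin, dmax)
}

#' Electron structure factors by direct summation
#'
#' Computes complex structure factors
#' \eqn{F(h) = \sum_{sym}\sum_{atoms} occ\, f(s)\, e^{-B s^2}
#' e^{2\pi i h\cdot(Rx+t)}}
#' over all symmetry copies, with elastic electron form factors and
#' \eqn{s = \sin\theta/\lambda = 1/(2d)}.
#'
#' @param model a \linkS4class{StructureModel} with Cartesian coordinates
#'   compatible with `refl`'s cell.
#' @param refl a \linkS4class{ReflectionSet} (indices define where F is
#'   evaluated).
#' @param table form-factor table, default the built-in electron table.
#' @return `refl` with added/overwritten columns `F` (amplitude), `phase`
#'   (degrees in `[0,360)`) and attribute-free complex values in column
#'   `A`, `B` (real, imaginary parts).
#' @export
structureFactors <- function(model, refl, table = electronFormFactorTable()) {
  rec <- reflections(refl)
  a <- atoms(model)
  if (!nrow(a)) stop("empty model", call. = FALSE)
  sg <- spaceGroupInfo(refl@spacegroup)
  M <- cellOrthMatrix(refl@cell)
  frac <- as.matrix(a[, c("x", "y", "z")]) %*% t(solve(M))
  ff <- .ffCoefsFor(a$element, table)
  Fc <- cpp_structure_factors(
    as.matrix(rec[, c("h", "k", "l")]) * 1.0, 1 / (2 * rec$d), frac,
    a$occ, a$b, ff$idx, ff$a, ff$b,
    lapply(sg$ops, function(o) o$R * 1.0), lapply(sg$ops, `[[`, "t"))
  rec$A <- Re(Fc)
  rec$B <- Im(Fc)
  rec$F <- Mod(Fc)
  rec$phase <- (Arg(Fc) * 180 / pi) %% 360
  ReflectionSet(rec, refl@cell, refl@spacegroup, refl@dmin, refl@dmax)
}

## equal-count resolution shells on s^2; returns integer shell ids
assignShells <- function(d, nShells) {
  n <- length(d)
  nShells <- max(1L, min(nShells, n))
  if (nShells == 1L) return(rep(1L, n))
  ord <- order(1 / d^2)
  sh <- integer(n)
  sh[ord] <- as.integer(cut(seq_len(n), breaks = nShells, labels = FALSE))
  sh
}

#' Normalized structure factors
#'
#' Computes E-values by shell normalization of intensities:
#' \eqn{E^2(h) = I(h) / (\epsilon(h)\,\langle I/\epsilon\rangle_{shell})}
#' with equal-count shells in \eqn{s^2}.  Within each shell the mean of
#' \eqn{|E|^2} is exactly 1.  Shells whose mean intensity is non-positive
#' are merged with their neighbour.
#'
#' @param refl a \linkS4class{ReflectionSet} with an `I` column (an `F`
#'   column is squared if `I` is absent).
#' @param nShells number of resolution shells (default 20).
#' @return `refl` with an added `E` column.
#' @export
normalizeE <- function(refl, nShells = 20) {
  rec <- reflections(refl)
  if (is.null(rec$I)) {
    if (is.null(rec$F)) stop("no intensities or amplitudes", call. = FALSE)
    rec$I <- rec$F^2
  }
  sh <- assignShells(rec$d, nShells)
  iEps <- rec$I / rec$epsilon
  repeat {
    means <- tapply(iEps, sh, mean)
    bad <- names(means)[means <= 0]
    if (!length(bad) || length(unique(sh)) <= 1) break
    b <- as.integer(bad[1])
    ids <- sort(unique(sh))
    nb <- if (b == max(ids)) ids[which(ids == b) - 1] else ids[which(ids == b) + 1]
    sh[sh == b] <- nb
  }
  shellMean <- tapply(iEps, sh, mean)[as.character(sh)]
  rec$E <- as.numeric(sqrt(pmax(iEps / shellMean, 0)))
  ReflectionSet(rec, refl@cell, refl@spacegroup, refl@dmin, refl@dmax)
}

#' Twinning L-test
#'
#' Computes the moments of \eqn{L = (I_1 - I_2)/(I_1 + I_2)} over pairs of
#' neighbouring, symmetry-unrelated reflections.  Pairs are drawn as
#' `(h,k,l)` against `(h,k,l+delta)` (and the k-offset analogue) for small
#' non-symmetric offsets.  For untwinned acentric data the expectations
#' are \eqn{\langle|L|\rangle = 1/2} and \eqn{\langle L^2\rangle = 1/3};
#' for a perfect twin 0.375 and 0.2.
#'
#' @param refl a \linkS4class{ReflectionSet} with intensities.
#' @param offsets integer offsets used to form neighbour pairs.
#' @return list with `meanAbsL`, `meanL2`, `nPairs`, and the analytic
#'   reference values `untwinned` and `perfectTwin`.
#' @export
lTest <- function(refl, offsets = 1:2) {
  rec <- reflections(refl)
  if (is.null(rec$I)) stop("intensities required for the L-test", call. = FALSE)
  use <- rec$I > 0 & !rec$centric
  rec <- rec[use, , drop = FALSE]
  key <- paste(rec$h, rec$k, rec$l, sep = ",")
  idx <- seq_len(nrow(rec))
  names(idx) <- key
  L <- numeric(0)
  for (dlt in offsets) {
    for (axis in c("l", "k")) {
      mate <- if (axis == "l") paste(rec$h, rec$k, rec$l + dlt, sep = ",")
              else paste(rec$h, rec$k + dlt, rec$l, sep = ",")
      j <- idx[mate]
      ok <- !is.na(j)
      i1 <- rec$I[ok]
      i2 <- rec$I[j[ok]]
      L <- c(L, (i1 - i2) / (i1 + i2))
    }
  }
  L <- L[is.finite(L)]
  if (length(L) < 500) {
    warning("only ", length(L), " L-test pairs; estimates will be noisy",
            call. = FALSE)
  }
  list(meanAbsL = mean(abs(L)), meanL2 = mean(L^2), nPairs = length(L),
       untwinned = c(meanAbsL = 0.5, meanL2 = 1 / 3),
       perfectTwin = c(meanAbsL = 0.375, meanL2 = 0.2))
}

## ---------------------------------------------------------------------------
## reflection I/O
## ---------------------------------------------------------------------------

#' Write reflections as TSV
#'
#' Plain whitespace table `h k l I sigI [F phase]`; round-trips exactly
#' through [readReflectionsTSV()].
#'
#' @param refl a \linkS4class{ReflectionSet}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReflectionsTSV <- function(refl, path) {
  rec <- reflections(refl)
  cols <- intersect(c("h", "k", "l", "I", "sigI", "F", "phase"), names(rec))
  hdr <- c(sprintf("# cell %s", paste(format(refl@cell, digits = 15),
                                      collapse = " ")),
           sprintf("# spacegroup %s", refl@spacegroup))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(rec[, cols], digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reflections from TSV
#'
#' Reads tables written by [writeReflectionsTSV()] or any whitespace table
#' with columns `h k l I sigI` (optionally `F`, `phase`).  Cell and space
#' group come from `# cell` / `# spacegroup` header comments unless given.
#'
#' @param path input path.
#' @param cell,spacegroup override/percolate the crystal frame.
#' @return a \linkS4class{ReflectionSet}.
#' @export
readReflectionsTSV <- function(path, cell = NULL, spacegroup = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(cell)) {
    cl <- grep("^# cell ", hdr, value = TRUE)
    if (length(cl)) cell <- as.numeric(strsplit(trimws(sub("^# cell ", "", cl[1])),
                                                "\\s+")[[1]])
  }
  if (is.null(spacegroup)) {
    sl <- grep("^# spacegroup ", hdr, value = TRUE)
    spacegroup <- if (length(sl)) trimws(sub("^# spacegroup ", "", sl[1])) else "P1"
  }
  if (is.null(cell) || length(cell) != 6) {
    stop("cell parameters required (header or argument)", call. = FALSE)
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  sg <- spaceGroupInfo(spacegroup)
  hkl <- as.matrix(tab[, c("h", "k", "l")])
  cls <- .reflClass(hkl, sg)
  tab$d <- dSpacing(hkl, cell)
  tab$centric <- cls$centric
  tab$epsilon <- cls$epsilon
  ReflectionSet(tab, cell, sg$symbol)
}

#' Read structure factors from an mmCIF file
#'
#' Minimal reader for structure-factor mmCIF: parses the `_refln` loop
#' (indices plus whichever of intensity/amplitude/sigma/phase columns are
#' present) and the cell/symmetry items.
#'
#' @param path input path.
#' @return a \linkS4class{ReflectionSet}.
#' @export
readReflectionsMmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getv <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(ln)) return(NA_character_)
    gsub("['\"]", "", trimws(sub(paste0("^", tag, "\\s+"), "", ln[1])))
  }
  cell <- suppressWarnings(as.numeric(c(
    getv("_cell\\.length_a"), getv("_cell\\.length_b"),
    getv("_cell\\.length_c"), getv("_cell\\.angle_alpha"),
    getv("_cell\\.angle_beta"), getv("_cell\\.angle_gamma"))))
  sgsym <- getv("_symmetry\\.space_group_name_H-M")
  if (is.na(sgsym)) sgsym <- "P1"
  ## locate the _refln loop
  li <- grep("^\\s*loop_", lines)
  for (start in li) {
    j <- start + 1
    tags <- character(0)
    while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
      tags <- c(tags, trimws(lines[j]))
      j <- j + 1
    }
    if (!any(grepl("^_refln\\.", tags))) next
    rows <- character(0)
    while (j <= length(lines) && nzchar(trimws(lines[j])) &&
           !grepl("^(loop_|_|#)", trimws(lines[j]))) {
      rows <- c(rows, lines[j])
      j <- j + 1
    }
    tab <- utils::read.table(text = rows, col.names = make.names(tags))
    nm <- function(tag) make.names(paste0("_refln.", tag))
    pick <- function(tag) {
      cn <- nm(tag)
      if (cn %in% names(tab)) suppressWarnings(as.numeric(tab[[cn]])) else NULL
    }
    rec <- data.frame(h = pick("index_h"), k = pick("index_k"),
                      l = pick("index_l"))
    iMeas <- pick("intensity_meas"); iSig <- pick("intensity_sigma")
    fMeas <- pick("F_meas_au") %||% pick("F_meas")
    fSig <- pick("F_meas_sigma_au") %||% pick("F_meas_sigma")
    ph <- pick("phase_meas") %||% pick("phase_calc")
    if (!is.null(iMeas)) { rec$I <- iMeas; rec$sigI <- iSig }
    if (!is.null(fMeas)) {
      rec$F <- fMeas
      if (is.null(rec$I)) {
        rec$I <- fMeas^2
        rec$sigI <- if (!is.null(fSig)) 2 * fMeas * fSig else abs(rec$I) * 0.1
      }
    }
    if (!is.null(ph)) rec$phase <- ph %% 360
    if (any(!is.finite(cell))) stop("mmCIF lacks cell parameters", call. = FALSE)
    sg <- spaceGroupInfo(sgsym)
    hkl <- as.matrix(rec[, c("h", "k", "l")])
    cls <- .reflClass(hkl, sg)
    rec$d <- dSpacing(hkl, cell)
    rec$centric <- cls$centric
    rec$epsilon <- cls$epsilon
    return(ReflectionSet(rec, cell, sg$symbol))
  }
  stop("no _refln loop found in ", path, call. = FALSE)
}
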