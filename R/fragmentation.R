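## Fragment-library generation: sequential shredding, spherical compact
## models, the per-residue Shred-LLG descriptor and model selection.

#' Per-residue shred descriptor
#'
#' @slot profile data.frame with columns `chain`, `resno`, `score`.
#' @slot fragmentScores data.frame with columns `id`, `size`, `score`, `z`.
#' @slot normalization description of the score scale.
#' @export
setClass("ShredProfile",
  representation(profile = "data.frame", fragmentScores = "data.frame",
                 normalization = "character")
)

setMethod("show", "ShredProfile", function(object) {
  cat(sprintf("ShredProfile: %d residues from %d scored fragments (%s)\n",
              nrow(object@profile), nrow(object@fragmentScores),
              object@normalization))
})

## split a polyalanine template into break-free segments; breaks are
## CA-CA > 4.5 A or residue-number gaps
chainSegments <- function(model, breakDist = 4.5) {
  a <- atoms(model)
  ca <- a[a$name == "CA", , drop = FALSE]
  segs <- list()
  for (ch in unique(ca$chain)) {
    cc <- ca[ca$chain == ch, , drop = FALSE]
    cc <- cc[order(cc$resno), , drop = FALSE]
    if (!nrow(cc)) next
    d <- sqrt(rowSums((as.matrix(cc[-1, c("x", "y", "z")]) -
                       as.matrix(cc[-nrow(cc), c("x", "y", "z")]))^2))
    gap <- diff(cc$resno) != 1 | d > breakDist
    brk <- cumsum(c(0, gap))
    for (b in unique(brk)) {
      segs[[length(segs) + 1]] <- list(chain = ch, resno = cc$resno[brk == b])
    }
  }
  segs
}

subsetResidues <- function(model, chain, resno) {
  a <- atoms(model)
  keep <- a$chain %in% chain & a$resno %in% resno
  StructureModel(a[keep, , drop = FALSE], cell = model@cell,
                 spacegroup = model@spacegroup)
}

runsToSpans <- function(chain, resno) {
  resno <- sort(unique(resno))
  brk <- cumsum(c(0, diff(resno) != 1))
  do.call(rbind, lapply(unique(brk), function(b) {
    r <- resno[brk == b]
    data.frame(chain = chain, first = min(r), last = max(r))
  }))
}

#' Sequential fragment library
#'
#' Shreds a template into contiguous polyalanine segments: for each size
#' `s` in `[sizeMin, sizeMax]` and each start on the `1, 1+step, ...` grid
#' of every break-free chain segment, emits the extracted window
#' (`kind = "extract"`) or its complement in the template
#' (`kind = "omit"`).  Chain breaks (CA-CA > 4.5 angstroms or numbering
#' gaps) terminate segments and restart the grid.
#'
#' @param template a \linkS4class{StructureModel}; converted to
#'   polyalanine internally.
#' @param sizeMin,sizeMax fragment sizes in residues (defaults 10 and 20).
#' @param step start-grid spacing in residues (default 4).
#' @param kind "extract" or "omit".
#' @param templateId identifier recorded on the fragments.
#' @return a \linkS4class{FragmentLibrary}.
#' @export
sequentialFragments <- function(template, sizeMin = 10, sizeMax = 20,
                                step = 4, kind = c("extract", "omit"),
                                templateId = "template") {
  kind <- match.arg(kind)
  if (sizeMin > sizeMax || step < 1) {
    stop("invalid shred parameters: need sizeMin <= sizeMax and step >= 1",
         call. = FALSE)
  }
  poly <- toPolyalanine(template)
  segs <- chainSegments(poly)
  if (!any(vapply(segs, function(s) length(s$resno), numeric(1)) >= sizeMin)) {
    stop("no chain segment with at least ", sizeMin, " residues", call. = FALSE)
  }
  allKeys <- unique(atoms(poly)[, c("chain", "resno")])
  frags <- list()
  mode <- paste0("sequential_", kind)
  for (seg in segs) {
    L <- length(seg$resno)
    for (s in sizeMin:sizeMax) {
      if (s > L) next
      starts <- seq(1, L - s + 1, by = step)
      for (st in starts) {
        win <- seg$resno[st:(st + s - 1)]
        if (kind == "extract") {
          spans <- runsToSpans(seg$chain, win)
          model <- subsetResidues(poly, seg$chain, win)
        } else {
          keep <- !(allKeys$chain == seg$chain & allKeys$resno %in% win)
          if (!any(keep)) next
          spans <- do.call(rbind, lapply(
            split(allKeys[keep, ], allKeys$chain[keep]),
            function(k) runsToSpans(k$chain[1], k$resno)))
          rownames(spans) <- NULL
          model <- StructureModel(
            atoms(poly)[!(atoms(poly)$chain == seg$chain &
                          atoms(poly)$resno %in% win), , drop = FALSE],
            cell = poly@cell, spacegroup = poly@spacegroup)
        }
        id <- sprintf("%s_%s_s%02d_r%04d", kind, seg$chain, s, win[1])
        frags[[length(frags) + 1]] <-
          Fragment(id, templateId, spans, model, mode)
      }
    }
  }
  FragmentLibrary(templateId, mode, frags)
}

#' Cluster rotations geometrically
#'
#' Greedy clustering of scored rotations: visiting rotations in order of
#' descending score, each joins the first existing cluster whose
#' representative lies within `toleranceDeg` under the rotation-angle
#' metric (minimized over the rotational symmetries of the space group),
#' otherwise it founds a new cluster.
#'
#' @param rotations list of 3x3 rotation matrices.
#' @param scores numeric scores, same length.
#' @param toleranceDeg clustering tolerance in degrees (default 15).
#' @param spacegroup Hermann-Mauguin symbol (P1 when no symmetry applies).
#' @param cell cell parameters (needed to express the symmetry rotations
#'   in Cartesian space); defaults to a unit orthogonal cell.
#' @return list of clusters, each a list with `representative` (rotation),
#'   `score` (of the representative), `members` (list of rotations),
#'   `memberScores`, `toleranceDeg`.
#' @export
clusterRotations <- function(rotations, scores, toleranceDeg = 15,
                             spacegroup = "P1",
                             cell = c(1, 1, 1, 90, 90, 90)) {
  stopifnot(length(rotations) >= 1, length(scores) == length(rotations))
  sg <- spaceGroupInfo(spacegroup)
  pg <- pointGroupRotations(sg, cell)
  ## keep proper rotations only for the orientation metric
  pg <- Filter(function(S) det(S) > 0, pg)
  symDist <- function(Ra, Rb) {
    min(vapply(pg, function(S) rotationAngle(S %*% Ra, Rb), numeric(1)))
  }
  ord <- order(-scores)
  clusters <- list()
  for (i in ord) {
    R <- rotations[[i]]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      if (symDist(R, clusters[[ci]]$representative) <= toleranceDeg) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, list(R))
        clusters[[ci]]$memberScores <- c(clusters[[ci]]$memberScores, scores[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1]] <- list(
        representative = R, score = scores[i], members = list(R),
        memberScores = scores[i], toleranceDeg = toleranceDeg)
    }
  }
  clusters
}

#' Shred-LLG per-residue descriptor
#'
#' Builds the per-residue descriptor from scored sequential fragments:
#' scores are z-scored within each fragment-size group, and each residue's
#' value is the mean z-score over all fragments that contain it.  The
#' profile is therefore invariant to affine rescaling of any single size
#' group's scores.  Residues covered by no scored fragment are absent
#' from the profile.
#'
#' @param library a sequential-mode \linkS4class{FragmentLibrary}.
#' @param scores named numeric vector of fragment scores (names are
#'   fragment ids), or unnamed in library order.
#' @return a \linkS4class{ShredProfile}.
#' @export
shredProfile <- function(library, scores) {
  frs <- fragments(library)
  if (!length(frs)) stop("empty fragment library", call. = FALSE)
  if (!grepl("^sequential", library@mode)) {
    stop("Shred profiles are defined for sequential-mode libraries",
         call. = FALSE)
  }
  ids <- vapply(frs, function(f) f@id, character(1))
  if (!is.null(names(scores))) {
    miss <- setdiff(ids, names(scores))
    if (length(miss)) stop("unscored fragments: ", paste(utils::head(miss, 3),
                           collapse = ", "), call. = FALSE)
    scores <- scores[ids]
  } else if (length(scores) != length(frs)) {
    stop("scores must match the library length or be named by id",
         call. = FALSE)
  }
  sizes <- vapply(frs, nResidues, numeric(1))
  z <- numeric(length(scores))
  for (s in unique(sizes)) {
    g <- sizes == s
    mu <- mean(scores[g]); sd <- stats::sd(scores[g])
    z[g] <- if (!is.na(sd) && sd > 0) (scores[g] - mu) / sd else 0
  }
  ## each residue's value: mean z over all fragments whose model contains it
  resKey <- lapply(frs, function(f) {
    a <- unique(atoms(f)[, c("chain", "resno")])
    paste(a$chain, a$resno, sep = "\r")
  })
  keyAll <- rep(unlist(resKey), times = 1)
  zAll <- rep(z, times = lengths(resKey))
  sums <- tapply(zAll, keyAll, sum)
  cnts <- tapply(zAll, keyAll, length)
  keys <- names(sums)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  prof <- data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
                     score = as.numeric(sums / cnts))
  prof <- prof[order(prof$chain, prof$resno), ]
  rownames(prof) <- NULL
  new("ShredProfile", profile = prof,
      fragmentScores = data.frame(id = ids, size = sizes,
                                  score = as.numeric(scores), z = z),
      normalization = "within-size z-score, per-residue mean")
}

## local maxima of a numeric vector (plateau-tolerant)
.localMaxima <- function(x) {
  n <- length(x)
  if (n == 1) return(1L)
  up <- c(TRUE, diff(x) >= 0)
  down <- c(diff(x) <= 0, TRUE)
  which(up & down & (x > min(x)))
}

#' Select derived models from a shred profile
#'
#' Emits up to `maxModels` polyalanine models built from residues picked
#' by four selection rules on the (min-max normalized) profile:
#' peaks (residues in local-maximum regions), plateaus (runs of at least
#' `plateauLen` residues each within 10 percent of the run maximum),
#' residues at or above 75 percent of the profile maximum, and residues at
#' or above the smallest local-maximum value.  Duplicate residue sets are
#' dropped, as are models under `minResidues` residues.
#'
#' @param profile a \linkS4class{ShredProfile}.
#' @param template the template \linkS4class{StructureModel}.
#' @param maxModels maximum number of models (default 4).
#' @param minResidues smallest model emitted (default 10).
#' @param plateauLen minimum plateau length (default 6).
#' @return a \linkS4class{FragmentLibrary} (possibly empty, with warning).
#' @export
selectModels <- function(profile, template, maxModels = 4, minResidues = 10,
                         plateauLen = 6) {
  prof <- profile@profile
  if (!nrow(prof)) stop("empty profile", call. = FALSE)
  poly <- toPolyalanine(template)
  x <- prof$score
  rng <- diff(range(x))
  p <- if (rng > 0) (x - min(x)) / rng else rep(1, length(x))
  lm <- .localMaxima(p)
  sets <- list()
  ## rule 1: peak regions - expand each local maximum while >= 75% of it
  if (length(lm)) {
    sel <- logical(length(p))
    for (i in lm) {
      thr <- 0.75 * p[i]
      j <- i; while (j >= 1 && p[j] >= thr) { sel[j] <- TRUE; j <- j - 1 }
      j <- i; while (j <= length(p) && p[j] >= thr) { sel[j] <- TRUE; j <- j + 1 }
    }
    sets$peaks <- which(sel)
  }
  ## rule 2: plateaus - maximal runs within 10% of their running maximum
  inRun <- logical(length(p))
  i <- 1
  while (i <= length(p)) {
    j <- i
    while (j < length(p) &&
           abs(max(p[i:(j + 1)]) - min(p[i:(j + 1)])) <= 0.1 * max(p[i:(j + 1)])) {
      j <- j + 1
    }
    if (j - i + 1 >= plateauLen) inRun[i:j] <- TRUE
    i <- j + 1
  }
  sets$plateaus <- which(inRun)
  ## rule 3: values above 75% of the maximum
  sets$above75 <- which(p >= 0.75 * max(p))
  ## rule 4: values above the minimum peak height
  if (length(lm)) sets$aboveMinPeak <- which(p >= min(p[lm]))
  ## build, dedupe, size-filter
  frags <- list()
  seen <- character(0)
  for (nm in names(sets)) {
    idx <- sets[[nm]]
    if (length(idx) < minResidues) next
    key <- paste(sort(idx), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    sub <- prof[idx, , drop = FALSE]
    spans <- do.call(rbind, lapply(split(sub, sub$chain), function(s)
      runsToSpans(s$chain[1], s$resno)))
    rownames(spans) <- NULL
    model <- subsetResidues(poly, unique(sub$chain), sub$resno)
    frags[[length(frags) + 1]] <- Fragment(
      paste0("select_", nm), "profile", spans, model, "sequential_extract")
    if (length(frags) >= maxModels) break
  }
  if (!length(frags)) {
    warning("no residues selected by any rule; empty library", call. = FALSE)
  }
  FragmentLibrary("profile", "sequential_extract", frags)
}

#' Spherical (compact) fragment library
#'
#' For each residue's C-alpha as a centre, collects the `nTarget` spatially
#' nearest residues, keeps contiguous runs of at least `minContig`
#' residues, and emits the result as a multi-span polyalanine fragment.
#' Centres whose pruned neighbourhood falls more than 10 residues short of
#' `nTarget` are grown (up to `nTarget + 10` neighbours) or skipped, so
#' all emitted models are within 10 residues of the target size.
#' Duplicate residue sets are removed.
#'
#' @param template a \linkS4class{StructureModel}.
#' @param nTarget target model size in residues.
#' @param minContig shortest contiguous run kept (default 3).
#' @param templateId identifier recorded on the fragments.
#' @return a \linkS4class{FragmentLibrary}.
#' @export
sphericalFragments <- function(template, nTarget, minContig = 3,
                               templateId = "template") {
  if (nTarget < minContig) {
    stop("nTarget must be at least minContig", call. = FALSE)
  }
  poly <- toPolyalanine(template)
  a <- atoms(poly)
  ca <- a[a$name == "CA", , drop = FALSE]
  ca <- ca[order(ca$chain, ca$resno), , drop = FALSE]
  n <- nrow(ca)
  if (n < nTarget) stop("template smaller than nTarget", call. = FALSE)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  frags <- list()
  seen <- character(0)
  for (ci in seq_len(n)) {
    sel <- NULL
    for (k in nTarget:min(n, nTarget + 10)) {
      near <- order(D[ci, ])[seq_len(k)]
      keep <- integer(0)
      for (ch in unique(ca$chain[near])) {
        rn <- sort(ca$resno[near][ca$chain[near] == ch])
        brk <- cumsum(c(0, diff(rn) != 1))
        for (b in unique(brk)) {
          run <- rn[brk == b]
          if (length(run) >= minContig) {
            keep <- c(keep, which(ca$chain == ch & ca$resno %in% run))
          }
        }
      }
      if (length(keep) >= nTarget - 10) { sel <- sort(unique(keep)); break }
    }
    if (is.null(sel) || length(sel) > nTarget + 10) next
    key <- paste(sel, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    sub <- ca[sel, , drop = FALSE]
    spans <- do.call(rbind, lapply(split(sub, sub$chain), function(s)
      runsToSpans(s$chain[1], s$resno)))
    rownames(spans) <- NULL
    model <- subsetResidues(poly, unique(sub$chain), sub$resno)
    frags[[length(frags) + 1]] <- Fragment(
      sprintf("sph_%s%04d", ca$chain[ci], ca$resno[ci]), templateId,
      spans, model, "spherical")
  }
  FragmentLibrary(templateId, "spherical", frags)
}

#' Expected-LLG-based model sizing
#'
#' Returns the smallest model size `n` (in residues) whose expected
#' log-likelihood gain reaches `targetEllg`, using
#' \eqn{eLLG(n) = \sum_{acentric} \sigma_A^4/2 + \sum_{centric}
#' \sigma_A^4/4} with
#' \eqn{\sigma_A(s) = \sqrt{f_n}\, e^{-2\pi^2\, rmsd^2 s^2/3}},
#' \eqn{f_n = n/N_{asu}} and \eqn{s = 1/d}.
#'
#' @param dataset a \linkS4class{ReflectionSet} (resolution range and
#'   centric flags are used).
#' @param rmsdEst expected model-to-target r.m.s.d. in angstroms, `> 0`.
#' @param totalResidues ordered residues in the asymmetric unit.
#' @param targetEllg target expected LLG (default 30).
#' @return integer model size in residues.
#' @export
ellgModelSize <- function(dataset, rmsdEst, totalResidues, targetEllg = 30) {
  stopifnot(rmsdEst >= 0, totalResidues >= 1)
  rec <- reflections(dataset)
  if (!nrow(rec)) stop("empty reflection set", call. = FALSE)
  s2 <- 1 / rec$d^2
  atten <- exp(-2 * pi^2 * rmsdEst^2 * s2 / 3)
  w <- ifelse(rec$centric, 1 / 4, 1 / 2)
  ## eLLG(n) = (n/N)^2 * sum(w * atten^4)
  base <- sum(w * atten^4)
  ellg <- function(n) (n / totalResidues)^2 * base
  for (n in seq_len(totalResidues)) {
    if (ellg(n) >= targetEllg) return(as.integer(n))
  }
  warning("target eLLG ", targetEllg, " unreachable; returning whole ",
          "structure (", totalResidues, " residues, eLLG ",
          signif(ellg(totalResidues), 4), ")", call. = FALSE)
  as.integer(totalResidues)
}
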