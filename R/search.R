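## Placement of polyalanine fragments against intensity data: rotation
## search on a Patterson-correlation-style E^2 - 1 target, brute-force
## translation search with a grid-referenced Z-score, packing filter,
## rigid-body refinement and a Rice-likelihood placement score.

fragModel <- function(fragment) {
  if (is(fragment, "Fragment")) fragment@model else fragment
}

fragAtomsCentered <- function(fragment) {
  a <- atoms(fragModel(fragment))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  list(atoms = a, xyz = sweep(xyz, 2, ctr), center = ctr)
}

.searchPrep <- function(data, dminSearch = NULL, needE = FALSE) {
  rec <- reflections(data)
  if (needE && is.null(rec$E)) {
    stop("data must carry E-values; run normalizeE() first", call. = FALSE)
  }
  if (!is.null(dminSearch)) rec <- rec[rec$d >= dminSearch, , drop = FALSE]
  if (!nrow(rec)) stop("no reflections in the search resolution range",
                       call. = FALSE)
  rec
}

#' Rotation search for a fragment
#'
#' Scores orientations on a uniform z-x-z Euler grid by the correlation of
#' normalized squared molecular transforms: for each rotation, the
#' fragment's transform is evaluated at the data's scattering vectors (as
#' an isolated molecule, i.e. in a large P1 box), shell-normalized to
#' \eqn{E^2 - 1}, and Pearson-correlated with the observed
#' \eqn{E^2 - 1}.  This translation-independent target is a documented
#' simplification of a maximum-likelihood rotation function.
#'
#' @param fragment a \linkS4class{Fragment} or polyalanine model.
#' @param data a \linkS4class{ReflectionSet} with `E` values.
#' @param rotStep grid step in degrees (must be 30 or less).
#' @param dminSearch optional high-resolution cutoff for the search
#'   (rotation functions are commonly run at moderate resolution).
#' @param nShells shells for the fragment-side normalization.
#' @param topN rows returned.
#' @param nRefl cap on the number of reflections used (the strongest by
#'   `|E|` are kept); `Inf` uses all.
#' @param refineTop number of top orientations polished by local
#'   (Nelder-Mead) maximization; 0 disables.
#' @param rescoreTop in space groups with rotational symmetry, the top
#'   `rescoreTop` grid orientations are re-ranked with the
#'   symmetry-summed ("locked") target — the squared transform summed
#'   over all point-group images — before refinement; 0 disables.
#' @return data.frame with columns `alpha`, `beta`, `gamma`, `score`,
#'   sorted by descending score.
#' @export
rotationSearch <- function(fragment, data, rotStep = 10, dminSearch = NULL,
                           nShells = 10, topN = 100, nRefl = 1500,
                           refineTop = 12, rescoreTop = 80) {
  if (rotStep > 30) {
    stop("rotation grid step above 30 degrees is meaningless sampling",
         call. = FALSE)
  }
  rec <- .searchPrep(data, dminSearch, needE = TRUE)
  if (nrow(rec) > nRefl) {
    rec <- rec[order(-rec$E)[seq_len(nRefl)], , drop = FALSE]
  }
  sg <- spaceGroupInfo(data@spacegroup)
  locked <- rescoreTop > 0 && sg$nsym > 1
  scoreFun <- if (locked) .lockedRotationScores else .rotationScores
  grid <- rotationGrid(rotStep, alphaMax = 360 / sg$zOrder)
  scores <- .rotationScores(fragment, data, rec,
                            lapply(seq_len(nrow(grid)), function(i)
                              eulerToMatrix(grid[i, 1], grid[i, 2], grid[i, 3])),
                            nShells)
  out <- data.frame(grid, score = scores)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  if (locked) {
    keep <- seq_len(min(rescoreTop, nrow(out)))
    out <- out[keep, , drop = FALSE]
    out$score <- .lockedRotationScores(
      fragment, data, rec,
      lapply(keep, function(i) eulerToMatrix(out$alpha[i], out$beta[i],
                                             out$gamma[i])), nShells)
    out <- out[order(-out$score), , drop = FALSE]
    rownames(out) <- NULL
  }
  for (i in seq_len(min(refineTop, nrow(out)))) {
    R0 <- eulerToMatrix(out$alpha[i], out$beta[i], out$gamma[i])
    obj <- function(p) {
      -scoreFun(fragment, data, rec,
                list(eulerToMatrix(p[1], p[2], p[3]) %*% R0), nShells)
    }
    fit <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 60, reltol = 1e-5,
                                       parscale = rep(rotStep / 2, 3)))
    if (-fit$value > out$score[i]) {
      eul <- matrixToEuler(eulerToMatrix(fit$par[1], fit$par[2],
                                         fit$par[3]) %*% R0)
      out$alpha[i] <- eul[1] %% 360
      out$beta[i] <- eul[2]
      out$gamma[i] <- eul[3] %% 360
      out$score[i] <- -fit$value
    }
  }
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, topN)
}

#' Score a fragment at given orientations
#'
#' Same target as [rotationSearch()] but for an explicit list of rotation
#' matrices (e.g. cluster representatives at which shredded sub-models are
#' re-scored).
#'
#' @inheritParams rotationSearch
#' @param rotations list of 3x3 rotation matrices.
#' @param symSum use the symmetry-summed target when the space group has
#'   rotational symmetry (default TRUE).
#' @return numeric vector of scores.
#' @export
scoreRotations <- function(fragment, data, rotations, dminSearch = NULL,
                           nShells = 10, symSum = TRUE) {
  rec <- .searchPrep(data, dminSearch, needE = TRUE)
  if (symSum && spaceGroupInfo(data@spacegroup)$nsym > 1) {
    .lockedRotationScores(fragment, data, rec, rotations, nShells)
  } else {
    .rotationScores(fragment, data, rec, rotations, nShells)
  }
}

.rotationScores <- function(fragment, data, rec, rotations, nShells) {
  fr <- fragAtomsCentered(fragment)
  ff <- .ffCoefsFor(fr$atoms$element)
  S <- recipMatrix(data@cell)
  svec <- as.matrix(rec[, c("h", "k", "l")]) %*% t(S)
  sh <- assignShells(rec$d, max(1L, min(nShells, nrow(rec) %/% 20)))
  rots <- do.call(rbind, lapply(rotations, function(R) as.numeric(t(R))))
  cpp_rotation_scan(svec, rots, fr$xyz, fr$atoms$occ, fr$atoms$b, ff$idx,
                    ff$a, ff$b, rec$E^2 - 1, sh, max(sh))
}

## symmetry-summed ("locked") rotation target: the squared molecular
## transform is accumulated over all point-group images of the trial
## orientation before shell normalization, so the score sees every
## symmetry copy's contribution to the Patterson rather than one
## molecule's worth.  Slower per orientation; used to re-rank and refine
## candidates from the fast single-copy scan.
.lockedRotationScores <- function(fragment, data, rec, rotations, nShells) {
  sg <- spaceGroupInfo(data@spacegroup)
  pg <- Filter(function(S) det(S) > 0,
               pointGroupRotations(sg, data@cell))
  fr <- fragAtomsCentered(fragment)
  ff <- .ffCoefsFor(fr$atoms$element)
  S <- recipMatrix(data@cell)
  svec <- as.matrix(rec[, c("h", "k", "l")]) %*% t(S)
  sh <- assignShells(rec$d, max(1L, min(nShells, nrow(rec) %/% 20)))
  eobs <- rec$E^2 - 1
  vapply(rotations, function(R) {
    Isum <- 0
    for (Sg in pg) {
      G <- cpp_molecular_transform(svec %*% (Sg %*% R), fr$xyz,
                                   fr$atoms$occ, fr$atoms$b, ff$idx,
                                   ff$a, ff$b)
      Isum <- Isum + Mod(G)^2
    }
    mns <- tapply(Isum, sh, mean)[as.character(sh)]
    e2 <- as.numeric(Isum / mns) - 1
    if (stats::sd(e2) == 0 || stats::sd(eobs) == 0) return(0)
    stats::cor(e2, eobs)
  }, numeric(1))
}

## fundamental translation domain modulo the allowed origin shifts
cheshireExtent <- function(sg) {
  switch(sg$symbol,
    "P1" = c(0, 0, 0),
    "P21" = c(0.5, 0, 0.5),
    "P212121" = c(0.5, 0.5, 0.5),
    "P43212" = c(0.5, 1, 0.5),
    "P41212" = c(0.5, 1, 0.5))
}

#' Translation search for an oriented fragment
#'
#' Brute-force scan of the fragment centroid over the fundamental
#' translation domain (the cell modulo allowed origin shifts; polar axes
#' are fixed at 0).  Each position is scored by the Pearson correlation of
#' \eqn{|F_{calc}|} with the observed amplitudes; the Z-score of the best
#' position against the whole grid-score distribution is reported as TFZ.
#'
#' @param fragment a \linkS4class{Fragment} or polyalanine model.
#' @param rotation 3x3 rotation matrix applied to the (centred) fragment.
#' @param data a \linkS4class{ReflectionSet} with `F` or `I`.
#' @param stepFrac translation grid step as a fraction of the cell
#'   (default 1/24).
#' @param dminSearch optional high-resolution cutoff.
#' @param topN number of placements returned.
#' @return list of \linkS4class{Placement} objects sorted by score (the
#'   score is stored in `cc`, as a percentage; `tfz` is attached to all).
#' @export
translationSearch <- function(fragment, rotation, data, stepFrac = 1 / 24,
                              dminSearch = NULL, topN = 5) {
  rec <- .searchPrep(data, dminSearch)
  fobs <- rec$F %||% sqrt(pmax(rec$I, 0))
  sg <- spaceGroupInfo(data@spacegroup)
  fr <- fragAtomsCentered(fragment)
  M <- cellOrthMatrix(data@cell)
  frac <- (fr$xyz %*% t(rotation)) %*% t(solve(M))
  ff <- .ffCoefsFor(fr$atoms$element)
  parts <- cpp_sym_partials(
    as.matrix(rec[, c("h", "k", "l")]) * 1.0, 1 / (2 * rec$d), frac,
    fr$atoms$occ, fr$atoms$b, ff$idx, ff$a, ff$b,
    lapply(sg$ops, function(o) o$R * 1.0), lapply(sg$ops, `[[`, "t"))
  ext <- cheshireExtent(sg)
  axgrid <- lapply(ext, function(e) {
    if (e == 0) 0 else seq(0, e - 1e-9, by = stepFrac)
  })
  tg <- as.matrix(expand.grid(x = axgrid[[1]], y = axgrid[[2]],
                              z = axgrid[[3]]))
  scores <- cpp_translation_scan(parts$G, parts$hR, tg, fobs)
  sdev <- stats::sd(scores)
  best <- order(-scores)
  tfz <- if (is.na(sdev) || sdev == 0) {
    warning("degenerate translation-score distribution; TFZ set to 0",
            call. = FALSE)
    0
  } else {
    (scores[best[1]] - mean(scores)) / sdev
  }
  id <- if (is(fragment, "Fragment")) fragment@id else "model"
  lapply(best[seq_len(min(topN, length(best)))], function(i) {
    Placement(id, rotation, tg[i, ], fr$center,
              tfz = tfz, cc = 100 * scores[i])
  })
}

#' Place a fragment model in the cell
#'
#' Applies a placement: model coordinates are centred, rotated, expressed
#' in fractional coordinates and shifted by the placement translation.
#'
#' @param fragment a \linkS4class{Fragment} or model (must be the one the
#'   placement was computed from, or share its centroid convention).
#' @param placement a \linkS4class{Placement}.
#' @param cell,spacegroup crystal frame of the placed model.
#' @return a \linkS4class{StructureModel} in Cartesian coordinates.
#' @export
applyPlacement <- function(fragment, placement, cell, spacegroup) {
  a <- atoms(fragModel(fragment))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, placement@center)
  M <- cellOrthMatrix(cell)
  frac <- (xyz %*% t(placement@rotation)) %*% t(solve(M))
  frac <- sweep(frac, 2, placement@translation, "+")
  cart <- frac %*% t(M)
  a$x <- cart[, 1]; a$y <- cart[, 2]; a$z <- cart[, 3]
  StructureModel(a, cell = cell, spacegroup = spacegroup)
}

#' Packing filter for a candidate placement
#'
#' Rejects a placement when more than `maxClashFrac` of its C-alpha atoms
#' lie closer than `clashDist` to any of its own symmetry copies or to any
#' previously placed model (including their symmetry copies), with
#' periodic images considered.
#'
#' @param placement candidate \linkS4class{Placement}.
#' @param fragment the fragment it places.
#' @param placed list of earlier accepted placements (with `fragments`
#'   giving the corresponding fragment for each, or a single shared one).
#' @param fragmentsPlaced list of fragments matching `placed`.
#' @param data \linkS4class{ReflectionSet} supplying cell and symmetry.
#' @param clashDist clash distance in angstroms (default 3).
#' @param maxClashFrac maximum tolerated clashing fraction (default 0.05).
#' @return TRUE (accept) or FALSE (reject).
#' @export
packFilter <- function(placement, fragment, placed = list(),
                       fragmentsPlaced = list(), data, clashDist = 3.0,
                       maxClashFrac = 0.05) {
  sg <- spaceGroupInfo(data@spacegroup)
  M <- cellOrthMatrix(data@cell)
  caFrac <- function(frag, pl) {
    m <- applyPlacement(frag, pl, data@cell, data@spacegroup)
    a <- atoms(m)
    as.matrix(a[a$name == "CA", c("x", "y", "z")]) %*% t(solve(M))
  }
  self <- caFrac(fragment, placement)
  ## symmetry + periodic images of a fractional coordinate set
  images <- function(frac, skipIdentity = FALSE) {
    out <- list()
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (k in seq_along(sg$ops)) {
      if (skipIdentity && k == 1) next
      o <- sg$ops[[k]]
      base <- frac %*% t(o$R)
      base <- sweep(base, 2, o$t, "+")
      for (si in seq_len(nrow(shifts))) {
        out[[length(out) + 1]] <- sweep(base, 2, as.numeric(shifts[si, ]), "+")
      }
    }
    out
  }
  minDistToSet <- function(fracA, fracSets) {
    cartA <- fracA %*% t(M)
    apply(cartA, 1, function(p) {
      mind <- Inf
      for (fs in fracSets) {
        cartB <- fs %*% t(M)
        d2 <- colSums((t(cartB) - p)^2)
        mind <- min(mind, sqrt(min(d2)))
      }
      mind
    })
  }
  targets <- images(self, skipIdentity = TRUE)
  ## identity op with non-zero lattice shifts is also a clash partner
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  for (si in seq_len(nrow(shifts))) {
    targets[[length(targets) + 1]] <-
      sweep(self, 2, as.numeric(shifts[si, ]), "+")
  }
  for (j in seq_along(placed)) {
    fr <- if (length(fragmentsPlaced)) fragmentsPlaced[[j]] else fragment
    targets <- c(targets, images(caFrac(fr, placed[[j]])))
  }
  if (!length(targets)) return(TRUE)
  dmin <- minDistToSet(self, targets)
  mean(dmin < clashDist) <= maxClashFrac
}

## correlation of |Fcalc| for a placed model with observed amplitudes
.placementScore <- function(fragment, rotation, translation, center, rec,
                            cell, sg, fobs) {
  a <- atoms(fragModel(fragment))
  xyz <- sweep(as.matrix(a[, c("x", "y", "z")]), 2, center)
  M <- cellOrthMatrix(cell)
  frac <- (xyz %*% t(rotation)) %*% t(solve(M))
  frac <- sweep(frac, 2, translation, "+")
  ff <- .ffCoefsFor(a$element)
  Fc <- cpp_structure_factors(
    as.matrix(rec[, c("h", "k", "l")]) * 1.0, 1 / (2 * rec$d), frac,
    a$occ, a$b, ff$idx, ff$a, ff$b,
    lapply(sg$ops, function(o) o$R * 1.0), lapply(sg$ops, `[[`, "t"))
  fc <- Mod(Fc)
  if (stats::sd(fc) == 0 || stats::sd(fobs) == 0) return(0)
  stats::cor(fc, fobs)
}

#' Rigid-body refinement of a placement
#'
#' Derivative-free local maximization (Nelder-Mead) of the
#' amplitude-correlation target over the six rigid-body parameters
#' (three rotation perturbation angles, three fractional translations).
#' The refined score never falls below the input score.
#'
#' @param placement starting \linkS4class{Placement}.
#' @param fragment the fragment it places.
#' @param data a \linkS4class{ReflectionSet} with `F` or `I`.
#' @param maxIter iteration budget (default 200 function evaluations).
#' @param dminSearch optional high-resolution cutoff.
#' @return the refined \linkS4class{Placement} (input returned unchanged
#'   if no improvement is found).
#' @export
rigidRefine <- function(placement, fragment, data, maxIter = 200,
                        dminSearch = NULL) {
  rec <- .searchPrep(data, dminSearch)
  fobs <- rec$F %||% sqrt(pmax(rec$I, 0))
  sg <- spaceGroupInfo(data@spacegroup)
  R0 <- placement@rotation
  t0 <- placement@translation
  ctr <- placement@center
  obj <- function(p) {
    dR <- eulerToMatrix(p[1], p[2], p[3])
    -.placementScore(fragment, dR %*% R0, t0 + p[4:6], ctr, rec,
                     data@cell, sg, fobs)
  }
  s0 <- -obj(rep(0, 6))
  fit <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                      control = list(maxit = maxIter,
                                     parscale = c(2, 2, 2, 0.01, 0.01, 0.01),
                                     reltol = 1e-6))
  if (-fit$value <= s0 + 1e-12) {
    placement@cc <- 100 * s0
    return(placement)
  }
  p <- fit$par
  Placement(placement@fragmentId, eulerToMatrix(p[1], p[2], p[3]) %*% R0,
            t0 + p[4:6], ctr, rfScore = placement@rfScore,
            tfz = placement@tfz, cc = 100 * -fit$value,
            llg = placement@llg)
}

#' Likelihood-gain-style placement score
#'
#' Rice-likelihood score of a placed model against normalized amplitudes:
#' \eqn{\sum_h [\log Rice(E_o; \sigma_A E_c) - \log Wilson(E_o)]}, with
#' the centric analogue (Woolfson) for centric reflections and
#' \eqn{\sigma_A(s) = \sqrt{f_n}\,e^{-2\pi^2 rmsd^2 s^2/3}} as in
#' [ellgModelSize()].  Zero when \eqn{\sigma_A = 0} (null model); higher
#' is better.
#'
#' @param placement a \linkS4class{Placement}.
#' @param fragment the fragment it places.
#' @param data a \linkS4class{ReflectionSet} with `E` values.
#' @param rmsdEst expected coordinate error of the model in angstroms.
#' @param totalResidues ordered residues in the asymmetric unit (sets the
#'   scattering fraction `f_n`).
#' @return scalar score.
#' @export
llgProxy <- function(placement, fragment, data, rmsdEst, totalResidues) {
  rec <- .searchPrep(data, needE = TRUE)
  placedModel <- applyPlacement(fragment, placement, data@cell,
                                data@spacegroup)
  idx <- ReflectionSet(rec[, c("h", "k", "l", "d", "centric", "epsilon")],
                       data@cell, data@spacegroup)
  calc <- structureFactors(placedModel, idx)
  crec <- reflections(normalizeE(calc))
  eo <- rec$E
  ec <- crec$E
  fn <- min(1, nResidues(fragModel(fragment)) / totalResidues)
  s2 <- 1 / rec$d^2
  sigA <- sqrt(fn) * exp(-2 * pi^2 * rmsdEst^2 * s2 / 3)
  sigA <- pmin(sigA, 0.999)
  one <- 1 - sigA^2
  X <- 2 * eo * sigA * ec / one
  logI0 <- function(x) log(besselI(x, 0, expon.scaled = TRUE)) + x
  logCosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)
  ll <- ifelse(rec$centric,
    -0.5 * log(one) - (eo^2 + sigA^2 * ec^2) / (2 * one) + eo^2 / 2 +
      logCosh(X / 2),
    -log(one) - (eo^2 + sigA^2 * ec^2) / one + eo^2 + logI0(X))
  sum(ll)
}
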