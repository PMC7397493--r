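## Synthetic MicroED experiments: ideal-geometry ground-truth folds,
## smoothly perturbed homologues, and multi-crystal wedge datasets with
## per-frame radiation damage, per-crystal scale/B differences and
## Gaussian measurement noise.

withSeed <- function(seed, expr) {
  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  force(expr)
}

## torsion angles producing a tight reversal between consecutive helices;
## chosen once for compactness, absence of steric clashes, and distinctly
## non-parallel helix axes (50-90 degree crossing angles) so the fold has
## no rotational pseudo-symmetry
.turnTorsions <- matrix(c(
   123,  117,
   119,   43,
   -60,  -95,
   116, -179
), ncol = 2, byrow = TRUE)

#' Generate an ideal-geometry ground-truth fold
#'
#' Builds a compact polyalanine fold (an antiparallel helix bundle or a
#' strand sheet with tight turns) from ideal backbone geometry, places it
#' at a generic position in the asymmetric unit of the requested cell with
#' a seeded random orientation, and verifies that symmetry copies do not
#' clash.
#'
#' @param nResidues chain length.
#' @param motif "helix_bundle" or "strand_sheet".
#' @param cell numeric length-6 cell.
#' @param spacegroup Hermann-Mauguin symbol.
#' @param seed RNG seed (orientation); the fold itself is deterministic.
#' @param bFactor uniform isotropic B in square angstroms (default 10).
#' @param centerFrac fractional position of the molecular centroid; when
#'   `NULL` (default) the position maximizing the closest symmetry
#'   contact is found by a deterministic grid search.
#' @param minContact minimum allowed distance to any symmetry copy
#'   (default 3 angstroms).
#' @return a \linkS4class{StructureModel} with cell and space group set.
#' @export
makeGroundTruth <- function(nResidues, motif = c("helix_bundle",
                                                 "strand_sheet"),
                            cell, spacegroup, seed = 1, bFactor = 10,
                            centerFrac = NULL, minContact = 3.0) {
  motif <- match.arg(motif)
  sg <- spaceGroupInfo(spacegroup)
  segLen <- if (motif == "helix_bundle") 18L else 8L
  ss <- if (motif == "helix_bundle") c(-57, -47) else c(-120, 120)
  turnLen <- nrow(.turnTorsions)
  phi <- numeric(0); psi <- numeric(0)
  state <- "seg"; left <- segLen; ti <- 1
  for (i in seq_len(nResidues)) {
    if (state == "seg") {
      phi <- c(phi, ss[1]); psi <- c(psi, ss[2])
      left <- left - 1
      if (left == 0) { state <- "turn"; ti <- 1 }
    } else {
      phi <- c(phi, .turnTorsions[ti, 1]); psi <- c(psi, .turnTorsions[ti, 2])
      ti <- ti + 1
      if (ti > turnLen) { state <- "seg"; left <- segLen }
    }
  }
  atomsDf <- buildBackbone(phi, psi)
  xyz <- as.matrix(atomsDf[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  ## principal-axis alignment keeps the placement cell-friendly (longest
  ## molecular axis along c, the long cell edge); a small seeded
  ## perturbation rotation removes exact axis alignment without spoiling
  ## the packing
  ev <- eigen(stats::cov(xyz))
  pc <- ev$vectors[, order(ev$values)]  # largest-variance axis last (-> z)
  if (det(pc) < 0) pc[, 3] <- -pc[, 3]
  xyz0 <- xyz %*% pc
  M <- cellOrthMatrix(cell)
  ## the perturbation orientation is a nuisance parameter: if the seeded
  ## one cannot be packed, walk deterministically through further seeded
  ## orientations before giving up
  bestGap <- -Inf
  model <- NULL
  for (attempt in 0:19) {
    R <- withSeed(seed * 101 + attempt, {
      ax <- stats::rnorm(3)
      ax <- ax / sqrt(sum(ax^2))
      ang <- stats::runif(1, 2, 8) * pi / 180
      quatToMatrix(c(cos(ang / 2), sin(ang / 2) * ax))
    })
    xyz <- xyz0 %*% t(R)
    cf <- centerFrac
    if (is.null(cf)) {
      isCA <- atomsDf$name == "CA"
      cf <- .bestCenterFrac(xyz[isCA, , drop = FALSE], M, sg)
    }
    ctr <- as.numeric(M %*% cf)
    pos <- sweep(xyz, 2, ctr, "+")
    cand <- atomsDf
    cand$x <- pos[, 1]; cand$y <- pos[, 2]; cand$z <- pos[, 3]
    cand$b <- bFactor
    candModel <- StructureModel(cand, cell = cell, spacegroup = sg$symbol)
    gap <- minSymContact(candModel)
    if (gap > bestGap) {
      bestGap <- gap
      model <- candModel
    }
    if (bestGap >= minContact) break
    if (!is.null(centerFrac)) break  # fixed placement: no retries
  }
  if (bestGap < minContact) {
    need <- ceiling(max(cell[1:3]) * minContact / max(bestGap, 0.1))
    stop(sprintf(paste0("symmetry copies clash (closest contact %.2f A); ",
                        "use a larger cell (roughly %d A in the longest ",
                        "dimension) or a different centerFrac"),
                 bestGap, need), call. = FALSE)
  }
  model
}

## deterministic grid search (coarse, then refined) for the centroid
## position maximizing the closest symmetry contact of a point cloud
.bestCenterFrac <- function(xyz, M, sg) {
  Mi <- solve(M)
  contactAt <- function(fracCtr) {
    pts <- sweep(xyz, 2, as.numeric(M %*% fracCtr), "+")
    frac <- pts %*% t(Mi)
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    cart0 <- frac %*% t(M)
    best <- Inf
    for (k in seq_along(sg$ops)) {
      o <- sg$ops[[k]]
      img <- sweep(frac %*% t(o$R), 2, o$t, "+")
      for (si in seq_len(nrow(shifts))) {
        if (k == 1 && all(shifts[si, ] == 0)) next
        cart <- sweep(img, 2, as.numeric(shifts[si, ]), "+") %*% t(M)
        d2 <- outer(rowSums(cart0^2), rowSums(cart^2), "+") -
          2 * cart0 %*% t(cart)
        best <- min(best, min(d2))
      }
    }
    sqrt(max(best, 0))
  }
  searchGrid <- function(center, span, step) {
    ax <- lapply(1:3, function(i) {
      v <- seq(center[i] - span, center[i] + span, by = step)
      v[v >= 0 & v <= 0.5]
    })
    g <- as.matrix(expand.grid(ax))
    vals <- apply(g, 1, contactAt)
    g[which.max(vals), ]
  }
  best <- searchGrid(c(0.25, 0.25, 0.25), 0.25, 0.1)
  best <- searchGrid(best, 0.08, 0.04)
  as.numeric(searchGrid(best, 0.03, 0.015))
}

## closest approach between a model and its non-identity symmetry/lattice
## copies
minSymContact <- function(model) {
  sg <- spaceGroupInfo(model@spacegroup)
  M <- cellOrthMatrix(model@cell)
  a <- atoms(model)
  frac <- as.matrix(a[, c("x", "y", "z")]) %*% t(solve(M))
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- Inf
  cart0 <- frac %*% t(M)
  for (k in seq_along(sg$ops)) {
    o <- sg$ops[[k]]
    img <- sweep(frac %*% t(o$R), 2, o$t, "+")
    for (si in seq_len(nrow(shifts))) {
      if (k == 1 && all(shifts[si, ] == 0)) next
      cart <- sweep(img, 2, as.numeric(shifts[si, ]), "+") %*% t(M)
      ## block-wise min distance
      d2 <- outer(rowSums(cart0^2), rowSums(cart^2), "+") -
        2 * cart0 %*% t(cart)
      best <- min(best, sqrt(max(min(d2), 0)))
    }
  }
  best
}

#' Perturb a model into a synthetic distant homologue
#'
#' Applies smoothly correlated coordinate noise (a sum of random
#' low-frequency sinusoidal modes along the chain) scaled so that the
#' C-alpha r.m.s.d. to the input, after superposition, hits the target
#' within 5 percent; optionally deletes contiguous loop stretches.
#'
#' @param model the input \linkS4class{StructureModel}.
#' @param targetRmsd target C-alpha r.m.s.d. in angstroms.
#' @param loopDeletionFraction fraction of residues removed in contiguous
#'   stretches (default 0).
#' @param seed RNG seed.
#' @param nModes number of sinusoidal modes per axis (default 4).
#' @return the perturbed \linkS4class{StructureModel}.
#' @export
perturbHomologue <- function(model, targetRmsd, loopDeletionFraction = 0,
                             seed = 1, nModes = 4) {
  stopifnot(targetRmsd >= 0)
  a <- atoms(model)
  reskey <- paste(a$chain, a$resno, sep = "\r")
  resIds <- unique(reskey)
  n <- length(resIds)
  out <- withSeed(seed, {
    u <- (match(reskey, resIds) - 1) / max(n - 1, 1)
    disp <- matrix(0, nrow(a), 3)
    if (targetRmsd > 0) {
      for (ax in 1:3) {
        for (k in seq_len(nModes)) {
          f <- stats::runif(1, 0.5, 2.5)
          ph <- stats::runif(1, 0, 2 * pi)
          amp <- stats::rnorm(1) / k
          disp[, ax] <- disp[, ax] + amp * sin(2 * pi * f * u + ph)
        }
      }
      ## iterate the scale: superposition absorbs part of the displacement
      scale <- targetRmsd / max(sqrt(mean(rowSums(disp^2))), 1e-9)
      for (it in 1:6) {
        cand <- a
        cand[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + scale * disp
        pm <- StructureModel(cand, cell = model@cell,
                             spacegroup = model@spacegroup)
        got <- superposeModels(pm, model, coreCutoff = Inf)@rmsd
        if (abs(got - targetRmsd) <= 0.05 * targetRmsd) break
        scale <- scale * targetRmsd / max(got, 1e-9)
      }
      a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + scale * disp
    }
    if (loopDeletionFraction > 0) {
      nDel <- round(loopDeletionFraction * n)
      if (nDel > 0) {
        start <- sample(max(n - nDel, 1), 1)
        del <- resIds[start:(start + nDel - 1)]
        a <- a[!reskey %in% del, , drop = FALSE]
      }
    }
    a
  })
  StructureModel(out, cell = model@cell, spacegroup = model@spacegroup)
}

#' Simulation configuration
#'
#' Assembles (and defaults) the parameters of a synthetic multi-crystal
#' MicroED experiment.  Defaults describe the study conditions used
#' throughout the package's own tests: a 60-residue helix bundle in
#' P43212, 2.5 angstrom data, six crystals of ten frames each with
#' 70-degree wedges, 10 percent relative Gaussian noise, modest
#' per-crystal scale/B spreads and no damage unless requested.
#'
#' @param nResidues,motif,cell,spacegroup,dmin ground-truth and data
#'   parameters.
#' @param nCrystals,framesPerCrystal,wedgeWidth,missingConeHalf crystal
#'   geometry (degrees for angles).
#' @param noiseFraction relative Gaussian noise on intensities.
#' @param scaleRange,bRange per-crystal uniform ranges (scale;
#'   square-angstrom B).
#' @param damageOnset first damaged frame (Inf disables damage).
#' @param damageRate decay rate per frame per \eqn{s^2}.
#' @param commonAxis force a common crystal orientation (default FALSE).
#' @param seed master RNG seed.
#' @return a named list.
#' @export
simulationConfig <- function(nResidues = 60, motif = "helix_bundle",
                             cell = c(48, 48, 68, 90, 90, 90),
                             spacegroup = "P43212", dmin = 2.5,
                             nCrystals = 6, framesPerCrystal = 10,
                             wedgeWidth = 70, missingConeHalf = 0,
                             noiseFraction = 0.1,
                             scaleRange = c(0.7, 1.4), bRange = c(0, 4),
                             damageOnset = Inf, damageRate = 0,
                             commonAxis = FALSE, seed = 1) {
  list(nResidues = nResidues, motif = motif, cell = cell,
       spacegroup = spacegroup, dmin = dmin, nCrystals = nCrystals,
       framesPerCrystal = framesPerCrystal, wedgeWidth = wedgeWidth,
       missingConeHalf = missingConeHalf, noiseFraction = noiseFraction,
       scaleRange = scaleRange, bRange = bRange, damageOnset = damageOnset,
       damageRate = damageRate, commonAxis = commonAxis, seed = seed)
}

#' Simulate a multi-crystal MicroED dataset
#'
#' Computes ground-truth electron structure factors, then lets each
#' crystal observe the symmetry-expanded reflections whose scattering
#' vectors fall inside its rotation wedge (minus the missing cone), in a
#' seeded random orientation per crystal.  Observed intensities are
#' \eqn{I = k\,e^{-2Bs^2}\,damage(frame)\,|F|^2 (1+\epsilon)} with
#' relative Gaussian noise \eqn{\epsilon} and resolution-dependent
#' exponential damage \eqn{damage = e^{-rate\,(frame-onset)^+ s^2}} on
#' late frames.
#'
#' @param config list from [simulationConfig()].
#' @param groundTruth optional \linkS4class{StructureModel} overriding the
#'   built-in generator.
#' @return list with `series` (list of \linkS4class{CrystalSeries}),
#'   `truth` (a \linkS4class{ReflectionSet} with F, phase and noise-free
#'   I), `phases` (truth \linkS4class{PhaseSet}), `model` (the ground
#'   truth) and `config`.
#' @export
simulateCrystals <- function(config = simulationConfig(),
                             groundTruth = NULL) {
  cfg <- config
  model <- groundTruth %||% makeGroundTruth(cfg$nResidues, cfg$motif,
                                            cfg$cell, cfg$spacegroup,
                                            seed = cfg$seed)
  refl <- generateReflections(cfg$cell, cfg$spacegroup, cfg$dmin)
  truth <- structureFactors(model, refl)
  trec <- reflections(truth)
  trec$I <- trec$F^2
  trec$sigI <- pmax(cfg$noiseFraction, 1e-4) * pmax(trec$I, stats::median(trec$I))
  truth <- ReflectionSet(trec, cfg$cell, cfg$spacegroup)
  sg <- spaceGroupInfo(cfg$spacegroup)
  S <- recipMatrix(cfg$cell)
  ## symmetry + Friedel expansion with back-pointers to the unique set
  h0 <- as.matrix(trec[, c("h", "k", "l")])
  exp1 <- do.call(rbind, lapply(sg$ops, function(o) h0 %*% o$R))
  expAll <- rbind(exp1, -exp1)
  parent <- rep(seq_len(nrow(h0)), times = 2 * length(sg$ops))
  dup <- duplicated(expAll)
  expAll <- expAll[!dup, , drop = FALSE]
  parent <- parent[!dup]
  svec <- expAll %*% t(S)
  s2 <- rowSums(svec^2) / 4  # (1/(2d))^2
  series <- withSeed(cfg$seed + 1, {
    lapply(seq_len(cfg$nCrystals), function(ci) {
      U <- if (cfg$commonAxis) diag(3) else randomRotations(1)[[1]]
      v <- svec %*% t(U)
      wedgeStart <- stats::runif(1, 0, 180)
      scale <- stats::runif(1, cfg$scaleRange[1], cfg$scaleRange[2])
      brel <- stats::runif(1, cfg$bRange[1], cfg$bRange[2])
      ## azimuth about the rotation (lab x) axis; flat-Ewald sweep covers
      ## 180 degrees per half-turn
      phi <- (atan2(v[, 3], v[, 2]) * 180 / pi - wedgeStart) %% 180
      inWedge <- phi <= cfg$wedgeWidth
      if (cfg$missingConeHalf > 0) {
        coneAxis <- U %*% c(0, 0, 1)
        cosang <- abs(v %*% coneAxis) / sqrt(rowSums(v^2))
        inWedge <- inWedge & (acos(pmin(cosang, 1)) * 180 / pi >
                              cfg$missingConeHalf)
      }
      idx <- which(inWedge)
      if (!length(idx)) {
        warning("crystal ", ci, ": wedge too narrow, no reflections",
                call. = FALSE)
        return(CrystalSeries(sprintf("xtal%02d", ci),
                             data.frame(frame = integer(0), h = integer(0),
                                        k = integer(0), l = integer(0),
                                        I = numeric(0), sigI = numeric(0))))
      }
      frame <- pmin(1L + floor(phi[idx] / cfg$wedgeWidth *
                               cfg$framesPerCrystal),
                    cfg$framesPerCrystal)
      pIdx <- parent[idx]
      decay <- exp(-2 * brel * s2[idx])
      dmg <- exp(-cfg$damageRate * pmax(frame - cfg$damageOnset, 0) * s2[idx])
      Iexp <- scale * decay * dmg * trec$I[pIdx]
      eps <- if (cfg$noiseFraction > 0) {
        stats::rnorm(length(idx), 0, cfg$noiseFraction)
      } else 0
      Iobs <- Iexp * (1 + eps)
      sigI <- pmax(cfg$noiseFraction * abs(Iexp),
                   1e-6 * (stats::median(trec$I) + 1))
      f <- data.frame(frame = frame, h = expAll[idx, 1], k = expAll[idx, 2],
                      l = expAll[idx, 3], I = Iobs, sigI = sigI)
      CrystalSeries(sprintf("xtal%02d", ci), f)
    })
  })
  phases <- PhaseSet(data.frame(h = trec$h, k = trec$k, l = trec$l,
                                phase = trec$phase, fom = 1),
                     cfg$cell, cfg$spacegroup)
  list(series = series, truth = truth, phases = phases, model = model,
       config = cfg)
}
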