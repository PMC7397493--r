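## End-to-end workflow: simulate (or load) data, shred a homologue,
## search, score, report.  The Rscript front end in inst/scripts wraps
## these functions for shell use.

#' Positional agreement of a placed model with the ground truth
#'
#' Minimum C-alpha r.m.s.d. (pairing by residue number) between a placed
#' model and a reference structure, over all symmetry operators, allowed
#' origin shifts and integer lattice translations -- the set of
#' equivalences under which a molecular-replacement solution is the same
#' solution.
#'
#' @param placed,reference \linkS4class{StructureModel} objects on the
#'   same crystal frame (cell/space group from `reference`).
#' @return minimum r.m.s.d. in angstroms.
#' @export
placementRmsd <- function(placed, reference) {
  sg <- spaceGroupInfo(reference@spacegroup)
  M <- cellOrthMatrix(reference@cell)
  Mi <- solve(M)
  pa <- atoms(placed); ra <- atoms(reference)
  pca <- pa[pa$name == "CA", , drop = FALSE]
  rca <- ra[ra$name == "CA", , drop = FALSE]
  common <- intersect(pca$resno, rca$resno)
  if (length(common) < 3) stop("fewer than 3 shared residues", call. = FALSE)
  P <- as.matrix(pca[match(common, pca$resno), c("x", "y", "z")]) %*% t(Mi)
  Q <- as.matrix(rca[match(common, rca$resno), c("x", "y", "z")]) %*% t(Mi)
  qc <- colMeans(Q)
  polar <- sg$polarAxes
  best <- Inf
  for (o in sg$ops) {
    base <- sweep(P %*% t(o$R), 2, o$t, "+")
    for (si in seq_len(nrow(sg$originShifts))) {
      img <- sweep(base, 2, sg$originShifts[si, ], "+")
      ## integer lattice alignment on fixed axes; free alignment on polar
      ## axes (where any origin is allowed)
      lat <- qc - colMeans(img)
      lat[!polar] <- round(lat[!polar])
      img <- sweep(img, 2, lat, "+")
      d2 <- rowSums(((img - Q) %*% t(M))^2)
      best <- min(best, sqrt(mean(d2)))
    }
  }
  best
}

#' Default pipeline configuration
#'
#' @param seed master seed.
#' @param outDir optional output directory for reports and artifacts.
#' @param simulate arguments for [simulationConfig()].
#' @param homologueRmsd perturbation applied to make the search template.
#' @param shred list with `sizeMin`, `sizeMax`, `step`.
#' @param search list with `rotStep`, `dminRot`, `nClusters`, `maxModels`,
#'   `stepFrac`.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(seed = 1, outDir = NULL, simulate = list(),
                           homologueRmsd = 1.0,
                           shred = list(sizeMin = 15, sizeMax = 25, step = 4),
                           search = list(rotStep = 12, rotBand = c(10, 3.5),
                                         nRotRefl = 1000, nClusters = 2,
                                         maxModels = 4, stepFrac = 1 / 24,
                                         dminRefine = 3.0)) {
  simulate$seed <- simulate$seed %||% seed
  list(seed = seed, outDir = outDir,
       simulate = do.call(simulationConfig, simulate),
       homologueRmsd = homologueRmsd, shred = shred, search = search)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the fragment-phasing workflow end to end
#'
#' Simulates a multi-crystal dataset from a ground truth, merges it,
#' shreds a perturbed homologue into a sequential fragment library, runs
#' the rotation search on the whole template, clusters rotation peaks,
#' scores every fragment at the cluster orientations to build the
#' Shred-LLG profile, selects derived models, places them by translation
#' search with rigid-body refinement and packing control, and evaluates
#' every accepted placement (CC, TFZ, likelihood score, wMPE against the
#' simulation's true phases, and positional r.m.s.d. against the ground
#' truth).
#'
#' @param config list from [pipelineConfig()].
#' @return (invisibly) a report list with elements `merge` (statistics),
#'   `nFragments`, `placements` (data.frame), `best` (best placement
#'   summary) and `config`; JSON/TSV copies are written to
#'   `config$outDir` when set.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  cfg <- config
  sim <- .stage("simulate", simulateCrystals(cfg$simulate))
  mr <- .stage("merge", {
    scaled <- scaleSeries(sim$series, cfg$simulate$cell,
                          cfg$simulate$spacegroup)
    mergeSeries(scaled, cfg$simulate$cell, cfg$simulate$spacegroup,
                dmin = cfg$simulate$dmin)
  })
  data <- .stage("normalize", {
    rec <- reflections(mr)
    rec$F <- sqrt(pmax(rec$I, 0))
    normalizeE(ReflectionSet(rec, cfg$simulate$cell,
                             cfg$simulate$spacegroup))
  })
  homologue <- .stage("homologue", {
    if (cfg$homologueRmsd > 0) {
      perturbHomologue(sim$model, cfg$homologueRmsd, seed = cfg$seed + 7)
    } else sim$model
  })
  library <- .stage("shred", {
    lib <- sequentialFragments(homologue, cfg$shred$sizeMin,
                               cfg$shred$sizeMax, cfg$shred$step,
                               templateId = "homologue")
    if (!length(lib)) stop("empty fragment library")
    lib
  })
  sr <- cfg$search
  ## rotation functions run on a band-limited copy of the data: the lowest
  ## resolution terms are dominated by inter-molecule interference that a
  ## single-copy transform cannot model
  dataRot <- .stage("normalize", {
    rec <- reflections(data)
    rec <- rec[rec$d <= sr$rotBand[1] & rec$d >= sr$rotBand[2], ,
               drop = FALSE]
    normalizeE(ReflectionSet(rec, data@cell, data@spacegroup))
  })
  placements <- .stage("search", {
    template <- toPolyalanine(homologue)
    rot <- rotationSearch(template, dataRot, rotStep = sr$rotStep,
                          topN = 40, nRefl = sr$nRotRefl,
                          refineTop = 8, rescoreTop = 60)
    reps <- lapply(seq_len(nrow(rot)), function(i)
      eulerToMatrix(rot$alpha[i], rot$beta[i], rot$gamma[i]))
    clusters <- clusterRotations(reps, rot$score, toleranceDeg = 15,
                                 spacegroup = data@spacegroup,
                                 cell = data@cell)
    clusters <- clusters[seq_len(min(sr$nClusters, length(clusters)))]
    repRots <- lapply(clusters, `[[`, "representative")
    ## Shred-LLG: score every fragment at the cluster orientations
    frs <- fragments(library)
    fragScores <- vapply(frs, function(f) {
      max(scoreRotations(f, dataRot, repRots))
    }, numeric(1))
    names(fragScores) <- vapply(frs, function(f) f@id, character(1))
    prof <- shredProfile(library, fragScores)
    models <- selectModels(prof, homologue, maxModels = sr$maxModels)
    if (!length(models)) stop("no models selected from the shred profile")
    accepted <- list(); acceptedFrags <- list()
    total <- nResidues(sim$model)
    for (f in fragments(models)) {
      for (ci in seq_along(repRots)) {
        rfs <- scoreRotations(f, dataRot, repRots[ci])
        pls <- translationSearch(f, repRots[[ci]], data,
                                 stepFrac = sr$stepFrac, topN = 1)
        pl <- pls[[1]]
        pl@rfScore <- rfs[1]
        pl <- rigidRefine(pl, f, data, maxIter = 80,
                          dminSearch = sr$dminRefine)
        if (!packFilter(pl, f, accepted, acceptedFrags, data)) next
        pl@llg <- llgProxy(pl, f, data, rmsdEst = cfg$homologueRmsd,
                           totalResidues = total)
        accepted[[length(accepted) + 1]] <- pl
        acceptedFrags[[length(acceptedFrags) + 1]] <- f
      }
    }
    if (!length(accepted)) stop("no placement passed the packing filter")
    list(placements = accepted, frags = acceptedFrags)
  })
  report <- .stage("score", {
    rows <- lapply(seq_along(placements$placements), function(i) {
      pl <- placements$placements[[i]]
      f <- placements$frags[[i]]
      placedModel <- applyPlacement(f, pl, data@cell, data@spacegroup)
      ## figure-of-merit weights from the sigma-A model: the wMPE of a
      ## partial model is conventionally FOM-weighted
      ps <- phasesFromModel(placedModel, data, rmsdEst = cfg$homologueRmsd,
                            totalResidues = nResidues(sim$model))
      wm <- wmpe(ps, sim$phases)
      eul <- matrixToEuler(pl@rotation)
      data.frame(fragment = pl@fragmentId, nres = nResidues(f),
                 alpha = eul[1], beta = eul[2], gamma = eul[3],
                 tx = pl@translation[1], ty = pl@translation[2],
                 tz = pl@translation[3], rf = pl@rfScore, tfz = pl@tfz,
                 cc = pl@cc, llg = pl@llg, wmpe = wm$wmpe,
                 rmsdToTruth = placementRmsd(placedModel, sim$model))
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$cc), ]
    rownames(tab) <- NULL
    list(
      merge = list(completeness = mr@completeness,
                   multiplicity = mr@multiplicity,
                   meanIoverSig = mr@meanIoverSig, ccHalf = mr@ccHalf,
                   nUnique = nrow(reflections(mr))),
      nFragments = length(library),
      placements = tab,
      best = as.list(tab[1, ]),
      config = cfg
    )
  })
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report[c("merge", "nFragments", "best")],
                         file.path(cfg$outDir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    utils::write.table(report$placements,
                       file.path(cfg$outDir, "placements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cfg, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         force = TRUE)
  }
  invisible(report)
}
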