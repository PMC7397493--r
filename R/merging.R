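## MicroED data-reduction heuristics: per-crystal scaling, CC1/2,
## damage-frame omission, inverse-variance merging and minimal-crystal
## merge-set selection.

## map observations to canonical unique indices; returns the frames table
## with h,k,l replaced by the symmetry-unique representative
.toUnique <- function(frames, sg) {
  if (!nrow(frames)) return(frames)
  can <- canonicalHKL(as.matrix(frames[, c("h", "k", "l")]), sg)
  frames$h <- as.integer(can[, 1])
  frames$k <- as.integer(can[, 2])
  frames$l <- as.integer(can[, 3])
  frames
}

obsTable <- function(series, sg) {
  do.call(rbind, lapply(series, function(cs) {
    f <- .toUnique(cs@frames, sg)
    f$crystal <- cs@id
    f
  }))
}

#' Scale crystals onto a reference
#'
#' Per crystal, fits a linear scale and relative B factor minimizing
#' \eqn{\sum (I_{ref} - k e^{-2Bs^2} I)^2} over reflections shared with
#' the reference crystal, and applies the correction to intensities and
#' sigmas.  Crystals sharing fewer than `minCommon` reflections with the
#' reference are left unscaled with a warning.
#'
#' @param series list of \linkS4class{CrystalSeries}.
#' @param cell,spacegroup crystal frame (for unique-index mapping and
#'   resolution).
#' @param reference index of the reference crystal (default 1).
#' @param minCommon minimum shared unique reflections (default 10).
#' @return list of scaled \linkS4class{CrystalSeries} (scale/bRel slots
#'   record the fitted parameters).
#' @export
scaleSeries <- function(series, cell, spacegroup, reference = 1,
                        minCommon = 10) {
  sg <- spaceGroupInfo(spacegroup)
  mergeOne <- function(cs) {
    f <- .toUnique(cs@frames, sg)
    key <- paste(f$h, f$k, f$l, sep = ",")
    I <- tapply(f$I, key, mean)
    data.frame(key = names(I), I = as.numeric(I),
               d = dSpacing(do.call(rbind, lapply(strsplit(names(I), ","),
                                                  as.numeric)), cell))
  }
  ref <- mergeOne(series[[reference]])
  out <- series
  for (i in seq_along(series)) {
    if (i == reference) next
    cur <- mergeOne(series[[i]])
    m <- merge(ref, cur, by = "key", suffixes = c(".ref", ".cur"))
    if (nrow(m) < minCommon) {
      warning("crystal '", series[[i]]@id, "' shares only ", nrow(m),
              " reflections with the reference; left unscaled",
              call. = FALSE)
      next
    }
    s2 <- 1 / (2 * m$d.ref)^2
    ## linearize: log(Iref/Icur) = log k - 2 B s^2 on positive pairs
    ok <- m$I.ref > 0 & m$I.cur > 0
    if (sum(ok) < minCommon) {
      warning("crystal '", series[[i]]@id,
              "' has too few positive common intensities; left unscaled",
              call. = FALSE)
      next
    }
    fit0 <- stats::lm(log(m$I.ref[ok] / m$I.cur[ok]) ~ I(-2 * s2[ok]))
    start <- c(k = exp(unname(stats::coef(fit0)[1])),
               B = unname(stats::coef(fit0)[2]))
    obj <- function(p) {
      sum((m$I.ref - p[1] * exp(-2 * p[2] * s2) * m$I.cur)^2)
    }
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    k <- fit$par[1]; B <- fit$par[2]
    f <- out[[i]]@frames
    sObs2 <- 1 / (2 * dSpacing(as.matrix(f[, c("h", "k", "l")]), cell))^2
    corr <- k * exp(-2 * B * sObs2)
    f$I <- f$I * corr
    f$sigI <- f$sigI * corr
    out[[i]] <- CrystalSeries(out[[i]]@id, f, scale = unname(k),
                              bRel = unname(B))
  }
  out
}

#' Half-dataset correlation CC1/2
#'
#' Randomly splits each unique reflection's observations into two halves
#' (seeded) and returns the Pearson correlation of the half-set mean
#' intensities over reflections represented in both halves.
#'
#' @param obs data.frame of observations with columns `h`, `k`, `l`, `I`
#'   (already mapped to unique indices), or a list of
#'   \linkS4class{CrystalSeries}.
#' @param spacegroup needed when `obs` is a series list.
#' @param seed RNG seed for the half-split (default 17).
#' @return CC1/2 (dimensionless).
#' @export
ccHalf <- function(obs, spacegroup = NULL, seed = 17) {
  if (is.list(obs) && !is.data.frame(obs)) {
    obs <- obsTable(obs, spaceGroupInfo(spacegroup))
  }
  key <- paste(obs$h, obs$k, obs$l, sep = ",")
  groups <- split(obs$I, key)
  ## seeded split without disturbing the caller's RNG stream
  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  h1 <- numeric(0); h2 <- numeric(0)
  for (g in groups) {
    if (length(g) < 2) next
    pick <- sample(length(g), floor(length(g) / 2))
    h1 <- c(h1, mean(g[pick]))
    h2 <- c(h2, mean(g[-pick]))
  }
  if (length(h1) < 3) stop("fewer than 3 reflections with observations in ",
                           "both halves", call. = FALSE)
  if (stats::sd(h1) == 0 && stats::sd(h2) == 0 && all(h1 == h2)) {
    ## identical constant halves: perfectly reproducible
    return(1)
  }
  if (stats::sd(h1) == 0 || stats::sd(h2) == 0) return(NA_real_)
  stats::cor(h1, h2)
}

#' Omit radiation-damaged trailing frames
#'
#' Greedy emulation of damage trimming: while fewer than `maxOmit` frames
#' have been dropped and removing the current last frame strictly
#' increases CC1/2 of the remaining observations, drop it.
#'
#' @param series a \linkS4class{CrystalSeries}, or a list of them (each
#'   crystal is trimmed independently from its own end).
#' @param spacegroup Hermann-Mauguin symbol.
#' @param maxOmit maximum frames to drop (default 6).
#' @param seed seed for the CC1/2 half-splits.
#' @return the trimmed series (same type as input), with attribute
#'   `omitted` giving the number of dropped frames (a vector for list
#'   input) and `ccTrace` the CC1/2 sequence (initial value first).
#' @export
omitDamageFrames <- function(series, spacegroup, maxOmit = 6, seed = 17) {
  if (!is(series, "CrystalSeries")) {
    out <- lapply(series, omitDamageFrames, spacegroup = spacegroup,
                  maxOmit = maxOmit, seed = seed)
    attr(out, "omitted") <- vapply(out, attr, integer(1), which = "omitted")
    return(out)
  }
  sg <- spaceGroupInfo(spacegroup)
  ccOf <- function(cs) {
    tryCatch(ccHalf(obsTable(list(cs), sg), seed = seed),
             error = function(e) NA_real_)
  }
  cur <- series
  trace <- ccOf(cur)
  omitted <- 0L
  while (omitted < maxOmit && length(unique(cur@frames$frame)) > 1) {
    lastFrame <- max(cur@frames$frame)
    cand <- CrystalSeries(cur@id,
                          cur@frames[cur@frames$frame < lastFrame, ,
                                     drop = FALSE],
                          cur@scale, cur@bRel)
    ccNew <- ccOf(cand)
    if (is.na(ccNew) || is.na(trace[length(trace)]) ||
        ccNew <= trace[length(trace)]) break
    cur <- cand
    omitted <- omitted + 1L
    trace <- c(trace, ccNew)
  }
  attr(cur, "omitted") <- omitted
  attr(cur, "ccTrace") <- trace
  cur
}

#' Merge multi-crystal observations
#'
#' Maps observations to the asymmetric unit, merges by inverse-variance
#' weighting, and computes the standard statistics: completeness against
#' the theoretical unique set, multiplicity, mean I/sigma, CC1/2 and an
#' outer-shell block (equal-count shells).
#'
#' @param series list of \linkS4class{CrystalSeries}.
#' @param cell,spacegroup crystal frame.
#' @param dmin,dmax resolution range of the theoretical set.
#' @param nShells shells for the statistics table (default 20).
#' @param seed seed for CC1/2 splits.
#' @return a \linkS4class{MergeResult}.
#' @export
mergeSeries <- function(series, cell, spacegroup, dmin, dmax = Inf,
                        nShells = 20, seed = 17) {
  if (!length(series)) stop("no crystals to merge", call. = FALSE)
  sg <- spaceGroupInfo(spacegroup)
  theo <- reflections(generateReflections(cell, spacegroup, dmin,
                                          if (is.finite(dmax)) dmax else 1e6))
  obs <- obsTable(series, sg)
  obs$d <- dSpacing(as.matrix(obs[, c("h", "k", "l")]), cell)
  obs <- obs[obs$d >= dmin & obs$d <= dmax, , drop = FALSE]
  if (!nrow(obs)) stop("no observations in resolution range", call. = FALSE)
  key <- paste(obs$h, obs$k, obs$l, sep = ",")
  w <- 1 / obs$sigI^2
  mergedI <- tapply(obs$I * w, key, sum) / tapply(w, key, sum)
  mergedSig <- sqrt(1 / tapply(w, key, sum))
  nobs <- tapply(w, key, length)
  hkl <- do.call(rbind, lapply(strsplit(names(mergedI), ","), as.numeric))
  rec <- data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                    l = as.integer(hkl[, 3]),
                    I = as.numeric(mergedI), sigI = as.numeric(mergedSig),
                    nobs = as.integer(nobs))
  rec$d <- dSpacing(as.matrix(rec[, c("h", "k", "l")]), cell)
  cls <- .reflClass(as.matrix(rec[, c("h", "k", "l")]), sg)
  rec$centric <- cls$centric
  rec$epsilon <- cls$epsilon
  ## restrict to the theoretical set (drops absences / out-of-range strays)
  tkey <- paste(theo$h, theo$k, theo$l, sep = ",")
  rec <- rec[paste(rec$h, rec$k, rec$l, sep = ",") %in% tkey, , drop = FALSE]
  rec <- rec[order(-rec$d), ]
  completeness <- 100 * nrow(rec) / nrow(theo)
  multiplicity <- sum(rec$nobs) / nrow(rec)
  meanIsig <- mean(rec$I / rec$sigI)
  cc <- tryCatch(ccHalf(obs, seed = seed), error = function(e) NA_real_)
  ## shell table
  sh <- assignShells(rec$d, nShells)
  shtab <- do.call(rbind, lapply(sort(unique(sh)), function(s) {
    r <- rec[sh == s, ]
    shObs <- obs[paste(obs$h, obs$k, obs$l, sep = ",") %in%
                 paste(r$h, r$k, r$l, sep = ","), ]
    theoShell <- sum(theo$d <= max(r$d) + 1e-9 & theo$d >= min(r$d) - 1e-9)
    data.frame(shell = s, dmax = max(r$d), dmin = min(r$d),
               n = nrow(r),
               completeness = 100 * nrow(r) / max(theoShell, nrow(r)),
               meanIoverSig = mean(r$I / r$sigI),
               ccHalf = tryCatch(ccHalf(shObs, seed = seed),
                                 error = function(e) NA_real_))
  }))
  merged <- ReflectionSet(rec, cell, sg$symbol, dmin,
                          if (is.finite(dmax)) dmax else max(rec$d))
  new("MergeResult", merged = merged, ccHalf = cc,
      meanIoverSig = meanIsig, completeness = completeness,
      multiplicity = multiplicity, nCrystals = length(series),
      shells = shtab)
}

#' Select the minimal merge set
#'
#' Exhaustively enumerates non-empty crystal subsets (up to `maxCrystals`
#' crystals), keeps those whose merged completeness exceeds `threshold`,
#' and among them picks the smallest subset, breaking ties by the highest
#' merged mean I/sigma.  When no subset passes, the full set is returned
#' with a warning.
#'
#' @param series list of \linkS4class{CrystalSeries}.
#' @param cell,spacegroup,dmin,dmax as for [mergeSeries()].
#' @param threshold completeness threshold in percent (default 90).
#' @param maxCrystals enumeration cap (default 16).
#' @param seed seed for CC1/2 splits.
#' @return list with `selection` (crystal ids), `result` (the
#'   \linkS4class{MergeResult} of the winning subset) and `table`
#'   (per-subset completeness and I/sigma for the subsets evaluated).
#' @export
selectMergeSet <- function(series, cell, spacegroup, dmin, dmax = Inf,
                           threshold = 90, maxCrystals = 16, seed = 17) {
  n <- length(series)
  if (n > maxCrystals) {
    stop("exhaustive enumeration capped at ", maxCrystals, " crystals",
         call. = FALSE)
  }
  ids <- vapply(series, function(cs) cs@id, character(1))
  subsets <- lapply(seq_len(2^n - 1), function(m) which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
  tab <- data.frame(subset = vapply(subsets, function(s)
    paste(ids[s], collapse = "+"), character(1)),
    size = lengths(subsets), completeness = NA_real_,
    meanIoverSig = NA_real_)
  results <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    mr <- mergeSeries(series[subsets[[i]]], cell, spacegroup, dmin, dmax,
                      nShells = 1, seed = seed)
    results[[i]] <- mr
    tab$completeness[i] <- mr@completeness
    tab$meanIoverSig[i] <- mr@meanIoverSig
  }
  pass <- which(tab$completeness > threshold)
  if (!length(pass)) {
    warning("no subset exceeds ", threshold, "% completeness; ",
            "returning the full set", call. = FALSE)
    best <- which(tab$size == n)
  } else {
    minSize <- min(tab$size[pass])
    candIdx <- pass[tab$size[pass] == minSize]
    best <- candIdx[which.max(tab$meanIoverSig[candIdx])]
  }
  list(selection = ids[subsets[[best]]], result = results[[best]],
       table = tab)
}

#' Read per-crystal observations from TSV
#'
#' Whitespace table with columns `frame h k l I sigI`.
#'
#' @param path input path.
#' @param id crystal identifier (default: file base name).
#' @return a \linkS4class{CrystalSeries}.
#' @export
readCrystalTSV <- function(path, id = NULL) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  need <- c("frame", "h", "k", "l", "I", "sigI")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "), call. = FALSE)
  CrystalSeries(id %||% sub("\\.[^.]*$", "", basename(path)), tab)
}

#' Write per-crystal observations as TSV
#' @param series a \linkS4class{CrystalSeries}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCrystalTSV <- function(series, path) {
  utils::write.table(series@frames[, c("frame", "h", "k", "l", "I", "sigI")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
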