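## Solution-quality metrics: weighted mean phase error (origin- and
## enantiomorph-aware), amplitude correlation, Fourier synthesis and
## omit-map difference peaks.

circDiffDeg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Phases of a model
#'
#' Computes structure factors of `model` on the indices of `refl` and
#' returns the phases as a \linkS4class{PhaseSet}.  By default the
#' figures of merit are 1; when `rmsdEst` and `totalResidues` are given
#' (and `refl` carries observed `E` values), per-reflection figures of
#' merit are attached from the sigma-A model:
#' \eqn{m = I_1(X)/I_0(X)} for acentrics and \eqn{\tanh(X/2)} for
#' centrics, with \eqn{X = 2 E_o \sigma_A E_c/(1-\sigma_A^2)} — the
#' standard expected cosine of the phase error for a partial model with
#' coordinate error.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param refl a \linkS4class{ReflectionSet}.
#' @param rmsdEst optional expected model coordinate error (angstroms).
#' @param totalResidues ordered residues in the asymmetric unit (sets
#'   the model's scattering fraction).
#' @return a \linkS4class{PhaseSet}.
#' @export
phasesFromModel <- function(model, refl, rmsdEst = NULL,
                            totalResidues = NULL) {
  idx <- reflections(refl)[, c("h", "k", "l", "d", "centric", "epsilon")]
  calc <- structureFactors(model, ReflectionSet(idx, refl@cell,
                                                refl@spacegroup))
  rec <- reflections(calc)
  fom <- rep(1, nrow(rec))
  obs <- reflections(refl)
  if (!is.null(rmsdEst) && !is.null(totalResidues) && !is.null(obs$E)) {
    ec <- reflections(normalizeE(calc))$E
    fn <- min(1, nResidues(model) / totalResidues)
    sigA <- pmin(sqrt(fn) * exp(-2 * pi^2 * rmsdEst^2 / (3 * rec$d^2)),
                 0.999)
    X <- 2 * obs$E * sigA * ec / (1 - sigA^2)
    i1i0 <- function(x) {
      r <- besselI(x, 1, expon.scaled = TRUE) /
        besselI(x, 0, expon.scaled = TRUE)
      ifelse(is.finite(r), r, 1)
    }
    fom <- ifelse(rec$centric, tanh(X / 2), i1i0(X))
    fom <- pmax(pmin(fom, 1), 0)
  }
  PhaseSet(data.frame(h = rec$h, k = rec$k, l = rec$l, phase = rec$phase,
                      fom = fom),
           refl@cell, refl@spacegroup)
}

#' Weighted mean phase error
#'
#' Computes \eqn{wMPE = \sum w |\Delta\phi|_{circ} / \sum w} over the
#' common index set, minimized over the allowed origin shifts of the
#' space group (including continuous polar axes, refined numerically) and
#' optionally the enantiomorph flip (phase negation).  Weights are the
#' figures of merit of the test set.
#'
#' @param test,reference \linkS4class{PhaseSet} objects on the same
#'   crystal frame.
#' @param enantiomorph also try the inverted-hand phase set (default TRUE).
#' @param polarStep grid step for polar-axis scanning (default 1/24).
#' @return list with `wmpe` (degrees), `shift` (the minimizing origin
#'   shift), `flipped` (logical), `n` (reflections compared).
#' @export
wmpe <- function(test, reference, enantiomorph = TRUE, polarStep = 1 / 24) {
  tr <- test@records
  rr <- reference@records
  key <- function(d) paste(d$h, d$k, d$l, sep = ",")
  idx <- match(key(tr), key(rr))
  sel <- which(!is.na(idx))
  if (!length(sel)) stop("no common reflections between phase sets",
                         call. = FALSE)
  H <- as.matrix(tr[sel, c("h", "k", "l")])
  w <- tr$fom[sel]
  if (all(w == 0)) w <- rep(1, length(sel))
  phT <- tr$phase[sel]
  phR <- rr$phase[idx[sel]]
  sg <- spaceGroupInfo(test@spacegroup)
  ## candidate origin shifts: discrete table x polar-axis grid
  polar <- sg$polarAxes
  axvals <- lapply(1:3, function(i) {
    if (polar[i]) seq(0, 1 - 1e-9, by = polarStep) else 0
  })
  pgrid <- as.matrix(expand.grid(axvals))
  cand <- do.call(rbind, lapply(seq_len(nrow(sg$originShifts)), function(i) {
    sweep(pgrid, 2, sg$originShifts[i, ], "+")
  }))
  costFor <- function(ph, shift) {
    sum(w * circDiffDeg(ph - 360 * as.numeric(H %*% shift), phR)) / sum(w)
  }
  evalAll <- function(ph) {
    costs <- vapply(seq_len(nrow(cand)), function(i)
      costFor(ph, cand[i, ]), numeric(1))
    b <- which.min(costs)
    shift <- cand[b, ]
    ## refine continuous axes
    if (any(polar)) {
      fn <- function(p) {
        s <- shift
        s[polar] <- p
        costFor(ph, s)
      }
      fit <- stats::optim(shift[polar], fn, method = "Nelder-Mead",
                          control = list(maxit = 200, reltol = 1e-8,
                                         warn.1d.NelderMead = FALSE))
      if (fit$value < costs[b]) {
        shift[polar] <- fit$par
        costs[b] <- fit$value
      }
    }
    list(cost = costs[b], shift = shift)
  }
  direct <- evalAll(phT)
  best <- c(direct, flipped = FALSE)
  if (enantiomorph) {
    flip <- evalAll((-phT) %% 360)
    if (flip$cost < direct$cost) best <- c(flip, flipped = TRUE)
  }
  list(wmpe = best$cost, shift = as.numeric(best$shift),
       flipped = best$flipped, n = length(sel))
}

#' Amplitude correlation coefficient
#'
#' 100 times the Pearson correlation of two amplitude sets over their
#' common indices (scale- and offset-invariant).
#'
#' @param a,b numeric amplitude vectors of equal length, or two
#'   \linkS4class{ReflectionSet} objects with `F` columns (matched on
#'   h,k,l).
#' @return percentage correlation.
#' @export
ampCC <- function(a, b) {
  if (is(a, "ReflectionSet")) {
    ra <- reflections(a); rb <- reflections(b)
    key <- function(d) paste(d$h, d$k, d$l, sep = ",")
    idx <- match(key(ra), key(rb))
    sel <- !is.na(idx)
    a <- ra$F[sel]
    b <- rb$F[idx[sel]]
  }
  if (length(a) < 3) stop("need at least 3 common amplitudes", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in amplitudes; CC set to 0", call. = FALSE)
    return(0)
  }
  100 * stats::cor(a, b)
}

## ---------------------------------------------------------------------------
## Fourier synthesis
## ---------------------------------------------------------------------------

## symmetry-expand (h, F, phase) to a full P1 index set
expandToP1 <- function(rec, sg) {
  h <- as.matrix(rec[, c("h", "k", "l")])
  out <- list()
  for (o in sg$ops) {
    h2 <- h %*% o$R
    ph2 <- rec$phase - 360 * as.numeric(h %*% o$t)
    out[[length(out) + 1]] <- data.frame(h = h2[, 1], k = h2[, 2],
                                         l = h2[, 3], F = rec$F,
                                         phase = ph2 %% 360)
  }
  full <- do.call(rbind, out)
  full <- rbind(full,
                data.frame(h = -full$h, k = -full$k, l = -full$l,
                           F = full$F, phase = (-full$phase) %% 360))
  full[!duplicated(full[, c("h", "k", "l")]), , drop = FALSE]
}

#' Fourier synthesis onto a cell-covering grid
#'
#' Inverse Fourier transform of (weighted) amplitudes and phases,
#' symmetry-expanded to P1, onto a real-space grid.  The map is
#' standardized to sigma units (mean 0, sd 1).
#'
#' @param refl a \linkS4class{ReflectionSet} with `F` and `phase`.
#' @param weights optional per-reflection weights (e.g. figures of merit).
#' @param gridSpacing target grid spacing in angstroms (default `dmin/3`).
#' @return a \linkS4class{MapGrid}.
#' @export
fourierMap <- function(refl, weights = NULL, gridSpacing = NULL) {
  rec <- reflections(refl)
  if (is.null(rec$F) || is.null(rec$phase)) {
    stop("amplitudes and phases required for synthesis", call. = FALSE)
  }
  if (!is.null(weights)) rec$F <- rec$F * weights
  sg <- spaceGroupInfo(refl@spacegroup)
  full <- expandToP1(rec, sg)
  cell <- refl@cell
  if (is.null(gridSpacing)) gridSpacing <- min(rec$d) / 3
  n <- pmax(4L, 2L * ceiling(cell[1:3] / gridSpacing / 2))
  hm <- apply(abs(as.matrix(full[, c("h", "k", "l")])), 2, max)
  if (any(hm * 2 >= n)) n <- pmax(n, 2L * (hm + 1L))
  arr <- array(0 + 0i, dim = n)
  idx <- cbind(full$h %% n[1], full$k %% n[2], full$l %% n[3]) + 1
  Fc <- full$F * exp(1i * full$phase * pi / 180)
  arr[idx] <- Conj(Fc)
  rho <- Re(stats::fft(arr, inverse = TRUE)) / cellVolume(cell)
  sdev <- stats::sd(rho)
  rho <- if (sdev > 0) (rho - mean(rho)) / sdev else rho - mean(rho)
  new("MapGrid", values = rho, cell = cell, spacegroup = refl@spacegroup)
}

#' Difference map coefficients and synthesis
#'
#' Builds `2mFo-Fc` or `Fo-Fc` coefficients from observed amplitudes and
#' model structure factors (matched on h,k,l) and synthesizes the map.
#' The figure of merit `m` weights Fo; it defaults to 1 (or to the `fom`
#' of `phases` when supplied).
#'
#' @param obs \linkS4class{ReflectionSet} with observed `F` (or `I`).
#' @param calc \linkS4class{ReflectionSet} with model `F` and `phase`.
#' @param kind "2mFo-Fc" or "Fo-Fc".
#' @param phases optional \linkS4class{PhaseSet} supplying figures of
#'   merit.
#' @param gridSpacing target grid spacing in angstroms.
#' @return a \linkS4class{MapGrid} in sigma units.
#' @export
differenceMap <- function(obs, calc, kind = c("2mFo-Fc", "Fo-Fc"),
                          phases = NULL, gridSpacing = NULL) {
  kind <- match.arg(kind)
  ro <- reflections(obs)
  if (is.null(ro$F)) ro$F <- sqrt(pmax(ro$I, 0))
  rc <- reflections(calc)
  if (is.null(rc$F) || is.null(rc$phase)) {
    stop("calc set must carry F and phase", call. = FALSE)
  }
  key <- function(d) paste(d$h, d$k, d$l, sep = ",")
  idx <- match(key(rc), key(ro))
  sel <- which(!is.na(idx))
  fo <- ro$F[idx[sel]]
  fc <- rc$F[sel]
  m <- rep(1, length(sel))
  if (!is.null(phases)) {
    pidx <- match(key(rc[sel, ]), key(phases@records))
    m[!is.na(pidx)] <- phases@records$fom[pidx[!is.na(pidx)]]
  }
  ## overall linear scale of Fo onto Fc
  k <- sum(fo * fc) / sum(fo^2)
  amp <- if (kind == "2mFo-Fc") 2 * m * k * fo - fc else k * fo - fc
  rec <- data.frame(h = rc$h[sel], k = rc$k[sel], l = rc$l[sel],
                    d = rc$d[sel], centric = rc$centric[sel],
                    epsilon = rc$epsilon[sel],
                    F = abs(amp),
                    phase = (rc$phase[sel] + ifelse(amp < 0, 180, 0)) %% 360)
  fourierMap(ReflectionSet(rec, obs@cell, obs@spacegroup),
             gridSpacing = gridSpacing)
}

#' Map value at a position
#'
#' Trilinear interpolation of a \linkS4class{MapGrid} at a Cartesian
#' position; positions outside the cell are wrapped by lattice
#' translations.
#'
#' @param map a \linkS4class{MapGrid}.
#' @param posCart Cartesian position (angstroms), length 3.
#' @return interpolated map value (sigma units).
#' @export
mapValueAt <- function(map, posCart) {
  n <- dim(map@values)
  M <- cellOrthMatrix(map@cell)
  frac <- wrapFrac(as.numeric(solve(M) %*% posCart))
  g <- frac * n
  i0 <- floor(g)
  f <- g - i0
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    ii <- (c(i0[1] + dx, i0[2] + dy, i0[3] + dz)) %% n + 1
    val <- val + w * map@values[ii[1], ii[2], ii[3]]
  }
  val
}

#' Omit-map peak height at a feature position
#'
#' Computes the `Fo-Fc` difference map from a model lacking a feature and
#' reports its value (in sigma units) at the feature position.
#'
#' @param modelWithout \linkS4class{StructureModel} lacking the feature.
#' @param data observed \linkS4class{ReflectionSet}.
#' @param featurePosCart Cartesian position of the omitted feature.
#' @param gridSpacing map grid spacing in angstroms.
#' @return list with `peak` (sigma units at the position), `maxMap`
#'   (global map maximum) and the `map` itself.
#' @export
omitPeakHeight <- function(modelWithout, data, featurePosCart,
                           gridSpacing = NULL) {
  calc <- structureFactors(modelWithout, data)
  map <- differenceMap(data, calc, kind = "Fo-Fc", gridSpacing = gridSpacing)
  list(peak = mapValueAt(map, featurePosCart), maxMap = max(map@values),
       map = map)
}

## ---------------------------------------------------------------------------
## phase-set I/O
## ---------------------------------------------------------------------------

#' Write a phase set as TSV
#' @param ps a \linkS4class{PhaseSet}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhaseSet <- function(ps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell %s", paste(format(ps@cell, digits = 15),
                                          collapse = " ")),
               sprintf("# spacegroup %s", ps@spacegroup)), con)
  utils::write.table(format(ps@records[, c("h", "k", "l", "phase", "fom")],
                            digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phase set from TSV
#' @param path input path.
#' @param cell,spacegroup crystal frame (read from header comments when
#'   absent).
#' @return a \linkS4class{PhaseSet}.
#' @export
readPhaseSet <- function(path, cell = NULL, spacegroup = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(cell)) {
    cl <- grep("^# cell ", lines, value = TRUE)
    if (length(cl)) cell <- as.numeric(strsplit(trimws(sub("^# cell ", "",
                                                           cl[1])), "\\s+")[[1]])
  }
  if (is.null(spacegroup)) {
    sl <- grep("^# spacegroup ", lines, value = TRUE)
    spacegroup <- if (length(sl)) trimws(sub("^# spacegroup ", "", sl[1]))
                  else "P1"
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  PhaseSet(tab, cell, spacegroup)
}
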