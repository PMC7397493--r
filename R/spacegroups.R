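## Space-group machinery for the groups the toolkit supports.
##
## Operator tables are hard-coded for P1, P21, P212121, P43212 and P41212 —
## the settings needed for protein MicroED work at this scale.  Unknown
## symbols are rejected loudly rather than half-supported.

.sgOps <- local({
  op <- function(r, t = c(0, 0, 0)) list(R = matrix(r, 3, 3, byrow = TRUE), t = t)
  I3 <- c(1, 0, 0, 0, 1, 0, 0, 0, 1)
  list(
    "P1" = list(op(I3)),
    "P21" = list( # unique axis b
      op(I3),
      op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 1 / 2, 0))
    ),
    "P212121" = list(
      op(I3),
      op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(1 / 2, 0, 1 / 2)),
      op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(1 / 2, 1 / 2, 0)),
      op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 1 / 2, 1 / 2))
    ),
    "P43212" = list(
      op(I3),
      op(c(0, -1, 0, 1, 0, 0, 0, 0, 1), c(1 / 2, 1 / 2, 3 / 4)),
      op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(0, 0, 1 / 2)),
      op(c(0, 1, 0, -1, 0, 0, 0, 0, 1), c(1 / 2, 1 / 2, 1 / 4)),
      op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(1 / 2, 1 / 2, 1 / 4)),
      op(c(0, -1, 0, -1, 0, 0, 0, 0, -1), c(0, 0, 1 / 2)),
      op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(1 / 2, 1 / 2, 3 / 4)),
      op(c(0, 1, 0, 1, 0, 0, 0, 0, -1), c(0, 0, 0))
    ),
    "P41212" = list(
      op(I3),
      op(c(0, -1, 0, 1, 0, 0, 0, 0, 1), c(1 / 2, 1 / 2, 1 / 4)),
      op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(0, 0, 1 / 2)),
      op(c(0, 1, 0, -1, 0, 0, 0, 0, 1), c(1 / 2, 1 / 2, 3 / 4)),
      op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(1 / 2, 1 / 2, 3 / 4)),
      op(c(0, -1, 0, -1, 0, 0, 0, 0, -1), c(0, 0, 1 / 2)),
      op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(1 / 2, 1 / 2, 1 / 4)),
      op(c(0, 1, 0, 1, 0, 0, 0, 0, -1), c(0, 0, 0))
    )
  )
})

## allowed origin shifts (discrete part) and polar axes per group
.sgOrigins <- list(
  "P1" = list(shifts = matrix(0, 1, 3), polar = c(TRUE, TRUE, TRUE)),
  "P21" = list(
    shifts = as.matrix(expand.grid(c(0, .5), 0, c(0, .5))),
    polar = c(FALSE, TRUE, FALSE)
  ),
  "P212121" = list(
    shifts = as.matrix(expand.grid(c(0, .5), c(0, .5), c(0, .5))),
    polar = c(FALSE, FALSE, FALSE)
  ),
  "P43212" = list(
    shifts = matrix(c(0, 0, 0, .5, .5, 0, 0, 0, .5, .5, .5, .5),
                    4, 3, byrow = TRUE),
    polar = c(FALSE, FALSE, FALSE)
  ),
  "P41212" = list(
    shifts = matrix(c(0, 0, 0, .5, .5, 0, 0, 0, .5, .5, .5, .5),
                    4, 3, byrow = TRUE),
    polar = c(FALSE, FALSE, FALSE)
  )
)

## order of the highest rotation about z in the point group (rotation-search
## alpha reduction) per group
.sgZOrder <- c("P1" = 1, "P21" = 1, "P212121" = 2, "P43212" = 4, "P41212" = 4)

normalizeSgSymbol <- function(symbol) {
  s <- gsub("[ _]", "", symbol)
  s <- sub("^p", "P", s)
  if (!s %in% names(.sgOps)) {
    stop("unsupported space group '", symbol, "'; supported symbols: ",
         paste(names(.sgOps), collapse = ", "), call. = FALSE)
  }
  s
}

#' Space-group description
#'
#' Operator table and derived symmetry information for a supported
#' Hermann-Mauguin symbol (P1, P21, P212121, P43212, P41212; spaces and
#' underscores in the symbol are ignored).
#'
#' @param symbol Hermann-Mauguin symbol.
#' @return list with elements `symbol`, `ops` (list of `R`/`t` pairs),
#'   `nsym`, `originShifts` (matrix of allowed discrete origin shifts),
#'   `polarAxes` (logical length 3), `zOrder`.
#' @export
spaceGroupInfo <- function(symbol) {
  s <- normalizeSgSymbol(symbol)
  list(symbol = s, ops = .sgOps[[s]], nsym = length(.sgOps[[s]]),
       originShifts = unname(as.matrix(.sgOrigins[[s]]$shifts)),
       polarAxes = .sgOrigins[[s]]$polar,
       zOrder = unname(.sgZOrder[[s]]))
}

#' Supported space-group symbols
#' @return character vector.
#' @export
supportedSpaceGroups <- function() names(.sgOps)

## reciprocal-space image of h under op: h' = h %*% R (row-index convention);
## F(h') = F(h) * exp(-2*pi*i * h.t)
symEquivalents <- function(hkl, sg) {
  hkl <- rbind(hkl)
  lapply(sg$ops, function(o) hkl %*% o$R)
}

## reflection classification against the operator table
.reflClass <- function(hkl, sg) {
  hkl <- rbind(hkl)
  n <- nrow(hkl)
  eps <- integer(n); centric <- logical(n); absent <- logical(n)
  Rs <- lapply(sg$ops, `[[`, "R")
  ts <- lapply(sg$ops, `[[`, "t")
  for (j in seq_along(Rs)) {
    hr <- hkl %*% Rs[[j]]
    fixed <- rowSums(abs(hr - hkl)) == 0
    eps <- eps + as.integer(fixed)
    centric <- centric | (rowSums(abs(hr + hkl)) == 0)
    ph <- as.numeric(hkl %*% ts[[j]])
    absent <- absent | (fixed & abs(ph - round(ph)) > 1e-9)
  }
  list(epsilon = eps, centric = centric, absent = absent)
}

## canonical symmetry-unique representative of each reflection (Friedel
## merged): the lexicographically largest equivalent by (h, k, l)
canonicalHKL <- function(hkl, sg) {
  hkl <- rbind(hkl)
  eq <- symEquivalents(hkl, sg)
  cand <- c(eq, lapply(eq, function(m) -m))
  best <- cand[[1]]
  key <- function(m) m[, 1] * 4e6 + m[, 2] * 2e3 + m[, 3]
  bk <- key(best)
  for (m in cand[-1]) {
    k <- key(m)
    swap <- k > bk
    best[swap, ] <- m[swap, , drop = FALSE]
    bk[swap] <- k[swap]
  }
  best
}

## Cartesian rotation parts of the point group (for rotation clustering)
pointGroupRotations <- function(sg, cell) {
  M <- cellOrthMatrix(cell)
  Mi <- solve(M)
  unique(lapply(sg$ops, function(o) M %*% o$R %*% Mi))
}
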