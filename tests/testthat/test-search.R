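## Small self-consistent search problems: data simulated from a known
## model, recovery checked against the known pose.

searchFixture <- function() {
  cached("searchFixture", function() {
    cellv <- c(26, 30, 34, 90, 90, 90)
    ## a helix-turn-helix piece: bent, so no slide-and-twist
    ## quasi-degeneracy muddies pose comparisons
    turns <- microshred:::.turnTorsions
    phi <- c(rep(-57, 8), turns[, 1], rep(-57, 6))
    psi <- c(rep(-47, 8), turns[, 2], rep(-47, 6))
    gt <- StructureModel(microshred:::buildBackbone(phi, psi))
    ## pose the helix at a known orientation/position inside the cell
    a <- atoms(gt)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, colMeans(xyz))
    Rtrue <- eulerToMatrix(40, 60, 20)
    xyz <- xyz %*% t(Rtrue)
    ctr <- c(13, 15, 17)
    xyz <- sweep(xyz, 2, ctr, "+")
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    posed <- StructureModel(a, cell = cellv, spacegroup = "P1")
    refl <- generateReflections(cellv, "P1", 3.0)
    sf <- structureFactors(posed, refl)
    rec <- reflections(sf)
    rec$I <- rec$F^2
    data <- normalizeE(ReflectionSet(rec, cellv, "P1"))
    frag <- StructureModel(atoms(gt))
    list(cell = cellv, truth = posed, data = data, Rtrue = Rtrue,
         frag = frag)
  })
}

test_that("the rotation search recovers a known orientation in P1", {
  fx <- searchFixture()
  rs <- rotationSearch(fx$frag, fx$data, rotStep = 24, topN = 20,
                       refineTop = 6)
  Rbest <- eulerToMatrix(rs$alpha[1], rs$beta[1], rs$gamma[1])
  expect_lt(rotationAngle(Rbest, fx$Rtrue), 15)
  ## and the truth orientation scores above the 95th grid percentile
  sTrue <- scoreRotations(fx$frag, fx$data, list(fx$Rtrue))
  expect_gt(sTrue, quantile(rs$score, 0.95) * 0.999)
})

test_that("a constant-intensity dataset scores zero everywhere", {
  fx <- searchFixture()
  rec <- reflections(fx$data)
  rec$E <- rep(1, nrow(rec))
  flat <- ReflectionSet(rec, fx$cell, "P1")
  sc <- scoreRotations(fx$frag, flat, list(diag(3), fx$Rtrue))
  expect_equal(sc, c(0, 0))
})

test_that("coarser than 30 degrees is refused", {
  fx <- searchFixture()
  expect_error(rotationSearch(fx$frag, fx$data, rotStep = 45),
               "30 degrees")
})

test_that("the translation search recovers a known position", {
  fx <- searchFixture()
  ## P1 has a fully polar origin: the domain is a single point and the
  ## score distribution is degenerate by construction
  pls <- suppressWarnings(
    translationSearch(fx$frag, fx$Rtrue, fx$data, topN = 3))
  pl <- pls[[1]]
  placed <- applyPlacement(fx$frag, pl, fx$cell, "P1")
  ## P1: any overall translation is equivalent, so judge by rmsd modulo
  ## lattice/symmetry equivalences
  expect_lt(placementRmsd(placed, fx$truth), 1.0)
  expect_gt(pl@cc, 90)
  expect_true(is.finite(pl@tfz))
})

test_that("self-amplitudes give perfect correlation at the truth pose", {
  fx <- searchFixture()
  a <- atoms(fx$frag)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  M <- cellOrthMatrix(fx$cell)
  tfrac <- as.numeric(solve(M) %*% c(13, 15, 17))
  sc <- microshred:::.placementScore(fx$frag, fx$Rtrue, tfrac, ctr,
                                     reflections(fx$data), fx$cell,
                                     spaceGroupInfo("P1"),
                                     reflections(fx$data)$F)
  expect_equal(sc, 1.0, tolerance = 1e-9)
})

test_that("a wrong rotation scores lower than the right one", {
  fx <- searchFixture()
  right <- suppressWarnings(
    translationSearch(fx$frag, fx$Rtrue, fx$data, topN = 1))[[1]]
  wrongR <- eulerToMatrix(45, 0, 0) %*% fx$Rtrue
  wrong <- suppressWarnings(
    translationSearch(fx$frag, wrongR, fx$data, topN = 1))[[1]]
  expect_gt(right@cc, wrong@cc)
})

test_that("the packing filter accepts isolated and rejects duplicate poses", {
  sim <- miniSim()
  data <- sim$truth
  poly <- toPolyalanine(sim$model)
  fr <- microshred:::fragAtomsCentered(poly)
  M <- cellOrthMatrix(data@cell)
  tfrac <- as.numeric(solve(M) %*% fr$center)
  pl <- Placement("m", diag(3), tfrac, fr$center)
  expect_true(packFilter(pl, poly, list(), list(), data))
  expect_false(packFilter(pl, poly, list(pl), list(poly), data))
})

test_that("a marginal clash fraction under 5 percent is accepted", {
  ## two 30-residue straight helices placed so exactly one CA pair clashes
  cellv <- c(200, 200, 200, 90, 90, 90)
  h <- helixModel(30)
  a <- atoms(h)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  a[, c("x", "y", "z")] <- sweep(xyz, 2, c(100, 100, 100), "+")
  m1 <- StructureModel(a, cell = cellv, spacegroup = "P1")
  rec <- data.frame(h = 1, k = 0, l = 0, d = 200, centric = FALSE,
                    epsilon = 1L, F = 1, I = 1)
  data <- ReflectionSet(rec, cellv, "P1")
  fr <- microshred:::fragAtomsCentered(m1)
  M <- cellOrthMatrix(cellv)
  t0 <- as.numeric(solve(M) %*% fr$center)
  pl0 <- Placement("a", diag(3), t0, fr$center)
  ## second copy placed end-to-end: its first CA sits 2 A beyond the
  ## first copy's last CA, so exactly one CA pair clashes (1/30 = 3.3%)
  ca <- as.matrix(atoms(m1)[atoms(m1)$name == "CA", c("x", "y", "z")])
  axis <- ca[30, ] - ca[1, ]
  axis <- axis / sqrt(sum(axis^2))
  shift <- (ca[30, ] - ca[1, ]) + 2.0 * axis
  pl1 <- Placement("b", diag(3), t0 + as.numeric(solve(M) %*% shift),
                   fr$center)
  caB <- sweep(ca, 2, shift, "+")
  nClash <- sum(vapply(1:30, function(i) {
    any(sqrt(rowSums(sweep(ca, 2, caB[i, ], "-")^2)) < 3)
  }, logical(1)))
  expect_equal(nClash, 1)
  expect_true(packFilter(pl1, m1, list(pl0), list(m1), data))
})

test_that("rigid refinement never lowers the score and recovers offsets", {
  fx <- searchFixture()
  a <- atoms(fx$frag)
  ctr <- colMeans(as.matrix(a[, c("x", "y", "z")]))
  M <- cellOrthMatrix(fx$cell)
  tTrue <- as.numeric(solve(M) %*% c(13, 15, 17))
  ## start at truth: stays there
  at <- Placement("f", fx$Rtrue, tTrue, ctr)
  r0 <- rigidRefine(at, fx$frag, fx$data, maxIter = 40)
  expect_gte(r0@cc, 99.9)
  ## start displaced: must improve and approach truth
  off <- Placement("f", eulerToMatrix(3, 2, -3) %*% fx$Rtrue,
                   tTrue + c(0.03, -0.02, 0.03), ctr)
  sc0 <- microshred:::.placementScore(fx$frag, off@rotation,
                                      off@translation, ctr,
                                      reflections(fx$data), fx$cell,
                                      spaceGroupInfo("P1"),
                                      reflections(fx$data)$F)
  ref <- rigidRefine(off, fx$frag, fx$data, maxIter = 400)
  expect_gte(ref@cc, 100 * sc0)
  before <- placementRmsd(applyPlacement(fx$frag, off, fx$cell, "P1"),
                          fx$truth)
  after <- placementRmsd(applyPlacement(fx$frag, ref, fx$cell, "P1"),
                         fx$truth)
  expect_lt(after, before)
})

test_that("the likelihood score vanishes for a null model and ranks poses", {
  fx <- searchFixture()
  a <- atoms(fx$frag)
  ctr <- colMeans(as.matrix(a[, c("x", "y", "z")]))
  M <- cellOrthMatrix(fx$cell)
  tTrue <- as.numeric(solve(M) %*% c(13, 15, 17))
  right <- Placement("f", fx$Rtrue, tTrue, ctr)
  ## rmsd -> infinity drives sigmaA, and the score, to zero
  expect_equal(llgProxy(right, fx$frag, fx$data, rmsdEst = 1e4,
                        totalResidues = 14), 0, tolerance = 1e-8)
  llgRight <- llgProxy(right, fx$frag, fx$data, rmsdEst = 0.3,
                       totalResidues = 14)
  set.seed(17)
  worse <- 0
  for (i in 1:5) {
    rnd <- Placement("f", randomRotations(1)[[1]], runif(3), ctr)
    llgRnd <- llgProxy(rnd, fx$frag, fx$data, rmsdEst = 0.3,
                       totalResidues = 14)
    worse <- worse + (llgRight > llgRnd)
  }
  expect_equal(worse, 5)
})

test_that("the likelihood score grows with model completeness", {
  fx <- searchFixture()
  M <- cellOrthMatrix(fx$cell)
  ntot <- nResidues(fx$truth)
  scores <- vapply(c(6, 12, ntot), function(n) {
    sub <- StructureModel(atoms(fx$truth)[atoms(fx$truth)$resno <= n, ],
                          cell = fx$cell, spacegroup = "P1")
    fr <- microshred:::fragAtomsCentered(sub)
    pl <- Placement("s", diag(3), as.numeric(solve(M) %*% fr$center),
                    fr$center)
    llgProxy(pl, sub, fx$data, rmsdEst = 0.2, totalResidues = ntot)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})
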