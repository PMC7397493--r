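test_that("sequential shredding enumerates the expected windows", {
  m <- helixModel(30)
  lib <- sequentialFragments(m, 10, 12, 4)
  ## sizes 10,11,12 on the 1,5,9,... grid: 6 + 5 + 5 windows
  expect_equal(length(lib), 16)
  sizes <- vapply(fragments(lib), nResidues, numeric(1))
  expect_equal(sum(sizes == 10), 6)
  expect_equal(sum(sizes == 11), 5)
  expect_equal(sum(sizes == 12), 5)
})

test_that("fragment counts follow the closed form on break-free chains", {
  set.seed(21)
  for (i in 1:5) {
    L <- sample(25:60, 1)
    smin <- sample(8:12, 1)
    smax <- smin + sample(0:6, 1)
    step <- sample(1:5, 1)
    lib <- sequentialFragments(helixModel(L), smin, smax, step)
    expected <- sum(vapply(smin:smax, function(s) {
      if (s > L) 0 else floor((L - s) / step) + 1
    }, numeric(1)))
    expect_equal(length(lib), expected,
                 info = sprintf("L=%d s=%d..%d step=%d", L, smin, smax, step))
  }
})

test_that("whole-chain window gives exactly one fragment", {
  m <- helixModel(14)
  lib <- sequentialFragments(m, 14, 14, 3)
  expect_equal(length(lib), 1)
  expect_equal(nResidues(fragments(lib)[[1]]), 14)
})

test_that("invalid shred parameters are rejected", {
  m <- helixModel(20)
  expect_error(sequentialFragments(m, 12, 10), "parameter")
  expect_error(sequentialFragments(m, 5, 10, step = 0), "parameter")
})

test_that("omit fragments complement their extracted window", {
  m <- helixModel(24)
  ext <- sequentialFragments(m, 10, 10, 4, kind = "extract")
  omt <- sequentialFragments(m, 10, 10, 4, kind = "omit")
  expect_equal(length(ext), length(omt))
  for (i in seq_along(fragments(ext))) {
    re <- unique(atoms(fragments(ext)[[i]])$resno)
    ro <- unique(atoms(fragments(omt)[[i]])$resno)
    expect_equal(sort(c(re, ro)), 1:24)
    expect_length(intersect(re, ro), 0)
  }
})

test_that("chain breaks restart the shred grid", {
  a <- atoms(helixModel(30))
  a <- a[!a$resno %in% 15:16, ]  # gap splits 30 into 14 + 14
  lib <- sequentialFragments(StructureModel(a), 10, 10, 4)
  ## each 14-residue segment: starts 1 and 5 -> 2 fragments
  expect_equal(length(lib), 4)
})

test_that("rotation clustering merges close and separates distant poses", {
  r0 <- diag(3)
  r10 <- eulerToMatrix(10, 0, 0)
  cl <- clusterRotations(list(r0, r10), c(1, 0.5), toleranceDeg = 15)
  expect_length(cl, 1)
  r170 <- eulerToMatrix(170, 0, 0)
  cl2 <- clusterRotations(list(r0, r170), c(1, 0.5), toleranceDeg = 15)
  expect_length(cl2, 2)
})

test_that("greedy clustering matches a brute-force oracle", {
  set.seed(33)
  rots <- randomRotations(50)
  scores <- runif(50)
  cl <- clusterRotations(rots, scores, toleranceDeg = 30)
  ## independent greedy pass with explicit loops
  ord <- order(-scores)
  reps <- list(); assign <- integer(50)
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (rotationAngle(rots[[i]], reps[[ci]]) <= 30) {
        assign[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) { reps[[length(reps) + 1]] <- rots[[i]]
                   assign[i] <- length(reps) }
  }
  expect_equal(length(cl), length(reps))
  sizes <- sort(vapply(cl, function(c) length(c$members), numeric(1)))
  expect_equal(sizes, sort(as.numeric(table(assign))))
})

test_that("symmetry-equivalent rotations fall into one cluster", {
  ## fourfold about z in a tetragonal frame: Rz(90) is equivalent to identity
  cl <- clusterRotations(list(diag(3), eulerToMatrix(90, 0, 0)), c(1, 0.9),
                         toleranceDeg = 5, spacegroup = "P43212",
                         cell = c(48, 48, 68, 90, 90, 90))
  expect_length(cl, 1)
})

test_that("the shred profile z-scores within size groups", {
  m <- helixModel(30)
  lib <- sequentialFragments(m, 10, 11, 4)
  ids <- vapply(fragments(lib), function(f) f@id, character(1))
  ## constant scores give an all-zero profile
  prof <- shredProfile(lib, setNames(rep(5, length(ids)), ids))
  expect_equal(prof@profile$score, rep(0, nrow(prof@profile)))
  ## shifting one size group uniformly changes nothing
  sizes <- vapply(fragments(lib), nResidues, numeric(1))
  sc <- setNames(seq_along(ids) * 1.0, ids)
  sc2 <- sc
  sc2[sizes == 10] <- sc2[sizes == 10] * 3 + 100
  p1 <- shredProfile(lib, sc)
  p2 <- shredProfile(lib, sc2)
  expect_equal(p1@profile$score, p2@profile$score, tolerance = 1e-12)
})

test_that("per-residue profile values match hand computation", {
  m <- helixModel(20)
  lib <- sequentialFragments(m, 12, 12, 4)  # windows at 1, 5, 9
  ids <- vapply(fragments(lib), function(f) f@id, character(1))
  sc <- setNames(c(1, 2, 6), ids)
  prof <- shredProfile(lib, sc)
  z <- (c(1, 2, 6) - 3) / sd(c(1, 2, 6))
  ## residue 1-4 only in window 1; residue 10-12 in all three
  p <- prof@profile
  expect_equal(p$score[p$resno == 2], z[1])
  expect_equal(p$score[p$resno == 10], mean(z))
  expect_equal(p$score[p$resno == 6], mean(z[1:2]))
})

test_that("model selection covers the documented rules", {
  m <- helixModel(40)
  lib <- sequentialFragments(m, 10, 10, 2)
  ids <- vapply(fragments(lib), function(f) f@id, character(1))
  starts <- vapply(fragments(lib), function(f) min(atoms(f)$resno),
                   numeric(1))
  ## flat profile: every residue at the maximum; one whole-chain model
  flat <- shredProfile(lib, setNames(rep(1, length(ids)) + 0 * starts, ids))
  ml <- selectModels(flat, m)
  expect_equal(length(ml), 1)
  expect_equal(nResidues(fragments(ml)[[1]]), 40)
  ## triangular profile: the 75% rule equals brute-force thresholding
  tri <- shredProfile(lib, setNames(-abs(starts - median(starts)), ids))
  mt <- selectModels(tri, m)
  p <- tri@profile$score
  pn <- (p - min(p)) / diff(range(p))
  want <- tri@profile$resno[pn >= 0.75]
  got <- lapply(fragments(mt), function(f) unique(atoms(f)$resno))
  expect_true(any(vapply(got, function(g) identical(sort(g), sort(want)),
                         logical(1))))
  expect_lte(length(mt), 4)
})

test_that("spherical fragments are compact and size-controlled", {
  m <- helixModel(20)
  lib <- sphericalFragments(m, 10)
  expect_gt(length(lib), 0)
  for (f in fragments(lib)) {
    expect_lte(abs(nResidues(f) - 10), 10)
    ## a straight helix makes spatial neighbours sequence neighbours
    expect_equal(nrow(f@spans), 1)
  }
  ## whole-chain target gives the whole chain
  whole <- sphericalFragments(m, 20)
  expect_equal(length(whole), 1)
  expect_equal(nResidues(fragments(whole)[[1]]), 20)
  expect_error(sphericalFragments(m, 2, minContig = 3), "minContig")
})

test_that("spherical neighbourhoods cross chain topology", {
  ## the compact bundle ground truth brings distinct helices together
  gt <- miniTruth()
  lib <- sphericalFragments(gt, 18)
  multi <- vapply(fragments(lib), function(f) nrow(f@spans) > 1, logical(1))
  expect_true(any(multi))
  ## verify one centre against an explicit distance sort
  ca <- atoms(gt)[atoms(gt)$name == "CA", ]
  D <- as.matrix(dist(as.matrix(ca[, c("x", "y", "z")])))
  near <- ca$resno[order(D[1, ])][1:18]
  f1 <- fragments(lib)[[1]]
  ## fragment residues must be drawn from the 28 nearest (18 + growth margin)
  near28 <- ca$resno[order(D[1, ])][1:28]
  expect_true(all(unique(atoms(f1)$resno) %in% near28))
})

test_that("eLLG model sizing matches a brute-force scan and is monotone", {
  refl <- generateReflections(c(48, 48, 68, 90, 90, 90), "P43212", 2.0)
  rec <- reflections(refl)
  n30 <- ellgModelSize(refl, rmsdEst = 1.0, totalResidues = 100,
                       targetEllg = 30)
  ## brute-force oracle from the definition
  s2 <- 1 / rec$d^2
  sigA4 <- function(n) ((n / 100) * exp(-2 * pi^2 * 1.0^2 * s2 / 3)^2)^2
  ellg <- function(n) sum(ifelse(rec$centric, 1 / 4, 1 / 2) * sigA4(n))
  oracle <- which(vapply(1:100, ellg, numeric(1)) >= 30)[1]
  expect_equal(n30, oracle)
  ## monotone in the target
  n60 <- ellgModelSize(refl, rmsdEst = 1.0, totalResidues = 100,
                       targetEllg = 60)
  expect_gte(n60, n30)
  ## rmsd -> 0, f_n = 1 limit: eLLG = N_ac/2 + N_c/4
  lim <- sum(ifelse(rec$centric, 1 / 4, 1 / 2))
  n <- ellgModelSize(refl, rmsdEst = 0, totalResidues = 50,
                     targetEllg = lim * 0.999)
  expect_equal(n, 50)
  expect_warning(
    ellgModelSize(refl, rmsdEst = 2.0, totalResidues = 10,
                  targetEllg = 1e6), "unreachable")
})
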