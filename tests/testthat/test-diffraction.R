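test_that("P1 reflection generation equals brute-force enumeration", {
  cellv <- c(10, 10, 10, 90, 90, 90)
  r <- generateReflections(cellv, "P1", 5, 100)
  g <- as.matrix(expand.grid(h = -2:2, k = -2:2, l = -2:2))
  g <- g[rowSums(abs(g)) > 0, ]
  g <- g[dSpacing(g, cellv) >= 5, ]
  expect_equal(nrow(reflections(r)), nrow(g) / 2)  # one per Friedel pair
})

test_that("degenerate resolution ranges are not errors", {
  r <- generateReflections(tinyCell, "P1", 10, 10)
  expect_s4_class(r, "ReflectionSet")
  expect_true(all(abs(reflections(r)$d - 10) < 1e-9))
})

test_that("systematically absent reflections never appear", {
  r <- reflections(generateReflections(c(48, 48, 68, 90, 90, 90),
                                       "P43212", 5))
  sg <- spaceGroupInfo("P43212")
  keys <- paste(r$h, r$k, r$l, sep = ",")
  can <- function(v) paste(microshred:::canonicalHKL(rbind(v), sg),
                           collapse = ",")
  expect_false(can(c(0, 0, 2)) %in% keys)
  expect_true(can(c(0, 0, 4)) %in% keys)
  expect_false(can(c(1, 0, 0)) %in% keys)
})

test_that("structure factors reduce to the form factor for one atom", {
  at <- data.frame(element = "C", name = "CA", resno = 1, resname = "ALA",
                   chain = "A", x = 0, y = 0, z = 0, occ = 1, b = 0)
  m <- StructureModel(at, cell = tinyCell, spacegroup = "P1")
  refl <- generateReflections(tinyCell, "P1", 3, 30)
  sf <- reflections(structureFactors(m, refl))
  expect_equal(sf$F, electronFormFactor("C", 1 / (2 * sf$d)),
               tolerance = 1e-12)
  expect_equal(sf$B, rep(0, nrow(sf)), tolerance = 1e-9)
})

test_that("an inversion pair gives purely real structure factors", {
  at <- data.frame(element = "C", name = "CA", resno = 1:2, resname = "ALA",
                   chain = "A", x = c(3, -3), y = c(4, -4), z = c(5, -5),
                   occ = 1, b = 5)
  m <- StructureModel(at, cell = tinyCell, spacegroup = "P1")
  sf <- reflections(structureFactors(m, generateReflections(tinyCell,
                                                            "P1", 3, 30)))
  expect_equal(max(abs(sf$B)), 0, tolerance = 1e-9)
})

test_that("structure factors are linear in occupancy and Friedel-symmetric", {
  m <- randomAtomModel(6, seed = 3)
  refl <- generateReflections(tinyCell, "P212121", 3, 30)
  full <- reflections(structureFactors(m, refl))
  a <- atoms(m)
  a$occ <- a$occ / 2
  half <- reflections(structureFactors(StructureModel(
    a, cell = m@cell, spacegroup = m@spacegroup), refl))
  expect_equal(half$F, full$F / 2, tolerance = 1e-9)
  ## F(-h) = conj(F(h))
  rec <- reflections(refl)[1:10, ]
  neg <- rec
  neg[, c("h", "k", "l")] <- -neg[, c("h", "k", "l")]
  sfp <- reflections(structureFactors(m, ReflectionSet(rec, tinyCell, "P1")))
  sfn <- reflections(structureFactors(m, ReflectionSet(neg, tinyCell, "P1")))
  expect_equal(sfn$A, sfp$A, tolerance = 1e-9)
  expect_equal(sfn$B, -sfp$B, tolerance = 1e-9)
})

test_that("amplitudes are origin-shift invariant and phases track h.t", {
  m <- randomAtomModel(5, seed = 12, sg = "P212121")
  refl <- generateReflections(tinyCell, "P212121", 3.5, 30)
  sf1 <- reflections(structureFactors(m, refl))
  shift <- c(0.5, 0, 0.5)  # allowed origin shift of P212121
  a <- atoms(m)
  M <- cellOrthMatrix(tinyCell)
  d <- as.numeric(M %*% shift)
  a$x <- a$x + d[1]; a$y <- a$y + d[2]; a$z <- a$z + d[3]
  sf2 <- reflections(structureFactors(StructureModel(
    a, cell = tinyCell, spacegroup = "P212121"), refl))
  expect_equal(sf2$F, sf1$F, tolerance = 1e-8)
  H <- as.matrix(sf1[, c("h", "k", "l")])
  dphi <- (sf2$phase - sf1$phase + 360 * as.numeric(H %*% shift)) %% 360
  expect_true(all(pmin(dphi, 360 - dphi) < 1e-4))
})

test_that("E normalization makes each shell average to one", {
  set.seed(6)
  refl <- generateReflections(tinyCell, "P212121", 2.2)
  rec <- reflections(refl)
  rec$I <- rexp(nrow(rec)) * rec$epsilon
  en <- reflections(normalizeE(ReflectionSet(rec, tinyCell, "P212121")))
  sh <- microshred:::assignShells(en$d, 20)
  expect_equal(max(abs(tapply(en$E^2, sh, mean) - 1)), 0,
               tolerance = 1e-12)
  ## constant intensities with unit epsilon give E = 1 everywhere
  rec$I <- 5
  rec <- rec[rec$epsilon == 1, ]
  en2 <- reflections(normalizeE(ReflectionSet(rec, tinyCell, "P212121")))
  expect_equal(en2$E, rep(1, nrow(en2)))
})

test_that("the L-test reproduces direct arithmetic on a small table", {
  set.seed(10)
  refl <- generateReflections(tinyCell, "P1", 3.0)
  rec <- reflections(refl)
  rec$I <- rexp(nrow(rec))
  lt <- lTest(ReflectionSet(rec, tinyCell, "P1"), offsets = 1)
  ## independent recomputation with plain loops
  key <- paste(rec$h, rec$k, rec$l, sep = ",")
  L <- c()
  for (i in seq_len(nrow(rec))) {
    for (mate in c(paste(rec$h[i], rec$k[i], rec$l[i] + 1, sep = ","),
                   paste(rec$h[i], rec$k[i] + 1, rec$l[i], sep = ","))) {
      j <- match(mate, key)
      if (!is.na(j)) L <- c(L, (rec$I[i] - rec$I[j]) / (rec$I[i] + rec$I[j]))
    }
  }
  expect_equal(lt$nPairs, length(L))
  expect_equal(lt$meanAbsL, mean(abs(L)))
  expect_equal(lt$meanL2, mean(L^2))
})

test_that("reflection TSV round-trips exactly and mmCIF reads", {
  m <- randomAtomModel(4, seed = 2)
  refl <- generateReflections(tinyCell, "P212121", 3, 30)
  sf <- structureFactors(m, refl)
  rec <- reflections(sf)
  rec$I <- rec$F^2
  rec$sigI <- 0.1 * rec$I + 1
  rs <- ReflectionSet(rec, tinyCell, "P212121")
  p <- tempfile(fileext = ".tsv")
  writeReflectionsTSV(rs, p)
  back <- readReflectionsTSV(p)
  expect_equal(reflections(back)$I, rec$I)
  expect_equal(reflections(back)$sigI, rec$sigI)
  expect_equal(back@spacegroup, "P212121")
  ## minimal structure-factor mmCIF
  p2 <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_r1sf",
    "_cell.length_a 20.0", "_cell.length_b 25.0", "_cell.length_c 30.0",
    "_cell.angle_alpha 90.0", "_cell.angle_beta 90.0",
    "_cell.angle_gamma 90.0",
    "_symmetry.space_group_name_H-M 'P 21 21 21'",
    "loop_",
    "_refln.index_h", "_refln.index_k", "_refln.index_l",
    "_refln.intensity_meas", "_refln.intensity_sigma",
    "1 2 3 100.0 5.0",
    "2 0 1 50.0 2.5"), p2)
  cifr <- readReflectionsMmcif(p2)
  expect_equal(nrow(reflections(cifr)), 2)
  expect_equal(reflections(cifr)$I, c(100, 50))
  expect_equal(cifr@spacegroup, "P212121")
})
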