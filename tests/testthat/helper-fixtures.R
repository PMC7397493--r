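## Shared fixtures, built in code.  Expensive objects are cached for the
## duration of the test run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

tinyCell <- c(20, 25, 30, 90, 90, 90)

## a random few-atom model in a P212121 frame (seeded, deterministic)
randomAtomModel <- function(n = 10, seed = 7, cell = tinyCell,
                            sg = "P212121") {
  set.seed(seed)
  at <- data.frame(
    element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
    name = "CA", resno = seq_len(n), resname = "ALA", chain = "A", ins = "",
    x = runif(n, 0, cell[1] * 0.8), y = runif(n, 0, cell[2] * 0.8),
    z = runif(n, 0, cell[3] * 0.8), occ = runif(n, 0.5, 1),
    b = runif(n, 5, 30))
  StructureModel(at, cell = cell, spacegroup = sg)
}

## straight polyalanine helix as a StructureModel
helixModel <- function(n = 20, cell = numeric(0), sg = NA_character_) {
  StructureModel(buildHelix(n), cell = cell, spacegroup = sg)
}

buildHelix <- function(n) {
  microshred:::buildBackbone(rep(-57, n), rep(-47, n))
}

## small shared P43212 ground truth + simulated data (built once)
miniTruth <- function() {
  cached("miniTruth", function() {
    makeGroundTruth(40, "helix_bundle", c(48, 48, 68, 90, 90, 90),
                    "P43212", seed = 1)
  })
}

miniSim <- function() {
  cached("miniSim", function() {
    simulateCrystals(simulationConfig(nResidues = 40, dmin = 3.0,
                                      nCrystals = 3, framesPerCrystal = 6,
                                      seed = 11))
  })
}

## naive all-symmetry direct-sum structure factors (independent oracle)
oracleStructureFactors <- function(model, refl) {
  rec <- reflections(refl)
  sg <- spaceGroupInfo(refl@spacegroup)
  a <- atoms(model)
  M <- cellOrthMatrix(refl@cell)
  frac <- as.matrix(a[, c("x", "y", "z")]) %*% t(solve(M))
  vapply(seq_len(nrow(rec)), function(i) {
    h <- as.numeric(rec[i, c("h", "k", "l")])
    s <- 1 / (2 * rec$d[i])
    Fv <- 0 + 0i
    for (o in sg$ops) {
      for (j in seq_len(nrow(a))) {
        x <- as.numeric(o$R %*% frac[j, ] + o$t)
        f <- electronFormFactor(a$element[j], s) * exp(-a$b[j] * s^2) *
          a$occ[j]
        Fv <- Fv + f * exp(2i * pi * sum(h * x))
      }
    }
    Fv
  }, complex(1))
}

## one-atom PDB fixture text
oneAtomPDB <- function(path) {
  writeLines(c(
    "CRYST1   20.000   25.000   30.000  90.00  90.00  90.00 P 1",
    paste0("ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
           "  1.00 10.00           C"),
    "END"), path)
  path
}
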