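## Internal-coordinate peptide geometry (NeRF placement).  Used both to
## reconstruct missing atoms in polyalanine conversion and to build the
## ideal-geometry folds of the synthetic-data generator.

## standard backbone internal coordinates (angstroms, degrees)
.pepGeom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  b_c_o = 1.231, b_ca_cb = 1.530,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_ca_cb = 109.5,
  t_c_n_ca_cb = 120.0  # chirality-defining torsion for L residues
)

## Place atom D given A, B, C with bond |CD|, angle B-C-D and torsion
## A-B-C-D (natural extension reference frame).
placeAtom <- function(A, B, C, bond, angleDeg, torsionDeg) {
  ang <- angleDeg * pi / 180
  tor <- torsionDeg * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## Build an all-backbone (N, CA, C, O, CB) chain from phi/psi lists.
## phi[1] and psi[n] are not used for placement of interior atoms but psi
## feeds the carbonyl O torsion; returns an atom data.frame.
buildBackbone <- function(phi, psi, omega = NULL, chain = "A", startRes = 1L) {
  g <- .pepGeom
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(omega)) omega <- rep(180, n)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N; CB <- N
  ## seed first residue in a canonical frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  a <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA[i, ] <- placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                           g$b_n_ca, g$a_c_n_ca, omega[i - 1])
      C[i, ] <- placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                          g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    CB[i, ] <- placeAtom(C[i, ], N[i, ], CA[i, ],
                         g$b_ca_cb, g$a_n_ca_cb, g$t_c_n_ca_cb)
  }
  for (i in seq_len(n)) {
    ## carbonyl O anti to the next amide N (psi + 180)
    O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ],
                        g$b_c_o, g$a_ca_c_o, psi[i] + 180)
  }
  resno <- startRes + seq_len(n) - 1L
  one <- function(mat, nm, el) {
    data.frame(element = el, name = nm, resno = resno, resname = "ALA",
               chain = chain, ins = "", x = mat[, 1], y = mat[, 2],
               z = mat[, 3], occ = 1, b = 10, stringsAsFactors = FALSE)
  }
  df <- rbind(one(N, "N", "N"), one(CA, "CA", "C"), one(C, "C", "C"),
              one(O, "O", "O"), one(CB, "CB", "C"))
  df <- df[order(df$resno, match(df$name, c("N", "CA", "C", "O", "CB"))), ]
  rownames(df) <- NULL
  df
}

## rebuild a missing C-beta at ideal tetrahedral geometry (e.g. glycine)
constructCB <- function(N, CA, C) {
  g <- .pepGeom
  placeAtom(C, N, CA, g$b_ca_cb, g$a_n_ca_cb, g$t_c_n_ca_cb)
}

## rebuild a missing carbonyl O; nextN may be NULL at a chain terminus
constructO <- function(N, CA, C, nextN = NULL) {
  g <- .pepGeom
  tor <- if (is.null(nextN)) 0 else torsionAngle(N, CA, C, nextN) + 180
  placeAtom(N, CA, C, g$b_c_o, g$a_ca_c_o, tor)
}
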