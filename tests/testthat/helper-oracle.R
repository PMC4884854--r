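# A red acceptance expectation must not silence the rest of the suite.
options(testthat.progress.max_fails = 1000L)

# Independent pure-R oracles, kept deliberately separate from the package
# implementation (which evaluates the energy in compiled code).

# polynomial strain energy from a plane-strain deformation gradient
oracle_energy <- function(p, F, isochoric = TRUE) {
  J <- det(F)
  B11 <- F[1, 1]^2 + F[1, 2]^2
  B22 <- F[2, 1]^2 + F[2, 2]^2
  B12 <- F[1, 1] * F[2, 1] + F[1, 2] * F[2, 2]
  i1 <- B11 + B22 + 1
  i2 <- (B11 * B22 - B12^2) + B11 + B22
  if (isochoric) {
    i1 <- i1 * J^(-2 / 3)
    i2 <- i2 * J^(-4 / 3)
  }
  a <- i1 - 3; b <- i2 - 3; v <- J - 1
  p$c10 * a + p$c01 * b + p$c11 * a * b + p$c20 * a^2 + p$c02 * b^2 +
    v^2 / p$d1 + v^4 / p$d2
}

# Cauchy stress by central differences of the oracle energy
oracle_cauchy <- function(p, F, h = 1e-7, isochoric = TRUE) {
  P <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (oracle_energy(p, Fp, isochoric) -
                  oracle_energy(p, Fm, isochoric)) / (2 * h)
  }
  P %*% t(F) / det(F)
}

# random admissible plane-strain deformation gradients (moderate strain)
random_F <- function(n, scale = 0.15, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      F <- diag(2) + matrix(runif(4, -scale, scale), 2, 2)
      if (det(F) > 0.5) return(F)
    }
  })
}

table1 <- function() {
  list(tumor = material_params(1.41e-3, 1.41e-3, 17.1e-2, 1.66e-2, 1.66e-2,
                               label = "tumor"),
       benign = material_params(0.375e-3, 0.375e-3, 0.0256e-1, 0.0283e-2,
                                0.0283e-2, label = "benign"))
}
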