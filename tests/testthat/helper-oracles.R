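# Independent brute-force oracles: explicit index loops written directly from
# the contraction definitions, sharing no code with the package internals.

eps3 <- function(i, j, k) (j - i) * (k - j) * (k - i) / 2

beta2_oracle <- function(alpha) {
  s1 <- 0
  s2 <- 0
  for (i in 1:3) for (j in 1:3) {
    s1 <- s1 + 3 * alpha[i, j] * alpha[i, j]
    s2 <- s2 + alpha[i, i] * alpha[j, j]
  }
  (s1 - s2) / 2
}

betaG2_oracle <- function(alpha, gprime) {
  s1 <- 0
  s2 <- 0
  for (i in 1:3) for (j in 1:3) {
    s1 <- s1 + 3 * alpha[i, j] * gprime[i, j]
    s2 <- s2 + alpha[i, i] * gprime[j, j]
  }
  (s1 - s2) / 2
}

betaA2_oracle <- function(alpha, aquad, omega) {
  s <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- s + alpha[i, j] * eps3(i, k, l) * aquad[k, l, j]
  }
  omega / 2 * s
}

# componentwise transformation oracle: alpha and A as polar tensors, G' with
# the det(R) axial factor
transform_oracle <- function(t, r) {
  al <- matrix(0, 3, 3)
  gp <- matrix(0, 3, 3)
  aq <- array(0, c(3, 3, 3))
  d <- det(r)
  for (i in 1:3) for (j in 1:3) {
    for (a in 1:3) for (b in 1:3) {
      al[i, j] <- al[i, j] + r[i, a] * r[j, b] * t$alpha[a, b]
      gp[i, j] <- gp[i, j] + d * r[i, a] * r[j, b] * t$gprime[a, b]
    }
  }
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
      aq[i, j, k] <- aq[i, j, k] +
        r[i, a] * r[j, b] * r[k, cc] * t$aquad[a, b, cc]
    }
  }
  list(alpha = al, gprime = gp, aquad = aq)
}

# random valid tensor set built directly, bypassing the fixture generator
random_raw_tensor_set <- function(wavelength_nm = 532) {
  m <- matrix(rnorm(9), 3)
  alpha <- (m + t(m)) / 2 + diag(3) * 3
  gprime <- matrix(rnorm(9), 3)
  aq <- array(rnorm(27), c(3, 3, 3))
  aq <- (aq + aperm(aq, c(1, 3, 2))) / 2
  tr <- aq[, 1, 1] + aq[, 2, 2] + aq[, 3, 3]
  for (j in 1:3) aq[, j, j] <- aq[, j, j] - tr / 3
  tensor_set(alpha, gprime, aq, wavelength_nm = wavelength_nm)
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), .Machine$double.eps)
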