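# Independent brute-force spin propagator used as the oracle for the
# production simulator.  Deliberately avoids the production code path:
# operators are rebuilt locally, the propagator is a truncated Taylor
# series of exp(-iH dt) at dt = 1 microsecond composed by (associative)
# repeated multiplication, and the FID is acquired by stepping the density
# matrix one dwell time at a time and taking the trace directly.

oracle_op <- function(mat, k, n) {
  out <- 1
  for (i in seq_len(n)) out <- kronecker(out, if (i == k) mat else diag(2))
  out
}

oracle_ix <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
oracle_iy <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
oracle_iz <- diag(c(0.5, -0.5))
oracle_ip <- matrix(c(0, 0, 1, 0), 2, 2)

oracle_hamiltonian <- function(offsets_hz, J_hz) {
  n <- length(offsets_hz)
  H <- matrix(0i, 2^n, 2^n)
  for (i in seq_len(n)) H <- H + 2 * pi * offsets_hz[i] * oracle_op(oracle_iz, i, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) if (J_hz[i, j] != 0) {
    H <- H + 2 * pi * J_hz[i, j] *
      (oracle_op(oracle_ix, i, n) %*% oracle_op(oracle_ix, j, n) +
       oracle_op(oracle_iy, i, n) %*% oracle_op(oracle_iy, j, n) +
       oracle_op(oracle_iz, i, n) %*% oracle_op(oracle_iz, j, n))
  }
  H
}

oracle_taylor_expm <- function(A, terms = 30) {
  X <- diag(nrow(A)) + 0i
  term <- X
  for (k in seq_len(terms)) {
    term <- A %*% term / k
    X <- X + term
  }
  X
}

oracle_mat_pow <- function(U, n) {
  R <- diag(nrow(U)) + 0i
  B <- U
  while (n > 0) {
    if (n %% 2 == 1) R <- R %*% B
    B <- B %*% B
    n <- n %/% 2
  }
  R
}

# FID of one coupled component under the idealized echo train, acquired at
# n_acq points of the acquisition dwell time.  Per-proton normalized like
# the production simulator (divide by 2^n / 4).
oracle_component_fid <- function(offsets_hz, J_hz, timing, acq, n_acq,
                                 dt = 1e-6) {
  n <- length(offsets_hz)
  H <- oracle_hamiltonian(offsets_hz, J_hz)
  U1 <- oracle_taylor_expm(-1i * H * dt)
  rot <- matrix(c(0, 1, -1, 0), 2, 2)    # 180 deg about y
  P <- 1
  for (i in seq_len(n)) P <- kronecker(P, rot)
  rho <- matrix(0i, 2^n, 2^n)
  for (i in seq_len(n)) rho <- rho + oracle_op(oracle_ix, i, n)
  for (k in 1:5) {
    steps <- round(timing$delays[k] / 1000 / dt)
    stopifnot(abs(timing$delays[k] / 1000 - steps * dt) < 1e-12)
    U <- oracle_mat_pow(U1, steps)
    rho <- U %*% rho %*% Conj(t(U))
    if (k < 5) rho <- P %*% rho %*% Conj(t(P))
  }
  D <- matrix(0i, 2^n, 2^n)
  for (i in seq_len(n)) D <- D + oracle_op(oracle_ip, i, n)
  dwell_steps <- round(1 / acq$spectral_width / dt)
  Udw <- oracle_mat_pow(U1, dwell_steps)
  fid <- complex(n_acq)
  for (m in seq_len(n_acq)) {
    fid[m] <- sum(diag(rho %*% D))
    if (m < n_acq) rho <- Udw %*% rho %*% Conj(t(Udw))
  }
  fid / (2^n / 4)
}

# Full-system oracle FID (sums coupled components; skips components larger
# than max_spins).
oracle_system_fid <- function(sys, timing, acq, n_acq, max_spins = 6) {
  comps <- mrsiglx:::spin_components(sys)
  fid <- complex(n_acq)
  for (idx in comps) {
    if (length(idx) > max_spins) next
    off <- (sys$shifts[idx] - acq$ref_ppm) * acq$larmor_freq
    fid <- fid + oracle_component_fid(off, sys$J[idx, idx, drop = FALSE],
                                      timing, acq, n_acq)
  }
  fid
}
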