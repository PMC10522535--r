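# Shared synthetic fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# Small noiseless session: 4x4 patch, one forward run per paradigm.
noiseless_session <- function() {
  fixture("noiseless", function() {
    patch <- generate_patch(nx = 4, ny = 4, seed = 7)
    cfg <- simulation_config(
      run_spec = list(between = c(forward = 1L, reverse = 1L),
                      within = c(forward = 1L, reverse = 1L),
                      diagonal = c(forward = 1L, reverse = 0L)),
      noise_sd = 0, seed = 3)
    sim <- simulate_session(patch, cfg)
    sim$Ypsc <- preprocess_timeseries(sim$Y, tr = cfg$tr, runs = sim$seq$runs)
    sim
  })
}

# Small noisy session at tSNR 50 (noise sd 2 on baseline 100).
noisy_session <- function() {
  fixture("noisy", function() {
    patch <- generate_patch(nx = 8, ny = 8, seed = 7)
    cfg <- simulation_config(
      run_spec = list(between = c(forward = 1L, reverse = 1L),
                      within = c(forward = 1L, reverse = 1L),
                      diagonal = c(forward = 1L, reverse = 0L)),
      noise_sd = 2, seed = 3)
    sim <- simulate_session(patch, cfg)
    sim$Ypsc <- preprocess_timeseries(sim$Y, tr = cfg$tr, runs = sim$seq$runs)
    sim
  })
}

expect_all_equal <- function(a, b, tol = 1e-8) {
  expect_equal(unname(a), unname(b), tolerance = tol)
}

# Exhaustive closed-testing oracle for the Hommel adjustment: the adjusted
# p-value of hypothesis i is the maximum, over all subsets containing i, of
# the subset's Simes combination p-value.
hommel_oracle <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  subsets <- lapply(seq_len(2^m - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
  })
  for (i in seq_len(m)) {
    worst <- 0
    for (S in subsets) {
      if (!(i %in% S)) next
      ps <- sort(p[S])
      simes <- min(length(S) * ps / seq_along(ps))
      worst <- max(worst, simes)
    }
    adj[i] <- min(1, worst)
  }
  adj
}

# Dense direct-solve oracle for the Laplace extrapolation: assemble the full
# linear system with base R and solve() it.
laplace_dense_oracle <- function(known, frame_n) {
  kb <- nrow(known)
  off <- (frame_n - kb) %/% 2
  kn <- matrix(FALSE, frame_n, frame_n)
  kn[off + seq_len(kb), off + seq_len(kb)] <- TRUE
  val <- matrix(0, frame_n, frame_n)
  val[off + seq_len(kb), off + seq_len(kb)] <- known
  unk <- which(!kn)
  A <- matrix(0, length(unk), length(unk))
  b <- numeric(length(unk))
  pos <- match(seq_len(frame_n^2), unk)
  for (u in seq_along(unk)) {
    r <- (unk[u] - 1) %% frame_n + 1
    c <- (unk[u] - 1) %/% frame_n + 1
    deg <- 0
    for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + s[1]; cc <- c + s[2]
      if (rr < 1 || rr > frame_n || cc < 1 || cc > frame_n) next
      deg <- deg + 1
      lin <- (cc - 1) * frame_n + rr
      if (kn[lin]) b[u] <- b[u] + val[lin] else A[u, pos[lin]] <- -1
    }
    A[u, u] <- deg
  }
  out <- val
  out[unk] <- solve(A, b)
  out
}

# Full-protocol 40x40 patch at tSNR 50 with 2D Gaussian fits: the
# parameter-recovery surface.
recovery_session <- function() {
  fixture("recovery", function() {
    patch <- generate_patch(nx = 40, ny = 40, seed = 7)
    cfg <- simulation_config(noise_sd = 2, seed = 3)   # tSNR 50
    sim <- simulate_session(patch, cfg)
    sim$Ypsc <- preprocess_timeseries(sim$Y, tr = cfg$tr,
                                      runs = sim$seq$runs)
    sim$fits <- fit_patch(sim$Ypsc, "gaussian2d", sim$seq)
    sim
  })
}

# Moderate patch fitted with all four families plus the travelling-wave
# reference: the pipeline-fidelity surface.
pipeline_session <- function() {
  fixture("pipeline", function() {
    patch <- generate_patch(nx = 16, ny = 16, seed = 7)
    cfg <- simulation_config(
      run_spec = list(between = c(forward = 1L, reverse = 1L),
                      within = c(forward = 1L, reverse = 1L),
                      diagonal = c(forward = 1L, reverse = 1L)),
      noise_sd = 2, seed = 3)
    sim <- simulate_session(patch, cfg)
    sim$Ypsc <- preprocess_timeseries(sim$Y, tr = cfg$tr,
                                      runs = sim$seq$runs)
    sim$fits <- fit_patch(sim$Ypsc, PRF_FAMILIES, sim$seq)
    sim$tw_between <- tw_analysis(sim$Ypsc, sim$seq, "between")
    sim$tw_within <- tw_analysis(sim$Ypsc, sim$seq, "within")
    sim
  })
}
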