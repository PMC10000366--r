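# Shared fixtures: small deterministic objects built in code.

tiny_config <- function(seed = 1L, ...) {
  synthetic_config(n_subjects = 2, trials_per_subject = 3, trial_seconds = 2,
                   eeg_fs = 128, fps = 4, frame_size = 12, seed = seed, ...)
}

random_frames <- function(n, h = 6, w = 6, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(runif(h * w), h, w))
}

# finite-difference gradient of a scalar loss over one layer parameter
fd_grad <- function(loss_fn, layer, param, idx, eps = 1e-6) {
  layer[[param]][idx] <- layer[[param]][idx] + eps
  lp <- loss_fn()
  layer[[param]][idx] <- layer[[param]][idx] - 2 * eps
  lm <- loss_fn()
  layer[[param]][idx] <- layer[[param]][idx] + eps
  (lp - lm) / (2 * eps)
}

expect_rel_equal <- function(a, b, tol = 1e-4) {
  expect_lt(abs(a - b) / max(abs(a), abs(b), 1e-8), tol)
}
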