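# Small fixtures shared across test files; everything is generated in code.

# trial table simulated from known parameters, multiple conditions
sim_trials <- function(params, n_per_cond, seed = 1, t_max = 4) {
  tabs <- lapply(seq_along(params$v), function(cc) {
    simulate_lit(params, condition = cc, n_trials = n_per_cond,
                 t_max = t_max, seed = seed + cc)$trials
  })
  out <- do.call(rbind, tabs)
  class(out) <- c("trial_table", "data.frame")
  out
}

# tiny epochs object with planted rank-1 components
toy_epochs <- function(n_trials = 40, n_ch = 8, fs = 100,
                       times = seq(-0.5, 0.1, by = 1 / 100), seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(n_trials * n_ch * length(times)),
               c(n_trials, n_ch, length(times)))
  eeg_epochs(arr, times, paste0("ch", seq_len(n_ch)), fs,
             metadata = data.frame(rt = runif(n_trials, 0.3, 1),
                                   hand = rep(c("left", "right"),
                                              length.out = n_trials)))
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
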