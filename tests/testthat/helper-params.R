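# Baseline market scenario used throughout: non-R&D cost 13 / revenue 22,
# R&D cost 18 / revenue 35.
baseline_params <- function(eta1 = 0.8, eta2 = 0.4, lam = 0.3, N = 6,
                            xi = 0.1) {
  game_params(Cpl = 13, Cph = 18, RT = 22, RI = 35,
              eta1 = eta1, eta2 = eta2, lam = lam, N = N, xi = xi)
}

# Random valid parameter draw. With chain_safe = TRUE the selection
# intensity is kept small enough that the linear fitness map stays
# positive at every interior state.
random_params <- function(chain_safe = FALSE, N_max = 25L, xi = NULL) {
  repeat {
    p <- game_params(Cpl = runif(1, 1, 20), Cph = runif(1, 1, 30),
                     RT = runif(1, 5, 40), RI = runif(1, 5, 60),
                     eta1 = runif(1), eta2 = runif(1), lam = runif(1),
                     N = sample(2:N_max, 1),
                     xi = if (is.null(xi)) runif(1, 0.001, 1) else xi)
    if (!chain_safe) return(p)
    f <- fitness(p, seq_len(p$N - 1L), "linear")
    if (all(f$e_I > 0) && all(f$e_T > 0)) return(p)
  }
}
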