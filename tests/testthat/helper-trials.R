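# Minimal trial tables for unit tests: work trials at a fixed exertion,
# rest trials at zero.
make_trials <- function(types, E = NULL) {
  if (is.null(E)) E <- ifelse(types == "work", 6, 0)
  data.frame(trial = seq_along(types), trial_type = types, exertion_E = E,
             stringsAsFactors = FALSE)
}

# Scalar reference implementation of the latent dynamics: an explicit
# trial loop over the exported single-step updates, used as an independent
# oracle for the vectorized trajectory code.
loop_trajectory <- function(alpha, delta, theta, E, t_rest, F_start) {
  RF <- UF <- numeric(length(E))
  rf <- uf <- 0
  for (t in seq_along(E)) {
    uf <- update_unrecoverable(uf, E[t], theta)
    rf <- update_recoverable(rf, E[t], t_rest[t], alpha, delta)
    RF[t] <- rf
    UF[t] <- uf
  }
  list(RF = RF, UF = UF, F = F_start + RF + UF)
}
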