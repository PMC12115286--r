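# shared generators for end-to-end tests

make_session <- function(modality, commands = evaluation_sequence(),
                         noise = 0, seed = 1L, ...) {
  subj <- subject_model(piezo_noise_sd = noise,
                        accel_noise_sd = noise * sin(30 * pi / 180),
                        seed = seed, ...)
  generate_session(command_script(commands, modality), subj, modality)
}

run_session <- function(modality, commands = evaluation_sequence(),
                        noise = 0, seed = 1L, ...) {
  ses <- make_session(modality, commands, noise, seed, ...)
  fit <- fit_session(ses, modality)
  run_pipeline(ses$trace, fit, pipeline_config(modality))
}

# a 1 s piezo window with given per-channel peaks (burst-free, deterministic)
peak_window <- function(p1, p2, p3, n = 1000) {
  mk <- function(p) { v <- numeric(n); v[n %/% 2] <- p; v }
  piezo_trace(mk(p1), mk(p2), mk(p3))
}
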