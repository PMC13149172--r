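# Shared fixture builders: everything is generated in code at test time.

# Single-trace recording (1x1 grid) with optional noise override.
sim_trace_rec <- function(rhythm, duration = 10, modality = "voltage",
                          seed = 1, waveform = NULL, noise_sd = NULL) {
  cfg <- sim_config(height = 1, width = 1, duration = duration,
                    modality = modality, waveform = waveform,
                    rhythm = rhythm, noise_sd = noise_sd, seed = seed)
  simulate_recording(cfg)
}

global_trace <- function(rec) extract_trace(rec$movie, "global")

# Analyze a recording's global trace with defaults.
quick_metrics <- function(rec) {
  tr <- preprocess_trace(global_trace(rec))
  measure_beats(tr)
}

# FD-like triangulated action-potential template (tri = 0.10 s).
fd_ap_template <- function() solve_template(0.02, 0.10, 0.20)

# Short template safe for fast rhythms.
fast_ap_template <- function() solve_template(0.02, 0.08, 0.13)
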