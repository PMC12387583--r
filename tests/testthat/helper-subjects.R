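# Deterministic observers for oracle checks: zero bias and zero noise make
# the hitting deviation equal the residual demand exactly.
noiseless_subject <- function(pfv = 18, nfv = 10, id = "T01") {
  synthetic_subject(id, pfv_amplitude = pfv, nfv_amplitude = nfv,
                    baseline_bias_mean = 0, motor_noise_sd = 0)
}

default_balloon <- function(x = 0) world_point(x, 1.6, 6)
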