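{"piezo_amp":1,"piezo_noise_sd":0.02,"blink_amp_factor":1,"tilt_angle":30,"accel_noise_sd":0.02,"burst_duration":0.3,"tilt_ramp":0.3,"tilt_hold":1,"seed":1}
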