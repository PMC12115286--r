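{"events":[{"onset":0.9,"action":"tilt_left"},{"onset":2.9,"action":"tilt_forward"},{"onset":4.9,"action":"tilt_right"},{"onset":6.9,"action":"tilt_back"},{"onset":8.9,"action":"tilt_forward"},{"onset":10.9,"action":"tilt_right"},{"onset":12.9,"action":"tilt_left"},{"onset":14.9,"action":"tilt_back"},{"onset":16.9,"action":"tilt_forward"},{"onset":18.9,"action":"tilt_left"},{"onset":20.9,"action":"tilt_back"},{"onset":22.9,"action":"tilt_right"}],"duration":24}
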