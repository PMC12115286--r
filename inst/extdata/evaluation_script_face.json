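{"events":[{"onset":1.2,"action":"wink_left"},{"onset":3.2,"action":"tongue_push"},{"onset":5.2,"action":"wink_right"},{"onset":7.2,"action":"blink"},{"onset":9.2,"action":"tongue_push"},{"onset":11.2,"action":"wink_right"},{"onset":13.2,"action":"wink_left"},{"onset":15.2,"action":"blink"},{"onset":17.2,"action":"tongue_push"},{"onset":19.2,"action":"wink_left"},{"onset":21.2,"action":"blink"},{"onset":23.2,"action":"wink_right"}],"duration":24}
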