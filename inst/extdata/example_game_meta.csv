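game_id,broadcast_duration_min,clock_duration_min,has_overtime
g01,186,60,FALSE
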