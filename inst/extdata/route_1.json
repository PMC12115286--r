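{"waypoints":[{"label":"A","x":4,"y":0,"_row":"A"},{"label":"B","x":8,"y":0,"_row":"B"},{"label":"C","x":12,"y":0,"_row":"C"},{"label":"D","x":16,"y":0,"_row":"D"},{"label":"E","x":20,"y":0,"_row":"E"}],"start":[0,0],"heading":0,"time_limit":360,"checkpoint_radius":0.5}
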