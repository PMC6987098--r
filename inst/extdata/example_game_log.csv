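game_id,position,player,event_type,event_sublabel,head_location,elevation_level,status,quarter,clock_remaining,velocity_mps,pile_count
g01,OL,OL_77,helmet,,front,3,confirmed,1,12:30,4.8,
g01,OL,OL_77,ground,,side,2,confirmed,2,08:15,3.1,
g01,OL,OL_77,shoulder,,front_boss,4,confirmed,4,10:00,5.6,
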