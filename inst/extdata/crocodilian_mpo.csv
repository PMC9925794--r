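# Species-level protected-area representation summary for the world's 28
# crocodilian species: observed Mean Percentage Overlap (MPO) with the
# IUCN category I-IV protected-area network, the mean MPO of the 1000-draw
# randomization null, the significance flag at p < 0.05 (lower / higher /
# ns), the IUCN Red List category, and the biogeographic realm.
# The observed and randomized MPO values are stored as two separate columns.
species_id,mpo_observed,mpo_randomized,flag,iucn_category,realm
Alligator mississippiensis,1.432,2.983,lower,LC,americas
Alligator sinensis,0.000,2.037,lower,CR,asia_oceania
Caiman crocodilus,6.071,2.993,higher,LC,americas
Caiman latirostris,0.946,2.992,lower,LC,americas
Caiman yacare,2.107,2.993,lower,LC,americas
Crocodylus acutus,4.166,2.990,higher,VU,americas
Crocodylus halli,0.350,2.066,lower,LC,asia_oceania
Crocodylus intermedius,5.658,2.990,higher,CR,americas
Crocodylus johnsoni,3.745,2.078,higher,LC,asia_oceania
Crocodylus mindorensis,4.631,2.040,ns,CR,asia_oceania
Crocodylus moreletii,2.519,3.006,ns,LC,americas
Crocodylus niloticus,4.120,2.410,higher,LC,africa_mideast
Crocodylus novaeguineae,3.230,2.042,higher,LC,asia_oceania
Crocodylus palustris,0.685,2.061,lower,VU,asia_oceania
Crocodylus porosus,3.527,2.055,higher,LC,asia_oceania
Crocodylus rhombifer,6.109,2.968,higher,CR,americas
Crocodylus siamensis,9.692,2.050,higher,CR,asia_oceania
Crocodylus suchus,3.376,2.396,higher,VU,africa_mideast
Gavialis gangeticus,0.515,2.052,lower,CR,asia_oceania
Mecistops cataphractus,2.057,2.413,ns,CR,africa_mideast
Mecistops leptorhynchus,3.467,2.398,higher,EN,africa_mideast
Melanosuchus niger,5.206,2.995,higher,NT,americas
Osteolaemus aftezelli,3.294,2.393,higher,EN,africa_mideast
Osteolaemus osborni,2.913,2.419,ns,VU,africa_mideast
Osteolaemus tetraspis,2.618,2.403,ns,VU,africa_mideast
Paleosuchus palpebrosus,4.543,2.992,higher,LC,americas
Paleosuchus trigonatus,6.793,2.983,higher,LC,americas
Tomistoma schlegelii,4.095,2.059,higher,VU,asia_oceania
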