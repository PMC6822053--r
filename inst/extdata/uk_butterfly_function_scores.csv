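species,B,C,P,P_Brassicaceae,P_Caryophyllaceae
Aglais io,0.125,0.699,0.116,0.074,0
Aglais urticae,0.121,0.396,0.21,0.138,0
Anthocharis cardamines,<0.001,0,<0.001,>0.001,0
Aphantopus hyperantus,0.25,0.326,0.19,0,0
Argynnis adippe,NA,0,NA,NA,NA
Argynnis aglaja,<0.001,0,<0.001,0,0
Argynnis paphia,0.002,0,0.002,0,0
Aricia agestis,<0.001,0,<0.001,0,0.001
Aricia artaxerxes,<0.001,0,<0.001,0,0
Boloria euphrosyne,<0.001,0,<0.001,0,>0.001
Boloria selene,<0.001,0,<0.001,0,>0.001
Callophrys rubi,<0.001,0,<0.001,0,>0.001
Carterocephalus palaemon,NA,0,NA,NA,NA
Celastrina argiolus,0.002,0.067,0.004,0,0
Coenonympha pamphilus,0.006,0,0.005,0,0.008
Coenonympha tullia,<0.001,0,<0.001,0,0
Colias croceus,<0.001,0,<0.001,0,0
Cupido minimus,<0.001,0,<0.001,0,0
Erebia aethiops,<0.001,0,<0.001,0,0
Erynnis tages,<0.001,0,<0.001,0,>0.001
Euphydryas aurinia,NA,0,NA,NA,NA
Gonepteryx rhamni,0.005,0.062,0.005,0.003,0
Hamearis lucina,NA,0,NA,NA,NA
Hesperia comma,<0.001,0,<0.001,0,0
Hipparchia semele,<0.001,0,<0.001,0,0
Lasiommata megera,0.001,0,0.001,0,0
Leptidea sinapis,<0.001,0,<0.001,0,0
Limenitis camilla,<0.001,0,NA,0,0
Lycaena phlaeas,0.003,0.059,0.005,0,0
Maniola jurtina,1,0.911,1,0,0
Melanargia galathea,0.009,0.099,0.008,0,0
Melitaea athalia,NA,0,NA,NA,NA
Neozephyrus quercus,<0.001,0,NA,0,>0.001
Ochlodes sylvanus,0.011,0.106,0.008,0,0.010227
Papilio machaon britannicus,<0.001,0,<0.001,0,>0.001
Pararge aegeria,0.13,0.177,0.11,0,0
Pieris napi,0.25,0.26,0.35,0.383,0
Pieris brassicae,0.612,0.923,0.627,0.250,0
Pieris rapae,0.561,0.985,0.898,0.561,0
Plebejus argus,<0.001,0,<0.001,>0.001,0
Polygonia c-album,0.031,0.18,0.029,0,0
Polyommatus bellargus,<0.001,0,NA,0,0
Polyommatus coridon,<0.001,0,NA,0,0
Polyommatus icarus,0.017,0.173,0.027,0,0
Pyrgus malvae,NA,0,NA,NA,NA
Pyronia tithonus,0.355,1,0.325,0,0
Satyrium pruni,NA,0,NA,NA,NA
Satyrium w-album,<0.001,0,<0.001,0,0
Thecla betulae,<0.001,0,<0.001,0,0
Thymelicus acteon,<0.001,0,<0.001,0,0
Thymelicus lineola,NA,0,NA,0,0
Thymelicus sylvestris,0.018,0,0.017,0,0
Vanessa atalanta,0.068,0.396,0.081,0,0
Vanessa cardui,0.013,0.071,NA,0,0
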