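taxon_name,plankton_group,size_class,carbon_factor,energy_factor,cross_class_flag
Acartia longiremis,holoplankton,SMZ,0.453,21.595,FALSE
Calanus spp.,holoplankton,LMZ,0.502,26.889,FALSE
Centropages typicus,holoplankton,SMZ,0.395,21.949,FALSE
Cladocera,holoplankton,SMZ,0.439,17.680,FALSE
Clausocalanidae,holoplankton,SMZ,0.497,21.222,FALSE
Clione larvae,holoplankton,LMZ,0.300,17.355,FALSE
Copepoda nauplii,holoplankton,SMZ,0.396,24.080,FALSE
Euphausiacea larvae,holoplankton,LMZ,0.395,13.915,FALSE
Fritillaria borealis,holoplankton,SMZ,0.545,3.868,FALSE
Hydrozoa,holoplankton,LMZ,0.101,7.864,FALSE
Limacina retroversa,holoplankton,LMZ,0.333,15.955,TRUE
Metridia longa,holoplankton,LMZ,0.510,28.549,FALSE
Oikopleura spp.,holoplankton,LMZ,0.504,3.868,TRUE
Oithona spp.,holoplankton,SMZ,0.465,18.691,FALSE
Paraeuchaeta spp.,holoplankton,LMZ,0.587,25.100,FALSE
Parasagitta elegans,holoplankton,LMZ,0.399,17.366,FALSE
Temora longicornis,holoplankton,SMZ,0.433,18.691,FALSE
Amphinomidae,meroplankton,SMZ,0.373,17.800,FALSE
Asteroidea,meroplankton,LMZ,0.130,9.944,FALSE
Bivalvia,meroplankton,SMZ,0.208,7.039,FALSE
Bryozoa,meroplankton,SMZ,0.402,8.721,FALSE
Cirripedia,meroplankton,SMZ,0.437,17.070,FALSE
Gastropoda,meroplankton,SMZ,0.335,18.335,FALSE
Ophiuroidea,meroplankton,SMZ,0.142,5.425,FALSE
Polychaeta,meroplankton,SMZ,0.373,17.800,FALSE
Decapoda zoea,meroplankton,LMZ,0.360,12.400,FALSE
Fish eggs,ichthyoplankton,LMZ,0.432,22.900,FALSE
Cod larvae,ichthyoplankton,LMZ,0.432,22.900,FALSE
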