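strain,t0,t10,surviving,chlorophyta
Aulosira terrestre,6.04,1.43,FALSE,FALSE
Calothrix membranacea,49.54,32.57,TRUE,FALSE
Chlorella vulgaris,95.68,0.49,FALSE,TRUE
Coccomyxa solorinae-saccatae,67.25,4.39,FALSE,TRUE
Coelastrella rubescens,70.34,71.00,TRUE,TRUE
Fischerella ambigua,92.54,19.13,TRUE,FALSE
Microchaete diplosiphon,95.08,88.50,TRUE,FALSE
Microcoleus autumnalis,99.17,97.20,TRUE,FALSE
Nodularia sphaerocarpa,67.25,18.00,TRUE,FALSE
Nostoc commune,81.80,86.00,TRUE,FALSE
Plectonema sp.,85.67,88.20,TRUE,FALSE
Pseudococcomyxa simplex,94.91,3.89,FALSE,TRUE
Scenedesmus communis,56.37,14.92,FALSE,TRUE
Scytonema mirabile,13.09,9.47,FALSE,FALSE
Stichococcus bacillaris,99.32,12.57,FALSE,TRUE
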