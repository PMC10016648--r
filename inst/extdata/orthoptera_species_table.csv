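species,family,n_female,n_male,c1_female_pg,c1_male_pg,gc_percent,karyotype
Bryodemella tuberculata,Acrididae,2,0,21.92,NA,42.05,22+X0
Calliptamus italicus,Acrididae,2,1,11.68,10.91,42.66,22+X0*
Euthystira brachyptera,Acrididae,2,0,17.95,NA,41.51,16+X0
Gomphocerippus rufus,Acrididae,2,0,13.18,NA,41.53,16+X0
Chorthippus albomarginatus,Acrididae,1,1,11.88,11.79,41.20,16+X0
Chorthippus apricarius,Acrididae,2,1,12.52,11.92,40.84,16+X0*
Chorthippus biguttulus,Acrididae,0,1,NA,10.99,41.80,16+X0
Chorthippus brunneus,Acrididae,0,1,NA,10.47,41.17,16+X0
Chorthippus dorsatus,Acrididae,2,1,12.59,12.80,41.39,16+X0
Chorthippus mollis,Acrididae,0,1,NA,11.58,41.50,16+X0*
Chorthippus pullus,Acrididae,1,0,13.44,NA,41.32,16+X0*
Chorthippus vagans,Acrididae,2,0,11.11,NA,41.30,16+X0
Chrysochraon dispar,Acrididae,1,1,19.43,18.76,41.43,16+X0
Locusta migratoria,Acrididae,0,1,NA,7.62,41.52,22+X0
Myrmeleotettix maculatus,Acrididae,2,0,11.83,NA,41.40,16+X0
Oedipoda caerulescens,Acrididae,2,0,14.13,NA,42.13,22+X0
Omocestus haemorrhoidalis,Acrididae,1,1,12.83,12.14,41.00,16+X0
Omocestus viridulus,Acrididae,1,1,14.03,13.28,41.11,16+X0
Pseudochorthippus montanus,Acrididae,1,1,13.12,12.42,41.22,16+X0*
Pseudochorthippus parallelus,Acrididae,2,1,13.14,12.67,41.83,16+X0
Psophus stridulus,Acrididae,0,1,NA,16.44,41.95,22+X0
Schistocerca gregaria,Acrididae,1,1,10.68,10.36,43.40,22+X0
Stenobothrus lineatus,Acrididae,1,1,14.00,13.63,41.25,16+X0
Stenobothrus nigromaculatus,Acrididae,1,1,13.18,12.48,41.05,16+X0*
Stenobothrus stigmaticus,Acrididae,1,1,11.91,11.21,41.24,16+X0*
Stethophyma grossum,Acrididae,1,0,18.51,NA,42.56,22+X0
Acheta domesticus,Gryllidae,1,1,2.88,2.63,39.13,10+X0
Gryllus assimilis,Gryllidae,1,1,2.24,2.09,38.58,28+X0
Gryllus bimaculatus,Gryllidae,1,1,2.22,1.98,38.83,28+X0
Gryllus campestris,Gryllidae,1,1,2.23,2.08,39.02,28+X0
Nemobius sylvestris,Gryllidae,1,0,2.56,NA,36.41,16+X0
Oecanthus pellucens,Gryllidae,1,1,1.44,1.37,39.97,18+XY
Tetrix subulata,Tetrigidae,0,1,NA,2.22,35.62,12+X0
Tetrix tuerki,Tetrigidae,2,0,2.37,NA,36.08,12+X0*
Tetrix undulata,Tetrigidae,1,1,2.36,2.18,35.84,12+X0
Bicolorana bicolor,Tettigoniidae,1,1,8.05,6.99,39.68,30+X0
Conocephalus dorsalis,Tettigoniidae,0,1,NA,3.52,39.32,32+X0
Conocephalus fuscus,Tettigoniidae,1,1,4.42,3.79,39.57,32+X0*
Decticus verrucivorus,Tettigoniidae,2,2,8.21,7.34,41.01,30+X0
Leptophyes punctatissima,Tettigoniidae,1,3,7.98,6.81,41.03,30+X0
Meconema meridionale,Tettigoniidae,1,1,10.69,9.90,41.23,26+X0*
Meconema thalassinum,Tettigoniidae,2,0,12.72,NA,40.85,26+X0
Metrioptera brachyptera,Tettigoniidae,1,1,8.78,7.97,39.93,30+X0
Phaneroptera falcata,Tettigoniidae,1,1,7.25,6.08,38.78,26+X0
Pholidoptera griseoaptera,Tettigoniidae,2,2,7.11,6.30,40.73,30+X0
Pholidoptera littoralis,Tettigoniidae,1,0,7.69,NA,40.20,30+X0*
Platycleis albopunctata,Tettigoniidae,2,2,6.54,5.74,39.51,30+X0*
Roeseliana roeselii,Tettigoniidae,1,3,8.30,7.70,40.30,30+X0
Tettigonia cantans,Tettigoniidae,1,1,7.16,6.34,40.89,28+X0
Tettigonia viridissima,Tettigoniidae,0,2,NA,5.69,42.88,28+X0
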