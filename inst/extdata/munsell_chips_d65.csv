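# Munsell chips used by the patch stimuli: 10 principal hues at Value 5, Chroma 2/4/6,
# plus the neutral N5. CIE 1931 xy chromaticities derived from the Munsell renotation
# colour map as distributed by the R package 'munsell' (hex sRGB -> linear RGB ->
# XYZ -> xy; sRGB is D65-native, so the neutral chip sits exactly on the D65 white
# point x=0.312727, y=0.329023). Luminance is not tabulated here: it depends on Value
# only (ASTM D1535 polynomial) and is scaled at run time.
hue,value,chroma,x,y
N,5,0,0.312727,0.329023
5R,5,2,0.342352,0.330878
5R,5,4,0.378354,0.332519
5R,5,6,0.411806,0.333884
5YR,5,2,0.355948,0.352332
5YR,5,4,0.399069,0.372658
5YR,5,6,0.443494,0.389944
5Y,5,2,0.352324,0.375483
5Y,5,4,0.391756,0.416135
5Y,5,6,0.429166,0.451827
5GY,5,2,0.330050,0.373509
5GY,5,4,0.348223,0.423231
5GY,5,6,0.363735,0.472191
5G,5,2,0.300122,0.352748
5G,5,4,0.284344,0.377253
5G,5,6,0.268765,0.402117
5BG,5,2,0.286618,0.334852
5BG,5,4,0.260544,0.339174
5BG,5,6,0.237009,0.343846
5B,5,2,0.281844,0.317416
5B,5,4,0.250666,0.301367
5B,5,6,0.222534,0.283387
5PB,5,2,0.291582,0.304925
5PB,5,4,0.268494,0.281416
5PB,5,6,0.247457,0.257228
5P,5,2,0.307715,0.305610
5P,5,4,0.302730,0.282459
5P,5,6,0.297790,0.259859
5RP,5,2,0.328488,0.318395
5RP,5,4,0.345289,0.307310
5RP,5,6,0.363210,0.294626
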