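# Antoine coefficients, convention log10(Psat/bar) = A - B/(T/K + C).
# Independently sourced from the NIST Chemistry WebBook (regressed data sets
# cited per row); validity range in kelvin.
# name: compound; smiles: structure; source: WebBook-listed regression.
name,smiles,A,B,C,T_min,T_max,P_unit,source
water,O,5.40221,1838.675,-31.737,273.20,333.15,bar,Liu and Lindsay 1970
methanol,CO,5.20409,1581.341,-33.50,288.10,356.83,bar,Ambrose and Sprake 1970
ethanol,CCO,5.24677,1598.673,-46.424,292.77,366.63,bar,Kretschmer and Wiebe 1949
acetone,CC(C)=O,4.42448,1312.253,-32.445,259.16,507.60,bar,Ambrose Sprake Townsend 1974
chloroform,ClC(Cl)Cl,4.20772,1233.129,-40.953,215.00,334.40,bar,Moelwyn-Hughes 1961
benzene,c1ccccc1,4.01814,1203.835,-53.226,287.70,354.07,bar,Willingham et al. 1945
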