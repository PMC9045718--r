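species,formula,ef_g_per_kg,carbon_atoms,mw_g_per_mol
CO2,CO2,1489,1,44.009
CO,CO,127,1,28.010
CH4,CH4,5.96,1,16.043
ethyne,C2H2,0.18,2,26.037
ethene,C2H4,1.42,2,28.053
ethane,C2H6,1.79,2,30.069
propene,C3H6,1.13,3,42.080
propane,C3H8,0.44,3,44.096
formaldehyde,CH2O,1.86,1,30.026
methanol,CH4O,1.74,1,32.042
acetic_acid,C2H4O2,4.41,2,60.052
formic_acid,CH2O2,0.57,1,46.025
acetaldehyde,C2H4O,0.77,2,44.053
acetone,C3H6O,0.75,3,58.079
methyl_ethyl_ketone,C4H8O,0.22,4,72.106
benzene,C6H6,1.11,6,78.112
toluene,C7H8,0.48,7,92.138
xylenes,C8H10,0.18,8,106.165
isoprene,C5H8,0.15,5,68.117
monoterpenes,C10H16,2.00,10,136.234
furan,C4H4O,0.80,4,68.074
phenol,C6H6O,2.96,6,94.111
glycolaldehyde,C2H4O2,0.86,2,60.052
hydroxyacetone,C3H6O2,0.75,3,74.078
butanedione,C4H6O2,0.73,4,86.089
hydrogen_cyanide,HCN,1.52,1,27.025
acetonitrile,C2H3N,0.61,2,41.052
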