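# Ingredient-level (substitution-method) energy values of the four sugarcane
# yeast samples by phase: AME, AMEn (kcal/kg DM), apparent metabolizability
# coefficients of dry matter and gross energy (%), with the published Average,
# P-value and CV columns and Tukey letters.
# NOTE (unresolved in source): the published footnote maps "1 - Yeast
# Distillery 1 (Diet C); 2 - Yeast Distillery 2 (Diet B); 3 - Yeast Distillery
# 3 (Diet D); 4 - Yeast distillery 4 (Diet 5)", conflicting with the identity
# diet legend; this file keeps the identity mapping I<->1 etc.
# The published pre-initial amc_dm_pct Average cell (73.15) repeats the Yeast
# IV cell instead of the column mean (74.11); preserved as printed.
phase,variable,I,II,III,IV,average,p_value,cv,I_letter,II_letter,III_letter,IV_letter
pre-initial,ame_kcal_kg,2090,1764,2223,1674,1937,0.001,10.438,b,c,a,d
pre-initial,amen_kcal_kg,1953,1537,2069,1566,1781,0.001,10.179,b,c,a,c
pre-initial,amc_dm_pct,73.37,70.12,79.81,73.15,73.15,0.389,3.912,,,,
pre-initial,amc_ge_pct,46.35,36.03,51.60,38.24,43.06,0.001,0.248,b,d,a,c
initial,ame_kcal_kg,1229,1802,1285,1571,1472,0.001,25.24,c,a,c,b
initial,amen_kcal_kg,1070,1670,1197,1527,1366,0.001,28.664,d,a,c,b
initial,amc_dm_pct,63.71,65.37,67.20,68.37,66.16,0.160,1.48,,,,
initial,amc_ge_pct,25.41,39.13,29.84,37.30,32.92,0.001,0.689,c,a,b,a
grower-1,ame_kcal_kg,924,961,879,986,938,0.028,18.19,ab,a,b,a
grower-1,amen_kcal_kg,803,940,698,944,846,0.001,23.382,b,a,c,a
grower-1,amc_dm_pct,60.32,58.25,77.33,67.63,65.88,0.001,2.725,b,b,a,ab
grower-1,amc_ge_pct,19.07,22.04,17.40,23.06,20.39,0.001,0.561,b,a,b,a
grower-2,ame_kcal_kg,800,1181,1422,779,1045,0.001,12.244,c,b,a,c
grower-2,amen_kcal_kg,785,1154,1408,781,1032,0.001,12.302,c,b,a,c
grower-2,amc_dm_pct,77.98,82.52,74.18,68.55,75.81,0.004,2.392,ab,a,ab,b
grower-2,amc_ge_pct,18.64,27.04,35.11,19.08,24.97,0.001,0.296,c,b,a,c
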