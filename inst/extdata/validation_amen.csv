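# Published validation table for the AMEn prediction equations: observed in
# vivo (phase-pooled) ingredient AMEn and the values predicted by equations
# 1-10, plus the published Average, SSD and mean-SSD footer rows, preserved
# exactly as printed (SSD basis undisclosed in the source; metadata only).
row,observed,eq1,eq2,eq3,eq4,eq5,eq6,eq7,eq8,eq9,eq10
Yeast 1,1153.30,1165.41,1140.18,1178.90,1183.65,1213.18,1177.59,1177.89,1177.85,1179.9,1114.64
Yeast 2,1325.80,1344.3,1328.05,1331.06,1297.65,1305.05,1344.92,1344.99,1345.06,1294.29,1340.82
Yeast 3,1326.03,1326.03,1329.35,1338.51,1342.39,1333.65,1320.27,1320.09,1322.04,1356.55,1353.13
Yeast 4,1205.0,1192.74,1230.04,1179.17,1205.94,1173.9,1185.07,1184.92,1184.88,1197.78,1215.09
average,1252.5,1257.1,1256.9,1256.9,1257.4,1256.4,1256.9,1257.4,1257.4,1257.1,1255.9
ssd,,399738.7,399738.7,399738.7,401936.8,401936.8,399914.9,399912,399908.1,400672.1,395185.3
mean_ssd,,99934.6,99934.6,99934.6,100484.2,100484.2,99978.7,99978,99977.2,100168,98796.3
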