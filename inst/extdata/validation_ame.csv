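# Published validation table for the AME prediction equations: observed in
# vivo (phase-pooled) ingredient AME and the values predicted by equations
# 1-10, plus the published Average, SSD (sum of squared deviations) and
# mean-SSD footer rows, preserved exactly as printed. The published SSD rows
# are NOT Sum((obs - pred)^2) over the four feed rows (basis undisclosed in
# the source); they are kept as metadata only.
row,observed,eq1,eq2,eq3,eq4,eq5,eq6,eq7,eq8,eq9,eq10
Yeast 1,1261.10,1219.34,1265.12,1273.1,1295.96,1271.44,1271.66,1271.71,1271.82,1276.62,1282.74
Yeast 2,1427.60,1388.73,1433.48,1437.91,1409.51,1435.76,1435.87,1435.94,1435.92,1409.22,1407.47
Yeast 3,1452.50,1414.15,1446.73,1440.53,1452.03,1442.63,1442.44,1442.39,1442.3,1460.2,1451.75
Yeast 4,1252.80,1216.34,1248.77,1242.57,1237.22,1244.33,1244.16,1244.13,1244.01,1248.63,1253.5
average,1348.5,1309.64,1348.5,1348.5,1348.7,1348.5,1348.5,1348.5,1348.5,1348.7,1348.9
ssd,,537625.3,537625.3,537625.3,538453,537712.4,537712.4,537712.4,537715.8,528258.5,539449.1
mean_ssd,,134406.3,134406.3,134406.3,134613.2,134428.1,134428.1,134428.1,134428.9,134564.6,134862.2
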