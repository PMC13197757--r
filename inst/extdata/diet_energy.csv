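# Diet-level trial summary: per-diet means of feed intake, AME, AMEn and the
# apparent metabolizability coefficients of dry matter and gross energy, with
# the published Average, P-value and SEM columns and Tukey letters, by phase.
# RD = reference diet; I-IV = RD with 30% of the like-labelled yeast sample.
# NOTE (unresolved in source): the published diet legend reads "I- RD + 30% of
# Yeast 2; II - RD + 30% of Yeast 1; III- RD + 30% of Yeast 3; IV - RD + 30%
# of Yeast 4", conflicting with the identity mapping used elsewhere; this file
# keeps the identity mapping and preserves the legend verbatim here.
# Feed intakes are grams over the 4-day collection window (thousand separators
# in the source normalized to plain numbers).
phase,variable,RD,I,II,III,IV,average,p_value,sem,RD_letter,I_letter,II_letter,III_letter,IV_letter
pre-initial,feed_intake_g,713.2,819.6,769.7,788.2,732.6,764.6,0.001,1.059,e,a,c,b,d
pre-initial,ame_kcal_kg,3186,2808,2888,2927,2776,2917,0.001,2.274,a,d,c,b,e
pre-initial,amen_kcal_kg,3009,2618,2722,2756,2618,2745,0.001,2.100,a,d,c,b,d
pre-initial,amc_dm_pct,61.63,63.89,64.82,66.52,63.53,64.08,0.213,0.506,,,,,
pre-initial,amc_ge_pct,66.95,61.53,60.72,63.03,58.58,62.16,0.001,0.048,a,c,d,b,e
initial,feed_intake_g,1690,1723,1736,1715,1673,1708,0.001,0.001,c,b,a,b,d
initial,ame_kcal_kg,3607,3127,2960,2982,3055,3146,0.001,4.667,a,b,d,d,c
initial,amen_kcal_kg,3215,2804,2631,2672,2757,2816,0.001,4.928,a,b,c,c,b
initial,amc_dm_pct,73.41,71.27,70.77,71.74,71.50,71.74,0.001,0.160,a,b,b,b,b
initial,amc_ge_pct,69.23,60.68,57.98,59.09,60.22,61.44,0.001,0.106,a,b,d,c,b
grower-1,feed_intake_g,2257,2406,2451,2458,2418,2398,0.001,1.795,c,b,a,a,b
grower-1,ame_kcal_kg,3671,2950,2924,2920,2943,3081,0.001,2.419,a,b,cd,d,bc
grower-1,amen_kcal_kg,3224,2617,2566,2544,2606,2711,0.001,2.821,a,b,c,c,b
grower-1,amc_dm_pct,79.14,73.58,74.02,78.66,75.91,76.26,0.001,0.295,a,c,c,ab,bc
grower-1,amc_ge_pct,69.47,57.37,56.91,56.30,58.17,59.64,0.001,0.062,a,c,c,c,b
grower-2,feed_intake_g,1909,2167,2099,2072,1984,2046,0.001,1.336,e,a,b,c,d
grower-2,ame_kcal_kg,3404,2813,2696,2871,2693,2895,0.001,2.009,a,c,d,b,d
grower-2,amen_kcal_kg,3356,2770,2657,2832,2658,2855,0.001,2.04,a,c,d,b,d
grower-2,amc_dm_pct,84.92,84.28,83.03,82.03,81.05,83.06,0.030,0.443,a,ab,ab,ab,b
grower-2,amc_ge_pct,66.95,61.53,60.72,63.03,58.58,62.16,0.001,0.067,a,c,d,b,e
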