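# Physicochemical composition and gross energy of four sugarcane yeast samples,
# expressed on the dry-matter basis. mgd_um is the mean geometric particle
# diameter from stacked-sieve analysis. ingredient_no is the Arabic alias used
# by the validation tables (identity mapping I<->1, II<->2, III<->3, IV<->4).
ingredient_id,ingredient_no,dm_pct,cp_pct,mm_pct,ee_pct,ndf_pct,ge_kcal_kg,mgd_um
Yeast I,1,90.71,17.11,7.54,0.37,6.86,4214,661
Yeast II,2,88.84,18.05,8.05,0.44,7.65,4268,695
Yeast III,3,89.99,14.94,9.1,0.49,3.02,4011,933
Yeast IV,4,90.47,21.12,9.0,0.30,12.13,4095,616
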