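athlete,hb_gdl,off_score,ret_pct,abps,hbmass_g,pv_ml,atl,ctl,total_tss
1,14.4,91.7,0.76,-1.47,1021,4222,317,1572,18871
2,13.5,72.9,1.07,-1.68,1021,4703,243,2234,26814
3,13.8,65.3,1.49,-1.59,1045,4751,256,1872,22466
4,15.5,86.9,1.31,-0.40,1157,3998,110,1395,16751
5,14.8,85.2,1.08,-0.91,1014,3944,524,2579,30957
6,13.3,64.4,1.32,-1.59,950,4318,583,4004,48050
7,13.4,80.3,0.80,-1.58,842,3688,237,1619,19439
8,14.3,74.1,1.32,-1.55,1116,4637,357,3174,38090
9,14.2,80.9,1.05,-1.52,1079,4417,517,2768,33223
10,14.4,64.0,1.81,-1.04,1056,4421,387,3051,36620
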