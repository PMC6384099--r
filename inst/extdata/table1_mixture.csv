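time_h,od600,glucose,rhamnose,acetate,lactate,butyrate,acetone,isopropanol,ethanol,butanol,propanediol
0,,111.2,129.3,37.3,ND,ND,ND,ND,ND,ND,ND
72,6.8,0,42.6,36.2,2.4,25.9,7.9,31.9,1.1,59.4,78.4
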