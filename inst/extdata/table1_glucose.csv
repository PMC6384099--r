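time_h,od600,glucose,acetate,lactate,butyrate,acetone,isopropanol,ethanol,butanol
0,,224.8,39.5,ND,ND,ND,ND,ND,ND
56,11.1,9.5,8.8,7.5,2.1,3.2,68.5,6,111.8
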