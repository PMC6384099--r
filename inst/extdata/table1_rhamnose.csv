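time_h,od600,rhamnose,acetate,butyrate,propanediol,propanol,propionate
0,,243.4,38.3,ND,ND,ND,ND
56,2.8,197,57.5,11.7,17.2,18.2,7.8
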