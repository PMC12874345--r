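name,ts_pct_fm,vs_pct_ts,xa,xc,xp,xl,xf,adf,ndf,adl,dq_xc
cattle_manure,3.6,75.1,249.4,586.6,124.0,48.5,,,,,0.69
deep_litter,30.7,85.0,150.0,699.3,123.7,27.0,,471.0,641.4,123.2,
maize_silage,30.1,96.7,33.4,846.1,76.0,44.5,211.4,231.8,423.1,26.5,
grass_silage,31.9,87.7,123.1,731.0,116.9,29.0,244.4,417.0,662.7,74.1,
meadow_grass,81.8,91.9,80.6,782.2,108.2,29.0,,,,61.8,
fresh_grass,10.7,88.9,111.2,713.5,146.3,29.0,267.4,,,,
straw,85.0,94.2,57.5,884.1,42.5,15.9,,,,136.9,
animal_feed_waste,32.8,90.0,100.0,731.2,117.8,51.0,200.0,,,,
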