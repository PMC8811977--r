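class,foliage,merchantable,other_wood,coarse_root,fine_root,carbon_fraction
softwood,0.030,0.42,0.14,0.090,0.012,0.5
hardwood,0.018,0.55,0.19,0.110,0.015,0.5
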