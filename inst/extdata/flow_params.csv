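class,param,pool,value
default,turnover,Foliage,0.10
hardwood,turnover,Foliage,0.95
default,turnover,Merchantable,0.0045
default,turnover,OtherWood,0.04
default,turnover,CoarseRoot,0.02
default,turnover,FineRoot,0.64
default,snag_fall,SnagStem,0.032
default,snag_fall,SnagBranch,0.10
default,bdr,SnagStem,0.0187
default,bdr,SnagBranch,0.0718
default,bdr,AbovegroundMedium,0.0374
default,bdr,AbovegroundFast,0.1435
default,bdr,AbovegroundVeryFast,0.3550
default,bdr,AbovegroundSlow,0.0150
default,bdr,BelowgroundFast,0.1435
default,bdr,BelowgroundVeryFast,0.5000
default,bdr,BelowgroundSlow,0.0050
default,p_air,SnagStem,0.83
default,p_air,SnagBranch,0.83
default,p_air,AbovegroundMedium,0.83
default,p_air,AbovegroundFast,0.83
default,p_air,AbovegroundVeryFast,0.83
default,p_air,AbovegroundSlow,1.00
default,p_air,BelowgroundFast,0.83
default,p_air,BelowgroundVeryFast,0.83
default,p_air,BelowgroundSlow,1.00
default,q10,SnagStem,2.00
default,q10,SnagBranch,2.00
default,q10,AbovegroundMedium,2.00
default,q10,AbovegroundFast,2.00
default,q10,AbovegroundVeryFast,2.65
default,q10,AbovegroundSlow,2.65
default,q10,BelowgroundFast,2.00
default,q10,BelowgroundVeryFast,2.00
default,q10,BelowgroundSlow,2.00
default,slow_transfer,AbovegroundSlow,0.006
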