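transition_type,source_pool,destination,proportion
fire_high,Foliage,atmosphere,0.90
fire_high,Foliage,AbovegroundVeryFast,0.10
fire_high,Merchantable,atmosphere,0.10
fire_high,Merchantable,SnagStem,0.90
fire_high,OtherWood,atmosphere,0.25
fire_high,OtherWood,SnagBranch,0.75
fire_high,CoarseRoot,BelowgroundFast,1.00
fire_high,FineRoot,BelowgroundVeryFast,1.00
fire_high,SnagStem,atmosphere,0.20
fire_high,SnagBranch,atmosphere,0.30
fire_high,AbovegroundMedium,atmosphere,0.40
fire_high,AbovegroundFast,atmosphere,0.60
fire_high,AbovegroundVeryFast,atmosphere,0.85
fire_high,AbovegroundSlow,atmosphere,0.08
fire_medium,Foliage,atmosphere,0.35
fire_medium,Foliage,AbovegroundVeryFast,0.15
fire_medium,Merchantable,atmosphere,0.03
fire_medium,Merchantable,SnagStem,0.12
fire_medium,OtherWood,atmosphere,0.08
fire_medium,OtherWood,SnagBranch,0.12
fire_medium,CoarseRoot,BelowgroundFast,0.05
fire_medium,FineRoot,BelowgroundVeryFast,0.10
fire_medium,SnagStem,atmosphere,0.08
fire_medium,SnagBranch,atmosphere,0.12
fire_medium,AbovegroundMedium,atmosphere,0.20
fire_medium,AbovegroundFast,atmosphere,0.35
fire_medium,AbovegroundVeryFast,atmosphere,0.50
fire_medium,AbovegroundSlow,atmosphere,0.04
fire_low,Foliage,atmosphere,0.15
fire_low,Foliage,AbovegroundVeryFast,0.10
fire_low,Merchantable,atmosphere,0.01
fire_low,Merchantable,SnagStem,0.05
fire_low,OtherWood,atmosphere,0.03
fire_low,OtherWood,SnagBranch,0.06
fire_low,CoarseRoot,BelowgroundFast,0.02
fire_low,FineRoot,BelowgroundVeryFast,0.05
fire_low,SnagStem,atmosphere,0.04
fire_low,SnagBranch,atmosphere,0.06
fire_low,AbovegroundMedium,atmosphere,0.10
fire_low,AbovegroundFast,atmosphere,0.20
fire_low,AbovegroundVeryFast,atmosphere,0.30
fire_low,AbovegroundSlow,atmosphere,0.02
clearcut,Merchantable,export,0.85
clearcut,Merchantable,AbovegroundMedium,0.15
clearcut,OtherWood,export,0.10
clearcut,OtherWood,AbovegroundFast,0.45
clearcut,OtherWood,AbovegroundMedium,0.45
clearcut,Foliage,AbovegroundVeryFast,1.00
clearcut,CoarseRoot,BelowgroundFast,1.00
clearcut,FineRoot,BelowgroundVeryFast,1.00
selection,Merchantable,export,0.25
selection,Merchantable,AbovegroundMedium,0.04
selection,OtherWood,export,0.03
selection,OtherWood,AbovegroundFast,0.13
selection,OtherWood,AbovegroundMedium,0.13
selection,Foliage,AbovegroundVeryFast,0.29
selection,CoarseRoot,BelowgroundFast,0.29
selection,FineRoot,BelowgroundVeryFast,0.29
insect_high,Foliage,AbovegroundVeryFast,0.90
insect_high,Merchantable,SnagStem,0.60
insect_high,OtherWood,SnagBranch,0.60
insect_high,CoarseRoot,BelowgroundFast,0.50
insect_high,FineRoot,BelowgroundVeryFast,0.50
insect_medium,Foliage,AbovegroundVeryFast,0.45
insect_medium,Merchantable,SnagStem,0.30
insect_medium,OtherWood,SnagBranch,0.30
insect_medium,CoarseRoot,BelowgroundFast,0.25
insect_medium,FineRoot,BelowgroundVeryFast,0.25
insect_low,Foliage,AbovegroundVeryFast,0.20
insect_low,Merchantable,SnagStem,0.10
insect_low,OtherWood,SnagBranch,0.10
insect_low,CoarseRoot,BelowgroundFast,0.08
insect_low,FineRoot,BelowgroundVeryFast,0.08
urbanization,Foliage,atmosphere,0.30
urbanization,Foliage,export,0.20
urbanization,Foliage,AbovegroundVeryFast,0.50
urbanization,Merchantable,atmosphere,0.30
urbanization,Merchantable,export,0.20
urbanization,Merchantable,AbovegroundMedium,0.50
urbanization,OtherWood,atmosphere,0.30
urbanization,OtherWood,export,0.20
urbanization,OtherWood,AbovegroundMedium,0.50
urbanization,CoarseRoot,atmosphere,0.30
urbanization,CoarseRoot,export,0.20
urbanization,CoarseRoot,BelowgroundFast,0.50
urbanization,FineRoot,atmosphere,0.30
urbanization,FineRoot,export,0.20
urbanization,FineRoot,BelowgroundVeryFast,0.50
ag_expansion,Foliage,atmosphere,0.40
ag_expansion,Foliage,export,0.15
ag_expansion,Foliage,AbovegroundVeryFast,0.45
ag_expansion,Merchantable,atmosphere,0.40
ag_expansion,Merchantable,export,0.15
ag_expansion,Merchantable,AbovegroundMedium,0.45
ag_expansion,OtherWood,atmosphere,0.40
ag_expansion,OtherWood,export,0.15
ag_expansion,OtherWood,AbovegroundMedium,0.45
ag_expansion,CoarseRoot,atmosphere,0.40
ag_expansion,CoarseRoot,export,0.15
ag_expansion,CoarseRoot,BelowgroundFast,0.45
ag_expansion,FineRoot,atmosphere,0.40
ag_expansion,FineRoot,export,0.15
ag_expansion,FineRoot,BelowgroundVeryFast,0.45
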