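level,scope,distance_km,duration_min,emissions_kg
authority,Fraser,30.6,64,4.67
authority,Interior,42.8,65.2,6.53
authority,Northern,69.4,93.8,10.59
authority,Vancouver Coastal,12.06,24.2,1.84
authority,Vancouver Island,24.4,37.8,3.72
stratum,urban,18.94,NA,2.89
stratum,rural,91.2,NA,13.92
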