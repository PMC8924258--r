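name,lat_min,lat_max,lon_min,lon_max
NE,38,48,-100,-70
SE,25,38,-100,-70
MT,25,48,-116,-100
CA,25,40,-125,-116
PNW,40,48,-125,-116
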