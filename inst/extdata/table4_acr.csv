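coil,lcod_slice8,lcod_slice9,lcod_slice10,lcod_slice11,uniformity_low,uniformity_high,ghost_top,ghost_bottom,ghost_left,ghost_right,ghost_large_roi
head_neck,1,8,9,10,702.75,759.16,20.6,21.2,33.5,40.9,733.2
torso,3,8,9,10,741.27,757.2,24.7,23.3,36.9,35,749.6
brain,8,9,10,10,2193.23,2517.25,26.4,26.1,24,21,2295.3
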