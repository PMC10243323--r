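gantry_angle,measured,dose_ALL,dose_NC,dose_NO,dose_NOC
180,71.3,71,70.7,72.8,72.9
160,70.7,70,70.4,72.4,72.2
140,69.0,69,70,69.6,69.5
120,74.2,73.4,72.6,73.2,72.9
90,83.9,83,83.4,83.4,82.9
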