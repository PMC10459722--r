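hour,pmv_operator1,pmv_operator2,pmv_operator3,pmv_operator4,illuminance,pm25,sound
9,0.191,0.191,-0.050,0.191,592.7,9.3,46.4
10,0.373,0.374,0.162,0.373,585.2,8.4,46.6
11,0.452,0.453,0.250,0.452,577.8,7.6,46.4
12,0.508,0.508,0.309,0.508,570.3,6.7,45.1
14,0.656,0.657,0.471,0.656,481.3,5.4,44.9
15,0.654,0.654,0.468,0.654,480.7,5.2,47.8
16,0.601,0.601,0.409,0.601,480.1,4.9,41.5
17,0.554,0.554,0.358,0.554,479.4,4.6,40.7
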