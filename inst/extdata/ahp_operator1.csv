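category,pm25,pmv,illuminance,sound
pm25,1,3,1/3,1/3
pmv,1/3,1,1,2
illuminance,3,1,1,3
sound,3,1/2,1/3,1
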