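category,pm25,pmv,illuminance,sound
pm25,1,1/4,3,3
pmv,4,1,4,4
illuminance,1/3,1/4,1,3
sound,1/3,1/4,1/3,1
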