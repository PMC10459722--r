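category,pm25,pmv,illuminance,sound
pm25,1,4,4,1/5
pmv,1/4,1,1,1/5
illuminance,1/4,1,1,1/5
sound,5,5,5,1
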