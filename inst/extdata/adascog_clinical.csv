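drug,dose_mg,weeks,adascog_effect
placebo,0,12,0.27
placebo,0,26,1.87
placebo,0,52,5.07
placebo,0,78,7.10
donepezil,5,12,-1.77
donepezil,5,26,-0.27
donepezil,5,52,2.87
donepezil,10,12,-2.12
donepezil,10,26,-0.64
donepezil,10,52,2.48
galantamine,8,12,-1.77
galantamine,8,26,-0.95
galantamine,8,52,1.29
galantamine,16,12,-1.96
galantamine,16,26,-1.10
galantamine,16,52,1.49
galantamine,24,12,-1.96
galantamine,24,26,-1.10
galantamine,24,52,1.49
rivastigmine,6,12,-0.66
rivastigmine,6,26,0.70
rivastigmine,6,52,3.71
rivastigmine,12,12,-1.82
rivastigmine,12,26,-0.77
rivastigmine,12,52,2.01
SB-742457,5,26,-0.22
SB-742457,15,26,-0.66
SB-742457,35,26,-1.12
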