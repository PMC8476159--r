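{"exchangeabilities":[1,2,1.5,0.9,2.4,1],"base_frequencies":[0.25,0.21,0.27,0.27],"doublet_frequencies":[0.0603672414689659,0.0603672414689659,0.0603672414689659,0.0671922687690751,0.0603672414689659,0.0603672414689659,0.0706042824171297,0.0603672414689659,0.0603672414689659,0.0706042824171297,0.0603672414689659,0.0603672414689659,0.0671922687690751,0.0603672414689659,0.0603672414689659,0.0603672414689659],"d":0.65,"alpha":0.45,"gamma_categories":4}
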