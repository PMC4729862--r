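# preset: alt-equal-conductance scheme, wild-type proxy trial
variant: "alt-equal-conductance"
trial: 7
seed: 1
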