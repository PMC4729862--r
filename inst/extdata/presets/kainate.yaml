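# preset: kainate scheme, wild-type proxy trial
variant: "kainate"
trial: 7
seed: 1
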