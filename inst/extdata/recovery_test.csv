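sample,analyte,added,measured
1,LA,34,32
2,LA,50,49
3,LA,78,84
4,LA,97,102
1,HMF,148,130
2,HMF,123,144
3,HMF,165,173
4,HMF,200,188
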