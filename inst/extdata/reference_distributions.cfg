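taxon: C. obtusa
mu: 408
sigma: 145
support_lo: 0
support_hi: 4500

taxon: C. japonica
mu: 662
sigma: 257
support_lo: 0
support_hi: 4500
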