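marker allele1 allele2 ind1 ind1 ind1 ind2 ind2 ind2 ind3 ind3 ind3
chr2_136608646 0 1 0.9421 0.0565 0.0014 0.0100 0.4900 0.5000 0.3333 0.3333 0.3334
chr11_89011046 0 1 0.0021 0.1201 0.8778 0.6000 0.3000 0.1000 0.2500 0.5000 0.2500
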