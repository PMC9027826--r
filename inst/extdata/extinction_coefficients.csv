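wavelength_nm,hbo,hbr
760,1486.5865,3843.707
850,2526.391,1798.643
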