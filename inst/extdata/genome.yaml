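# Chromosome-level units analysed in the crossing design (approximate
# scaffold sizes); 2L and 2R are separate units.
chromosomes:
  - {name: X,  length: 30600000}
  - {name: 2L, length: 11000000}
  - {name: 2R, length: 16000000}
  - {name: '3', length: 24000000}
  - {name: '4', length: 26000000}
  - {name: '5', length: 26000000}
map_length_cM: 50
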