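# Base-pair list for the L1-stalk helical-axis trace (E. coli 23S
# numbering), proximal to distal: helix H75 (2083-2090 paired with
# 2236-2229), then helix H76 (2093 onward paired with 2196 downward).
# The unpaired 2091-2092 linker carries no axis point; internal G-U and
# mismatch pairs are treated as pairs for tracing purposes. Users may
# override with their own pairing table.
version: 1
pairs:
  - [2083, 2236]
  - [2084, 2235]
  - [2085, 2234]
  - [2086, 2233]
  - [2087, 2232]
  - [2088, 2231]
  - [2089, 2230]
  - [2090, 2229]
  - [2093, 2196]
  - [2094, 2195]
  - [2095, 2194]
  - [2096, 2193]
  - [2097, 2192]
  - [2098, 2191]
  - [2099, 2190]
  - [2100, 2189]
  - [2101, 2188]
  - [2102, 2187]
  - [2103, 2186]
  - [2104, 2185]
  - [2105, 2184]
  - [2106, 2183]
  - [2107, 2182]
  - [2108, 2181]
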