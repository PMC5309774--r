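# Expected-interaction catalogs (E. coli 23S/16S numbering). Chain keys
# (rrna23s, rrna16s, s7, s11, s13, l1, trna) are bound to actual chain ids
# per structure at evaluation time.
version: 1
catalogs:
  b9:
    - name: "G2141(H78)-S11"
      a: {chain: rrna23s, residues: [2141]}
      b: {chain: s11}
    - name: "G2116(H77)-S7"
      a: {chain: rrna23s, residues: [2116]}
      b: {chain: s7}
    - name: "G2148(H78)-S7"
      a: {chain: rrna23s, residues: [2148]}
      b: {chain: s7}
    - name: "L1-S13"
      a: {chain: l1}
      b: {chain: s13}
  b7a:
    - name: "H68(1846-1848)-h23(A702)"
      a: {chain: rrna23s, residues: [1846, 1847, 1848]}
      b: {chain: rrna16s, residues: [700, 701, 702, 703, 704]}
  h68-h75:
    - name: "H68(A1853/A1854)-H75"
      a: {chain: rrna23s, residues: [1853, 1854]}
      b: {chain: rrna23s, residues: [2083, 2084, 2085, 2086, 2087, 2088,
                                     2089, 2090, 2229, 2230, 2231, 2232,
                                     2233, 2234, 2235, 2236]}
    - name: "H68(A1889/A1890)-H75"
      a: {chain: rrna23s, residues: [1889, 1890]}
      b: {chain: rrna23s, residues: [2083, 2084, 2085, 2086, 2087, 2088,
                                     2089, 2090, 2229, 2230, 2231, 2232,
                                     2233, 2234, 2235, 2236]}
  h68-trna:
    - name: "H68(1850-1852)-tRNA(acceptor)"
      a: {chain: rrna23s, residues: [1850, 1851, 1852]}
      b: {chain: trna, residues: [1, 2, 3, 4, 70, 71, 72]}
    - name: "H68(1891-1893)-tRNA(acceptor)"
      a: {chain: rrna23s, residues: [1891, 1892, 1893]}
      b: {chain: trna, residues: [1, 2, 3, 4, 70, 71, 72]}
  h68-h76:
    - name: "H68(1856)-H76(G-U region)"
      a: {chain: rrna23s, residues: [1856]}
      b: {chain: rrna23s, residues: [2098, 2099, 2100, 2101, 2102, 2187,
                                     2188, 2189, 2190, 2191]}
    - name: "H68(1886-1888)-H76(G-U region)"
      a: {chain: rrna23s, residues: [1886, 1887, 1888]}
      b: {chain: rrna23s, residues: [2098, 2099, 2100, 2101, 2102, 2187,
                                     2188, 2189, 2190, 2191]}
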