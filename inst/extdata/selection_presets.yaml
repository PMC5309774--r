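# Residue-selection presets (author numbering: E. coli 23S rRNA for
# bacterial presets, S. cerevisiae 25S/28S numbering for the eukaryotic
# core). Version 1.
version: 1
presets:
  bacterial-23s-core:
    description: >
      Conserved static core of bacterial 23S rRNA used for whole-subunit
      superposition.
    ranges:
      - [173, 269]
      - [292, 344]
      - [372, 542]
      - [552, 626]
      - [657, 926]
      - [938, 1053]
      - [1108, 1373]
      - [1375, 1412]
      - [1425, 1478]
      - [1552, 1579]
      - [1587, 1718]
      - [1744, 1859]
      - [1882, 1906]
      - [1930, 2088]
      - [2227, 2787]
  eukaryotic-28s-core:
    description: >
      Conserved static core of eukaryotic 28S (25S) rRNA used for
      whole-subunit superposition.
    ranges:
      - [16, 114]
      - [180, 234]
      - [270, 433]
      - [626, 704]
      - [788, 1062]
      - [1109, 1228]
      - [1282, 1554]
      - [1583, 1622]
      - [1653, 1705]
      - [1780, 1807]
      - [1819, 1948]
      - [2101, 2219]
      - [2225, 2249]
      - [2273, 2430]
      - [2596, 3150]
  l1-mobile-h76:
    description: Mobile domain of the L1 stalk (helix H76).
    ranges:
      - [2093, 2109]
      - [2181, 2196]
  l1-static-h75:
    description: Static domain at the base of the L1 stalk (helix H75).
    ranges:
      - [2083, 2090]
      - [2229, 2236]
  h76-gu-region:
    description: G-U-rich bending zone within helix H76.
    ranges:
      - [2098, 2102]
      - [2187, 2191]
  h68:
    description: Helix H68 of 23S rRNA (minor-groove interaction hub).
    ranges:
      - [1836, 1896]
markers:
  bacterial: {resno: 2127, atom: P}
  eukaryotic: {resno: 2469, atom: P}
groove:
  bacterial:
    a: {resno: 2093, atom: P}
    b: {resno: 2189, atom: P}
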