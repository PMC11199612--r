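{
  "_comment": "Required catalytic-residue patterns (R regex) per domain kind, used by detect_inactive_domains: a domain whose sequence lacks its pattern is flagged inactive. Patterns follow the canonical catalytic motifs: KR Rossmann NADPH-binding GxGxxG, DH HxxxGxxxxP active site, ER NADPH-binding GxGxxA, AT/TE GxSxG nucleophile elbow, KS active-site cysteine in GPxxxxxxC context.",
  "KR": "G.G..G",
  "DH": "H...G....P",
  "ER": "G.G..A",
  "AT": "G.S.G",
  "TE": "G.S.G",
  "KS": "GP......C"
}
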