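# Golden-Gate adapter configuration for cloning pegRNA parts into a
# BsmBI-digested U6 pegRNA acceptor vector. Overhangs are config values:
# adjust them to match your acceptor's sticky ends. Each oligo pair is
# top = top5 + payload + top3, bottom = bottom5 + revcomp(payload) + bottom3.
spacer:
  top5: "CACC"
  top3: "GTTTT"
  bottom5: ""
  bottom3: ""
scaffold:
  payload: "AGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC"
  top5: ""
  top3: ""
  bottom5: "AAAA"
  bottom3: ""
extension:
  top5: "GTGC"
  top3: ""
  bottom5: "AAAA"
  bottom3: ""
nicking:
  top5: "CACC"
  top3: ""
  bottom5: "AAAC"
  bottom3: ""
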