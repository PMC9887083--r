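# Three-fragment design plan over GLP-1(7-36): overlapping 14-mers with
# three hotspot residues each.
fragments:
- start: 7
  end: 20
  hotspots: [7, 9, 12]
- start: 12
  end: 25
  hotspots: [13, 15, 19]
- start: 23
  end: 36
  hotspots: [28, 29, 32]
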