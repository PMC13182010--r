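# Glycoside hydrolase family -> polymer capability map.
# GH18 (chitinases), GH5/GH9/GH6 (cellulases) and GH2 (xylan-active) are
# anchored by the primary analysis; the remaining families follow a
# standard curation of polymer-active GH classes and can be overridden.
polymers:
  agar:      [GH16, GH50, GH86, GH118]
  cellulose: [GH5, GH6, GH9]
  chitin:    [GH18, GH19, GH20]
  pectin:    [GH28]
  xylan:     [GH2, GH10, GH11, GH43]
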