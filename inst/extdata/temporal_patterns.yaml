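# Bundled temporal patterns for Historical detection.
#
# A condition is Recent when at most 2 weeks old; duration patterns
# therefore only match beyond the 14-day bound (>= 15 dagen, >= 3 weken,
# any number of maanden/jaar).  Guards veto a match when a relational
# operator sits next to the number ("als <3 weken niet beter" is an
# instruction, not a history) or when "net"/"recent" marks the event as
# fresh.
- id: status-na
  regex: "\\bstatus na\\b|\\bst\\.?\\s*na\\b"
  side: left
  window_tokens: 5
- id: duration-ago
  regex: "\\b(?:1[5-9]|[2-9][0-9]|[0-9]{3,})\\s*(?:dagen|dag)\\s+geleden\\b|\\b(?:[3-9]|[1-9][0-9]+)\\s*(?:weken|week)\\s+geleden\\b|\\b[1-9][0-9]*\\s*(?:maanden|maand|jaar|jaren)\\s+geleden\\b"
  side: either
  window_tokens: 6
  guard: "[<>]=?\\s*[0-9]|\\bnet\\b|\\brecent\\b"
- id: bare-duration
  regex: "\\b(?:1[5-9]|[2-9][0-9]|[0-9]{3,})\\s*(?:dagen|dag)\\b|\\b(?:[3-9]|[1-9][0-9]+)\\s*(?:weken|week)\\b|\\b[1-9][0-9]*\\s*(?:maanden|maand|jaar|jaren)\\b"
  side: either
  window_tokens: 10
  guard: "[<>]=?\\s*[0-9]|\\bnet\\b|\\brecent\\b"
- id: sinds-duration
  regex: "\\bsinds\\s+(?:[3-9]|[1-9][0-9]+)\\s*(?:weken|week)\\b|\\bsinds\\s+[1-9][0-9]*\\s*(?:maanden|maand|jaar|jaren)\\b"
  side: either
  window_tokens: 6
  guard: "[<>]=?\\s*[0-9]"
- id: in-verleden
  regex: "\\bin het verleden\\b"
  side: either
  window_tokens: 6
- id: als-kind
  regex: "\\bals kind\\b"
  side: either
  window_tokens: 6
- id: voorgeschiedenis
  regex: "\\bvoorgeschiedenis\\b"
  side: either
  window_tokens: 6
- id: year-mention
  regex: "\\bin\\s+((?:19|20)[0-9]{2})\\b"
  side: either
  window_tokens: 6
  requires_reference: true
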