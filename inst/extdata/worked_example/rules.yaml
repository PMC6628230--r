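version: worked-example-rules-1
enzymes:
- name: Tryptic
  clauses:
  - p1:
    - K
    - R
    block:
      P1':
      - P
- name: PostC
  clauses:
  - p1:
    - C
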