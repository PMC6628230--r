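# Protease specificity rules.
#
# One entry per enzyme; each clause may give `p1` (residues required
# immediately N-terminal to the scissile bond), `p1prime` (required at
# P1'), `require` (position -> residue set that must be present) and
# `block` (position -> residue set that must be absent). Positions run
# P4..P4'; the token "-" denotes a position beyond the chain termini.
#
# The specificities are authored from public PeptideCutter/BIOPEP-style
# conventions and, for sparsely documented food-science proteases
# (V-protease, proteinase P1, ginger protease, endopeptidase II), from
# the closest literature description. They are documented approximations:
# exact agreement with any particular web service's internal rule set is
# not guaranteed.
version: "pepsilico-rules-1.0"
enzymes:
  - name: "Chymotrypsin A"
    clauses:
      - p1: ["F", "Y"]
        block: {"P1'": ["P"]}
      - p1: ["W"]
        block: {"P1'": ["M", "P"]}
  - name: "Trypsin"
    clauses:
      - p1: ["K", "R"]
        block: {"P1'": ["P"]}
  - name: "Pepsin"
    clauses:
      - p1: ["F", "L"]
        block: {"P1'": ["P"], "P2": ["P"]}
      - p1prime: ["F", "L"]
        block: {"P1": ["P", "H", "K", "R"]}
  - name: "Proteinase K"
    clauses:
      - p1: ["A", "E", "F", "I", "L", "T", "V", "W", "Y"]
        block: {"P1'": ["P"]}
  - name: "Pancreatic elastase"
    clauses:
      - p1: ["A", "G", "S", "V"]
        block: {"P1'": ["P"]}
  - name: "Prolyl oligopeptidase"
    clauses:
      - p1: ["P"]
        block: {"P1'": ["P"]}
  - name: "V-protease"
    clauses:
      - p1: ["V"]
        block: {"P1'": ["P"]}
  - name: "Thermolysin"
    clauses:
      - p1prime: ["A", "F", "I", "L", "M", "V"]
        block: {"P1": ["D", "E"], "P2'": ["P"]}
  - name: "Chymotrypsin C"
    clauses:
      - p1: ["F", "L", "M", "W", "Y", "Q", "N"]
        block: {"P1'": ["P"]}
  - name: "Plasmin"
    clauses:
      - p1: ["K", "R"]
        block: {"P1'": ["P"]}
  - name: "Cathepsin"
    clauses:
      - p1: ["F", "L", "W", "Y"]
        block: {"P1'": ["P"]}
  - name: "Clostripain"
    clauses:
      - p1: ["R"]
  - name: "Chymase"
    clauses:
      - p1: ["F", "W", "Y"]
        block: {"P1'": ["P"]}
  - name: "Papain"
    clauses:
      - require: {"P2": ["A", "F", "I", "L", "V", "W", "Y"]}
        block: {"P1'": ["P"]}
  - name: "Ficin"
    clauses:
      - require: {"P2": ["A", "F", "G", "I", "L", "V"]}
        block: {"P1'": ["P"]}
  - name: "Leukocyte elastase"
    clauses:
      - p1: ["A", "I", "T", "V"]
        block: {"P1'": ["P"]}
  - name: "Metridin"
    clauses:
      - p1: ["F", "W", "Y"]
        block: {"P1'": ["P"]}
  - name: "Thrombin"
    clauses:
      - p1: ["R"]
        require: {"P2": ["G"], "P1'": ["G"]}
      - p1: ["R"]
        require: {"P2": ["P"], "P3": ["A", "F", "G", "I", "L", "T", "V", "M"],
                  "P4": ["A", "F", "G", "I", "L", "T", "V", "M"]}
        block: {"P1'": ["D", "E"], "P2'": ["D", "E"]}
  - name: "Pancreatic elastase II"
    clauses:
      - p1: ["F", "L", "M"]
        block: {"P1'": ["P"]}
  - name: "Bromelain"
    clauses:
      - p1: ["A", "G", "K", "R", "Y"]
        block: {"P1'": ["P"]}
  - name: "Endopeptidase II"
    clauses:
      - p1: ["E"]
        require: {"P1'": ["A", "G", "S", "V"]}
        block: {"P2": ["P"], "P2'": ["P"]}
  - name: "Oligopeptidase B"
    clauses:
      - p1: ["K", "R"]
        block: {"P1'": ["P"]}
  - name: "Calpain 2"
    clauses:
      - require: {"P2": ["F", "L", "V", "W"]}
        block: {"P1'": ["P"]}
      - p1: ["K", "M", "R", "Y"]
        block: {"P1'": ["P"]}
  - name: "Glycyl endopeptidase"
    clauses:
      - p1: ["G"]
        block: {"P1'": ["P"]}
  - name: "Oligopeptidase F"
    clauses:
      - p1: ["F", "L"]
  - name: "Proteinase P1 (lactocepin)"
    clauses:
      - p1: ["A", "F", "L", "M", "Q", "W", "Y"]
        block: {"P1'": ["P"]}
  - name: "Xaa-Pro dipeptidase"
    clauses:
      - p1prime: ["P"]
        require: {"P2": ["-"], "P2'": ["-"]}
  - name: "Pepsin (pH > 2)"
    clauses:
      - p1: ["F", "L", "W", "Y"]
        block: {"P1'": ["P"], "P2": ["P"]}
      - p1prime: ["F", "L", "W", "Y"]
        block: {"P1": ["P", "H", "K", "R"]}
  - name: "Cocolysin"
    clauses:
      - p1prime: ["F", "I", "L", "M", "V"]
        block: {"P1": ["D", "E"]}
  - name: "Subtilisin"
    clauses:
      - p1: ["A", "F", "L", "M", "W", "Y"]
        block: {"P1'": ["P"]}
  - name: "Chymosin"
    clauses:
      - p1: ["F"]
        p1prime: ["M"]
  - name: "Ginger protease (zingipain)"
    clauses:
      - require: {"P2": ["P"]}
        block: {"P1'": ["P"]}
  - name: "V-8 protease (Glutamyl endopeptidase)"
    clauses:
      - p1: ["D", "E"]
        block: {"P1'": ["P"]}
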