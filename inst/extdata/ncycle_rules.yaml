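# Transformation rules over nitrogen intermediates. Each rule licenses an
# edge substrate -> product for genomes whose census flag for `group` is
# TRUE (or whose homolog count is positive, for count groups). Hydrazine
# synthase consumes two substrates and is written as two rules. Rules
# marked hypothetical encode proposed hao-like homolog activities and are
# disabled unless requested.
rules:
  - group: amoCABDE
    from: "NH3"
    to: "NH2OH"
  - group: hao
    from: "NH2OH"
    to: "NO2-"
  - group: nxrAB_anammox
    from: "NO2-"
    to: "NO3-"
    reversible: true
    note: AnAOB-attributed NO3- source
  - group: nxr_canonical
    from: "NO2-"
    to: "NO3-"
  - group: narGHIJ
    from: "NO3-"
    to: "NO2-"
  - group: napAB
    from: "NO3-"
    to: "NO2-"
  - group: nirS
    from: "NO2-"
    to: "NO"
  - group: nirK
    from: "NO2-"
    to: "NO"
  - group: nirBD
    from: "NO2-"
    to: "NH4+"
  - group: nrfHA
    from: "NO2-"
    to: "NH4+"
  - group: norBC
    from: "NO"
    to: "N2O"
  - group: norZ
    from: "NO"
    to: "N2O"
  - group: nosZ_cladeI
    from: "N2O"
    to: "N2"
  - group: nosZ_cladeII
    from: "N2O"
    to: "N2"
  - group: hzsABC
    from: "NO"
    to: "N2H4"
  - group: hzsABC
    from: "NH4+"
    to: "N2H4"
  - group: hdh
    from: "N2H4"
    to: "N2"
  - group: hao_like
    from: "NH2OH"
    to: "NO"
    hypothetical: true
    note: proposed hao-like homolog activity
  - group: hao_like
    from: "NO2-"
    to: "NO"
    hypothetical: true
    note: proposed hao-like homolog activity
  - group: hao_like
    from: "NO2-"
    to: "NH2OH"
    hypothetical: true
    note: proposed hao-like homolog activity
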