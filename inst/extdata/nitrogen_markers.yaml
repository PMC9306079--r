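# Nitrogen-cycle marker-gene census groups. `required` genes must all be
# present (catalytic core only); `accessory` subunits are recorded but not
# required. `label` adds a per-gene metadata requirement (phylogenetic
# class derived upstream, e.g. from gene trees): a gene only satisfies a
# labelled group when its annotation carries that label. `count_prefix`
# marks homolog-counting pseudo-groups.
groups:
  amoCABDE:
    required: [amoA, amoB, amoC]
    accessory: [amoD, amoE]
  hao:
    required: [hao]
  hao_like:
    count_prefix: hao_like
  hzsABC:
    required: [hzsA, hzsB, hzsC]
  hdh:
    required: [hdh]
  nxrAB_anammox:
    required: [nxrA, nxrB]
    label: anammox
  nxr_like_periplasmic:
    required: [nxrA]
    label: periplasmic
  nxr_canonical:
    required: [nxrA]
    label: canonical
  narGHIJ:
    required: [narG, narH]
    accessory: [narI, narJ]
  napAB:
    required: [napA]
    accessory: [napB]
  nirS:
    required: [nirS]
  nirK:
    required: [nirK]
  nirBD:
    required: [nirB, nirD]
  nrfHA:
    required: [nrfA, nrfH]
  norBC:
    required: [norB, norC]
  norZ:
    required: [norZ]
  nosZ_cladeI:
    required: [nosZ]
    label: cladeI
  nosZ_cladeII:
    required: [nosZ]
    label: cladeII
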