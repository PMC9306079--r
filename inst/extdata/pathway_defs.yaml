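# Declarative pathway definitions: amino-acid and B-vitamin biosynthesis
# and carbon-fixation pathways. Each step lists alternative enzymes; a
# step is present when any one is encoded. Step lists are a pathway-
# committed reconstruction (shared trunk reactions are represented inside
# one pathway only) modelled on KEGG module granularity.
- pathway_id: alanine
  category: amino_acid
  steps:
    - [alaA, avtA]
- pathway_id: arginine
  category: amino_acid
  steps:
    - [argA]
    - [argB]
    - [argC]
    - [argD]
    - [argE]
    - [argF]
    - [argG]
    - [argH]
- pathway_id: asparagine
  category: amino_acid
  steps:
    - [asnA, asnB]
- pathway_id: aspartate
  category: amino_acid
  steps:
    - [aspC]
- pathway_id: cysteine
  category: amino_acid
  steps:
    - [cysE]
    - [cysK, cysM]
- pathway_id: glutamate
  category: amino_acid
  steps:
    - [gdhA, gltB]
- pathway_id: glutamine
  category: amino_acid
  steps:
    - [glnA]
- pathway_id: glycine
  category: amino_acid
  steps:
    - [glyA]
- pathway_id: histidine
  category: amino_acid
  steps:
    - [hisG]
    - [hisE]
    - [hisI]
    - [hisA]
    - [hisH, hisF]
    - [hisB]
    - [hisC]
    - [hisD]
- pathway_id: isoleucine
  category: amino_acid
  steps:
    - [ilvA]
    - [ilvB, ilvI]
    - [ilvC]
    - [ilvD]
    - [ilvE]
- pathway_id: leucine
  category: amino_acid
  steps:
    - [leuA]
    - [leuC]
    - [leuB]
    - [ilvE, tyrB]
- pathway_id: lysine
  category: amino_acid
  steps:
    - [dapA]
    - [dapB]
    - [dapD]
    - [dapE]
    - [dapF]
    - [lysA]
- pathway_id: methionine
  category: amino_acid
  steps:
    - [metA]
    - [metB]
    - [metC]
    - [metE, metH]
- pathway_id: phenylalanine
  category: amino_acid
  steps:
    - [aroG, aroF]
    - [aroB]
    - [aroD]
    - [aroE]
    - [aroA]
    - [aroC]
    - [pheA]
- pathway_id: proline
  category: amino_acid
  steps:
    - [proB]
    - [proA]
    - [proC]
- pathway_id: serine
  category: amino_acid
  steps:
    - [serA]
    - [serC]
    - [serB]
- pathway_id: threonine
  category: amino_acid
  steps:
    - [thrA, lysC]
    - [asd]
    - [hom]
    - [thrB]
    - [thrC]
- pathway_id: tryptophan
  category: amino_acid
  steps:
    - [trpE]
    - [trpD]
    - [trpC]
    - [trpA]
    - [trpB]
- pathway_id: tyrosine
  category: amino_acid
  steps:
    - [tyrA]
    - [tyrB, aspC]
- pathway_id: valine
  category: amino_acid
  steps:
    - [ilvB, ilvI]
    - [ilvC]
    - [ilvD]
    - [ilvE]
- pathway_id: B1
  category: b_vitamin
  steps:
    - [thiC]
    - [thiD]
    - [thiE]
    - [thiG]
    - [thiL]
- pathway_id: B2
  category: b_vitamin
  steps:
    - [ribA]
    - [ribD]
    - [ribH]
    - [ribE]
- pathway_id: B3
  category: b_vitamin
  steps:
    - [nadB]
    - [nadA]
    - [nadC]
- pathway_id: B5
  category: b_vitamin
  steps:
    - [panB]
    - [panD]
    - [panC]
- pathway_id: B6
  category: b_vitamin
  steps:
    - [pdxA]
    - [pdxJ]
    - [pdxH]
- pathway_id: B7
  category: b_vitamin
  steps:
    - [bioF]
    - [bioA]
    - [bioD]
    - [bioB]
- pathway_id: B9
  category: b_vitamin
  steps:
    - [folE]
    - [folB]
    - [folK]
    - [folP]
    - [folC]
    - [folA]
- pathway_id: B12
  category: b_vitamin
  steps:
    - [cbiL]
    - [cbiF]
    - [cbiG]
    - [cbiA]
    - [cobT]
    - [cobS]
    - [cobU]
    - [cobC]
- pathway_id: cbb
  category: carbon_fixation
  steps:
    - [rbcL]
    - [prkB]
  key_genes: [rbcL, prkB]
- pathway_id: wl
  category: carbon_fixation
  steps:
    - [fhs]
    - [acsA]
    - [acsB]
  key_genes: [acsA, acsB]
- pathway_id: rtca
  category: carbon_fixation
  steps:
    - [aclA]
    - [aclB]
    - [korA]
    - [korB]
  key_genes: [aclA, aclB]
- pathway_id: hp3
  category: carbon_fixation
  steps:
    - [mcr]
    - [pcs]
  key_genes: [mcr]
- pathway_id: hp3hb4
  category: carbon_fixation
  steps:
    - [abfD]
  key_genes: [abfD]
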