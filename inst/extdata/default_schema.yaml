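# Default schema for a semantic drug-target network: 10 node classes linked
# by 12 edge types. Edit a copy and load it with read_schema() to change the
# vocabulary.
node_classes:
  - Compound
  - Target
  - GOTerm
  - Pathway
  - Substructure
  - Tissue
  - SideEffect
  - Disease
  - ChemicalOntology
  - GeneFamily
edge_types:
  bind: [Compound, Target]
  express: [Compound, Target]
  hasGO: [Target, GOTerm]
  hasPathway: [Target, Pathway]
  hasTissue: [Target, Tissue]
  PPI: [Target, Target]
  hasGeneFamily: [Target, GeneFamily]
  hasSubstructure: [Compound, Substructure]
  hasSideEffect: [Compound, SideEffect]
  hasChemicalOntology: [Compound, ChemicalOntology]
  treats: [Compound, Disease]
  similarTo: [Compound, Compound]
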