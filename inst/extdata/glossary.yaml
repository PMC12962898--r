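# Placeholder heading glossaries (user-replaceable). Matching is exact on
# the normalized phrase.
metabolite:
  - key metabolites
  - key compounds
  - core components
  - key active ingredients
  - main active compounds
target:
  - key targets
  - core targets
  - hub targets
  - hub genes
  - core genes
pathway:
  - key pathways
  - core pathways
  - main enriched pathways
  - top kegg pathways
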