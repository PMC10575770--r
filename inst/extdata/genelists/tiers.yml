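# Synthetic fixture subsets of the public tier databases: just enough
# symbols to tier the bundled prioritisation table. Point read_tier_sources()
# at full database downloads for real analyses.
tier1:
  SFARI: sfari_subset.txt
  DDG2P: ddg2p_subset.txt
  DBDGD: dbdgd_subset.txt
tier2:
  AutDB: autdb_subset.txt
tier3:
  SynaptomeDB: synaptomedb_subset.txt
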