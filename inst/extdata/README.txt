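eukaryote_tree.nwk / pld_presence.tsv

Phylum/class-level rooted consensus tree of eukaryotes (30 tips; labelled
internal clades: M Metazoa, C Cnidaria, D Deuterostomia, P Protostomia,
S Spiralia, E Ecdysozoa, A Arthropoda, H Hexapoda) and per-taxon
presence/absence annotations of the ST-like and Aquatic GDPD-like
SMase D/PLD gene families, compiled from published genome and transcriptome
surveys of the family. The topology follows current organismal consensus:
ctenophore-first Metazoa; Anthozoa vs Medusozoa within Cnidaria; a platyzoan
(Rotifera + Platyhelminthes) clade within Spiralia; Mandibulata
(Myriapoda + Pancrustacea) sister to Chelicerata; Allotriocarida
(Branchiopoda + Hexapoda) vs Multicrustacea (Malacostraca + Copepoda).
Presence states are at the displayed taxon resolution; finer within-taxon
variation (e.g. among anthozoan orders or bdelloid rotifer genera) is not
encoded here.
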