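(Amoebozoa,(Fungi,(Ichthyosporea,(Choanoflagellata,(Ctenophora,(Porifera,(Placozoa,((Anthozoa,(Staurozoa,(Cubozoa,(Scyphozoa,Hydrozoa))))C,((Echinodermata,Chordata)D,(((Rotifera,Platyhelminthes),(Annelida,(Mollusca,Brachiopoda)))S,(Nematoda,(Priapulida,(Onychophora,(Tardigrada,(Chelicerata,(Myriapoda,((Malacostraca,Copepoda),(Branchiopoda,(Collembola,Insecta)H))))A))))E)P)))))M))))Eukaryota;
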