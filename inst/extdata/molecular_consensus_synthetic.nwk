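((Lissemys_scutata,(Lissemys_punctata,Lissemys_ceylonensis)),((Cyclanorbis_elegans,Cyclanorbis_senegalensis),(Cycloderma_aubryi,Cycloderma_frenatum)),((Trionyx_triunguis,((Apalone_ferox,(Apalone_mutica,Apalone_spinifera)),(Rafetus_euphraticus,Rafetus_swinhoei))),(Pelodiscus_sp,(((Chitra_indica,(Chitra_chitra,Chitra_vandijki)),(Pelochelys_cantorii,(Pelochelys_bibroni,Pelochelys_signifera))),((Dogania_subplana,Palea_steindachneri),((Amyda_cartilaginea,Amyda_ornata),(Nilssonia_formosa,(Nilssonia_leithii,(Nilssonia_gangetica,(Nilssonia_hurum,Nilssonia_nigricans))))))))));
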