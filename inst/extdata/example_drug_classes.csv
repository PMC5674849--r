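perturbagen,drug_class
Docetaxel,TUBB
Ixabepilone,TUBB
Bortezomib,Proteasome
Disulfiram,Proteasome
Trametinib,MAPK
Vorinostat,HDAC
Cisplatin,DNA cross-linker
Chloroquine,N/A
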