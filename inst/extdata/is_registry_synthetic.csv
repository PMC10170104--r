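name,polarity,mz,rt_rp,rt_hilic,detected_rp,detected_hilic,compound_subclass,role,spike_group,hmdb_id,kegg_id
Tryptophan-d5,POS,210.128,139,452,TRUE,TRUE,Indolyl carboxylic acids,IS,1,,
Palmitic acid-d31,NEG,286.417,598,72,TRUE,FALSE,Fatty acids,IS,1,,
Glucose-d7,NEG,186.100,26,475,TRUE,FALSE,Carbohydrates,IS,1,,
Trimipramine-d3,POS,298.263,352,118,TRUE,TRUE,Dibenzazepines,IS,2,,
Glibenclamide,POS,494.151,498,130,TRUE,TRUE,Sulfonylureas,IS,2,,
Bisoprolol-d5,POS,331.248,310,240,TRUE,TRUE,Phenol ethers,IS,3,,
Telmisartan-d7,POS,522.295,470,150,TRUE,TRUE,Benzimidazoles,IS,3,,
Hydrochlorothiazide,NEG,295.957,150,210,TRUE,TRUE,Benzothiadiazines,IS,3,,
Furosemide,NEG,329.001,330,180,TRUE,TRUE,Sulfonamides,IS,3,,
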