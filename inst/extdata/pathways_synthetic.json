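{
  "Aminoacyl-tRNA biosynthesis": {
    "members": ["C00062", "C00152", "C00049", "C00025", "C00064", "C00135",
                "C00123", "C00047", "C00073", "C00079", "C00078", "C00082"],
    "edges": []
  },
  "Arginine biosynthesis": {
    "members": ["C00025", "C00064", "C00049", "C00062", "C00327", "C00077",
                "C00169", "C00122", "C03406"],
    "edges": [["C00064", "C00025"], ["C00025", "C00077"],
              ["C00077", "C00327"], ["C00169", "C00327"],
              ["C00327", "C03406"], ["C00049", "C03406"],
              ["C03406", "C00062"], ["C03406", "C00122"]]
  },
  "Phenylalanine, tyrosine and tryptophan biosynthesis": {
    "members": ["C00251", "C00254", "C00108", "C00078", "C00166", "C00079",
                "C01179", "C00082"],
    "edges": [["C00251", "C00254"], ["C00251", "C00108"],
              ["C00108", "C00078"], ["C00254", "C00166"],
              ["C00166", "C00079"], ["C00254", "C01179"],
              ["C01179", "C00082"]]
  },
  "Alanine, aspartate and glutamate metabolism": {
    "members": ["C00049", "C00152", "C00025", "C00064", "C00026", "C00041",
                "C00122", "C00042"],
    "edges": [["C00049", "C00152"], ["C00049", "C00025"],
              ["C00025", "C00064"], ["C00025", "C00026"],
              ["C00026", "C00041"], ["C00049", "C00122"],
              ["C00122", "C00042"]]
  },
  "Purine metabolism": {
    "members": ["C00130", "C00294", "C00262", "C00385", "C00212", "C00366"],
    "edges": [["C00130", "C00294"], ["C00130", "C00212"],
              ["C00212", "C00294"], ["C00294", "C00262"],
              ["C00262", "C00385"], ["C00385", "C00366"]]
  },
  "Lysine degradation": {
    "members": ["C00047", "C00449", "C00956", "C03793", "C01181"],
    "edges": [["C00047", "C00449"], ["C00449", "C00956"],
              ["C00047", "C03793"], ["C03793", "C01181"]]
  },
  "Pyrimidine metabolism": {
    "members": ["C00475", "C00299", "C00106"],
    "edges": [["C00475", "C00299"], ["C00299", "C00106"]]
  },
  "Nicotinate and nicotinamide metabolism": {
    "members": ["C00153", "C00253", "C00003"],
    "edges": [["C00253", "C00153"], ["C00153", "C00003"]]
  },
  "Glycolysis and gluconeogenesis": {
    "members": ["C00031", "C00668", "C00085", "C00022"],
    "edges": [["C00031", "C00668"], ["C00668", "C00085"],
              ["C00085", "C00022"]]
  },
  "Glycerophospholipid metabolism": {
    "members": ["C00670", "C00114", "C00588"],
    "edges": [["C00670", "C00114"], ["C00114", "C00588"]]
  },
  "Sphingolipid metabolism": {
    "members": ["C00195", "C00319", "C00550"],
    "edges": [["C00195", "C00319"], ["C00195", "C00550"]]
  }
}
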