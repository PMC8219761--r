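{
  "_comment": "Synthetic pathway library: fixture analogues of small-molecule pathways with undirected topology. Compound sets and edges are fixture constants designed to exercise hit mapping, hypergeometric enrichment and betweenness-based impact; they are not a curated database.",
  "pathways": [
    {
      "name": "phenylalanine_tyrosine_tryptophan_biosynthesis",
      "compounds": ["chorismate", "prephenate", "tyrosine", "phenylalanine"],
      "edges": [["chorismate", "prephenate"], ["prephenate", "tyrosine"],
                ["tyrosine", "phenylalanine"]]
    },
    {
      "name": "pyruvate_metabolism",
      "compounds": ["pyruvic_acid", "lactic_acid", "acetic_acid",
                    "acetyl_coa", "oxaloacetate", "malate", "acetaldehyde",
                    "ethanol", "acetyl_phosphate", "pm_c01", "pm_c02",
                    "pm_c03", "pm_c04", "pm_c05", "pm_c06", "pm_c07",
                    "pm_c08", "pm_c09", "pm_c10", "pm_c11", "pm_c12",
                    "pm_c13"],
      "edges": [["pyruvic_acid", "lactic_acid"], ["pyruvic_acid", "acetic_acid"],
                ["pyruvic_acid", "acetyl_coa"], ["pyruvic_acid", "oxaloacetate"],
                ["pyruvic_acid", "malate"], ["pyruvic_acid", "acetaldehyde"],
                ["pyruvic_acid", "ethanol"], ["pyruvic_acid", "acetyl_phosphate"],
                ["pyruvic_acid", "pm_c01"], ["pyruvic_acid", "pm_c02"],
                ["pyruvic_acid", "pm_c03"], ["pyruvic_acid", "pm_c04"],
                ["pyruvic_acid", "pm_c05"], ["pyruvic_acid", "pm_c06"],
                ["pyruvic_acid", "pm_c07"], ["pyruvic_acid", "pm_c08"],
                ["pyruvic_acid", "pm_c09"], ["pyruvic_acid", "pm_c10"],
                ["pyruvic_acid", "pm_c11"], ["pyruvic_acid", "pm_c12"],
                ["pyruvic_acid", "pm_c13"]]
    },
    {
      "name": "glycolysis_gluconeogenesis",
      "compounds": ["glucose", "glucose_6_phosphate", "fructose_6_phosphate",
                    "phosphoenolpyruvate", "pyruvic_acid", "lactic_acid"],
      "edges": [["glucose", "glucose_6_phosphate"],
                ["glucose_6_phosphate", "fructose_6_phosphate"],
                ["fructose_6_phosphate", "phosphoenolpyruvate"],
                ["phosphoenolpyruvate", "pyruvic_acid"],
                ["phosphoenolpyruvate", "lactic_acid"]]
    },
    {
      "name": "alanine_aspartate_glutamate_metabolism",
      "compounds": ["asparagine", "aspartate", "oxaloacetate_aag",
                    "glutamate", "alanine"],
      "edges": [["asparagine", "aspartate"], ["aspartate", "oxaloacetate_aag"],
                ["oxaloacetate_aag", "glutamate"], ["aspartate", "alanine"]]
    },
    {
      "name": "valine_leucine_isoleucine_biosynthesis",
      "compounds": ["acetolactate", "ketoisovalerate", "valine",
                    "ketoisocaproate", "leucine"],
      "edges": [["acetolactate", "ketoisovalerate"],
                ["ketoisovalerate", "valine"],
                ["ketoisovalerate", "ketoisocaproate"],
                ["ketoisocaproate", "leucine"]]
    },
    {
      "name": "valine_leucine_isoleucine_degradation",
      "compounds": ["valine", "leucine", "isoleucine", "ketoisovalerate_d",
                    "ketoisocaproate_d", "ketomethylvalerate_d"],
      "edges": [["valine", "ketoisovalerate_d"],
                ["ketoisovalerate_d", "ketoisocaproate_d"],
                ["ketoisocaproate_d", "leucine"],
                ["isoleucine", "ketomethylvalerate_d"],
                ["ketomethylvalerate_d", "ketoisovalerate_d"]]
    },
    {
      "name": "tyrosine_metabolism",
      "compounds": ["tyrosine", "hydroxyphenylpyruvate", "homogentisate",
                    "fumarylacetoacetate", "tyramine_s"],
      "edges": [["tyrosine", "hydroxyphenylpyruvate"],
                ["hydroxyphenylpyruvate", "homogentisate"],
                ["homogentisate", "fumarylacetoacetate"],
                ["fumarylacetoacetate", "tyramine_s"]]
    },
    {
      "name": "phenylalanine_metabolism",
      "compounds": ["phenylalanine_m", "phenylpyruvate", "phenylacetate",
                    "tyrosine"],
      "edges": [["phenylalanine_m", "phenylpyruvate"],
                ["phenylpyruvate", "phenylacetate"],
                ["phenylalanine_m", "tyrosine"]]
    },
    {
      "name": "ketone_body_metabolism",
      "compounds": ["acetoacetate", "hydroxybutyrate", "acetone_kb",
                    "acetyl_coa_kb", "acetic_acid"],
      "edges": [["acetyl_coa_kb", "acetoacetate"],
                ["acetoacetate", "hydroxybutyrate"],
                ["acetoacetate", "acetone_kb"],
                ["acetyl_coa_kb", "acetic_acid"]]
    },
    {
      "name": "fatty_acid_biosynthesis",
      "compounds": ["acetic_acid", "acetyl_coa_fa", "malonyl_coa",
                    "palmitate", "stearate"],
      "edges": [["acetic_acid", "acetyl_coa_fa"],
                ["acetyl_coa_fa", "malonyl_coa"],
                ["malonyl_coa", "palmitate"], ["palmitate", "stearate"]]
    },
    {
      "name": "glutathione_metabolism",
      "compounds": ["glutathione", "cysteine_g", "glutamate_g", "glycine_g",
                    "alanine"],
      "edges": [["cysteine_g", "glutathione"], ["glutamate_g", "glutathione"],
                ["glycine_g", "glutathione"], ["glutathione", "alanine"]]
    },
    {
      "name": "selenocompound_metabolism",
      "compounds": ["selenide", "selenocysteine", "selenomethionine",
                    "alanine"],
      "edges": [["selenide", "selenocysteine"],
                ["selenocysteine", "selenomethionine"],
                ["selenocysteine", "alanine"]]
    },
    {
      "name": "citrate_cycle",
      "compounds": ["citrate_t", "isocitrate", "ketoglutarate", "succinate",
                    "fumarate", "malate_t", "oxaloacetate_t", "pyruvic_acid"],
      "edges": [["citrate_t", "isocitrate"], ["isocitrate", "ketoglutarate"],
                ["ketoglutarate", "succinate"], ["succinate", "fumarate"],
                ["fumarate", "malate_t"], ["malate_t", "oxaloacetate_t"],
                ["oxaloacetate_t", "pyruvic_acid"]]
    },
    {
      "name": "propanoate_metabolism",
      "compounds": ["propionate", "propionyl_coa", "methylmalonyl_coa",
                    "succinyl_coa", "lactic_acid"],
      "edges": [["propionate", "propionyl_coa"],
                ["propionyl_coa", "methylmalonyl_coa"],
                ["methylmalonyl_coa", "succinyl_coa"],
                ["propionate", "lactic_acid"]]
    },
    {
      "name": "glyoxylate_dicarboxylate_metabolism",
      "compounds": ["glyoxylate", "glycolate", "oxalate", "glycine_gd",
                    "acetic_acid"],
      "edges": [["glyoxylate", "glycolate"], ["glyoxylate", "oxalate"],
                ["glyoxylate", "glycine_gd"], ["glycolate", "acetic_acid"]]
    },
    {
      "name": "aminoacyl_trna_biosynthesis",
      "compounds": ["alanine", "valine", "leucine", "tyrosine", "trna_pool",
                    "glutamine_at", "glycine_at"],
      "edges": [["alanine", "trna_pool"], ["valine", "trna_pool"],
                ["leucine", "trna_pool"], ["tyrosine", "trna_pool"],
                ["glutamine_at", "trna_pool"], ["glycine_at", "trna_pool"]]
    },
    {
      "name": "butanoate_metabolism",
      "compounds": ["butyrate", "butyryl_coa", "acetoacetyl_coa",
                    "hydroxybutyrate_b", "acetic_acid"],
      "edges": [["butyrate", "butyryl_coa"],
                ["butyryl_coa", "acetoacetyl_coa"],
                ["acetoacetyl_coa", "hydroxybutyrate_b"],
                ["butyryl_coa", "acetic_acid"]]
    }
  ]
}
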