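{
  "id": "toycell",
  "version": "1",
  "compartments": {"c": "cytosol"},
  "metabolites": [
    {"id": "glc_c", "name": "glucose", "compartment": "c"},
    {"id": "gal_c", "name": "galactose", "compartment": "c"},
    {"id": "g6p_c", "name": "hexose 6-phosphate", "compartment": "c"},
    {"id": "ru5p_c", "name": "ribulose 5-phosphate", "compartment": "c"},
    {"id": "r5p_c", "name": "ribose 5-phosphate", "compartment": "c"},
    {"id": "prpp_c", "name": "phosphoribosyl pyrophosphate", "compartment": "c"},
    {"id": "nrg_c", "name": "energy equivalent", "compartment": "c"},
    {"id": "hem_c", "name": "heme-like cofactor", "compartment": "c"},
    {"id": "aa_c", "name": "amino-acid pool", "compartment": "c"}
  ],
  "reactions": [
    {"id": "EX_glc", "name": "glucose uptake", "metabolites": {"glc_c": 1}, "lower_bound": 0, "upper_bound": 10, "gene_reaction_rule": ""},
    {"id": "EX_gal", "name": "galactose uptake", "metabolites": {"gal_c": 1}, "lower_bound": 0, "upper_bound": 4, "gene_reaction_rule": ""},
    {"id": "HXK", "name": "hexokinase", "metabolites": {"glc_c": -1, "g6p_c": 1}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "hxk1 or hxk2"},
    {"id": "GALU", "name": "galactose utilisation", "metabolites": {"gal_c": -1, "g6p_c": 1}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "gal1"},
    {"id": "GLY", "name": "glycolysis (lumped)", "metabolites": {"g6p_c": -1, "nrg_c": 2}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "pyk1"},
    {"id": "ZWF", "name": "oxidative PPP entry", "metabolites": {"g6p_c": -1, "ru5p_c": 1}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "zwf1"},
    {"id": "RKI", "name": "ribose-5-phosphate isomerase", "metabolites": {"ru5p_c": -1, "r5p_c": 1}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "rki1"},
    {"id": "PRS", "name": "PRPP synthetase", "metabolites": {"r5p_c": -1, "nrg_c": -1, "prpp_c": 1}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "prs1"},
    {"id": "AAS", "name": "amino-acid synthesis (lumped)", "metabolites": {"g6p_c": -1, "nrg_c": -1, "aa_c": 1}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "aas1"},
    {"id": "HEM", "name": "heme-like cofactor synthesis", "metabolites": {"g6p_c": -1, "nrg_c": -2, "hem_c": 1}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "hem2 and hem15"},
    {"id": "DM_hem", "name": "cofactor drain", "metabolites": {"hem_c": -1}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": ""},
    {"id": "NGAM", "name": "non-growth maintenance", "metabolites": {"nrg_c": -1}, "lower_bound": 1, "upper_bound": 1, "gene_reaction_rule": ""},
    {"id": "OVF", "name": "hexose overflow", "metabolites": {"g6p_c": -1}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": ""},
    {"id": "GROWTH", "name": "biomass", "metabolites": {"prpp_c": -0.5, "aa_c": -0.5, "nrg_c": -2}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "", "objective_coefficient": 1}
  ],
  "genes": [
    {"id": "hxk1", "name": "hxk1"}, {"id": "hxk2", "name": "hxk2"},
    {"id": "gal1", "name": "gal1"}, {"id": "pyk1", "name": "pyk1"},
    {"id": "zwf1", "name": "zwf1"}, {"id": "rki1", "name": "rki1"},
    {"id": "prs1", "name": "prs1"}, {"id": "aas1", "name": "aas1"},
    {"id": "hem2", "name": "hem2"}, {"id": "hem15", "name": "hem15"}
  ]
}
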