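{
  "version": 1,
  "comment": "Default Karplus parameterization. 'basic_default' is a generic three-coefficient vicinal H,H set; 'extended_default' is the generalized Haasnoot-Altona-type H-C-C-H set. 'lambda' holds group electronegativity differences relative to hydrogen (Huggins scale, beta-substituent corrected) for the fragment substituent types used by the pyranose chair templates. All entries may be overridden by passing a user registry file.",
  "basic_default": { "form": "basic", "A": 7.76, "B": -1.10, "C": 1.40 },
  "extended_default": { "form": "extended", "P1": 13.70, "P2": -0.73, "P3": 0.0, "P4": 0.56, "P5": -2.47, "P6": 16.9 },
  "lambda": {
    "OH": 1.30,
    "O_ring": 1.24,
    "N_anilino": 0.79,
    "C_ring": 0.16,
    "C_exo": 0.22,
    "H": 0.0
  }
}
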