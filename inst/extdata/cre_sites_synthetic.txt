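# Synthetic stand-in training sites for the catabolite responsive element
# (cre) PWM. 14-nt pseudo-palindromic sites around the degenerate consensus
# TGWAARCGYTWWCA (W = A/T, R = A/G, Y = C/T). These are constructed
# fixtures, not experimentally determined sites; supply a real site list to
# build_pwm()/run_pipeline() for biological use.
TGAAAGCGCTTTCA
TGTAAACGCTATCA
TGAAAACGTTTACA
TGTAAGCGCTTTCA
TGAAAGCGTTATCA
TGTAAACGCTTTCA
AGAAAGCGCTTACA
TGAAAGCGCTTTCT
TGTAAGCGTTATCA
TGAAAACGCTTTCA
TGTAAACGTTTTCA
TGAAAGCGCTATCA
TGTAAGCGCTAACA
TGAAAACGCTTACA
TGTAAACGCTTTGA
TCAAAGCGCTTTCA
TGAAAGCGGTTTCA
TGTAAGCGCTTTCG
TGAAATCGCTATCA
TGTAAACGCGTTCA
TGAAAGCCCTTTCA
TGTAAGCGCTTTCA
TGAAAGCGCTTTAA
TGTAAACGCTATCA
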