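# [EK]_N alpha-helix calibration: CD-derived helical residue counts vs
# measured amide I' transition dipole strength (D^2), replicate SDs.
label,helical_residues,tds_D2,tds_sd_D2
EK1,0,0.13,0.005
EK2,5.9,0.15,0.01
EK3,13.2,0.21,0.02
EK4,20.2,0.26,0.03
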