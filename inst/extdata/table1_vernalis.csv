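ligand_id,k_on,k_off,kd_nM,dgqb_pfrosst,sd_pfrosst,dgqb_gaff,sd_gaff,single_measurement
VER37655,4.3e5,2.2e-2,51.2,10.9,0.5,9.7,0.1,FALSE
VER49181,4.6e6,6.1e-3,1.33,14.3,1.3,13,0.4,FALSE
VER49007,4.89e5,2.3e-2,47,14.3,0.6,12.1,0.9,FALSE
VER49008,1.4e6,1.1e-2,7.86,14.8,0.7,12.25,0.8,FALSE
VER49009,9.9e5,6.9e-3,6.97,15.05,0.7,11.9,1.0,FALSE
VER45862,1.40e6,1.49e-1,106,16.1,0.3,16.7,0.4,TRUE
VER45861,1.28e5,1.02e-2,79.7,14.2,0.6,14.4,0.3,TRUE
VER50589,8.2e5,4.05e-4,0.494,15,0.6,15.5,0.6,FALSE
VER53003,1.16e6,3.25e-4,0.280,17.6,0.6,16.2,0.4,FALSE
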