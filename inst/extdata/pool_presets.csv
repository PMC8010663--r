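# Frozen solute pool presets for 7 T CEST simulation (implementation defaults
# from the CEST literature; room-temperature phantom regime, rates quoted at
# pH 7.4). delta_ppm: shift vs water; protons_per_molecule: labile protons;
# k_exch: exchange rate to water (s^-1); T1/T2 in s.
name,delta_ppm,protons_per_molecule,k_exch,T1,T2
glucose,1.2,5,2500,1.0,0.01
creatine,1.9,4,950,1.0,0.01
glutamate,3.0,3,5500,1.0,0.008
gaba,2.75,3,6000,1.0,0.008
choline,0.9,1,1000,1.0,0.02
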