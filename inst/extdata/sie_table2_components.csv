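system,polymer,E_vdw,E_coul,E_rf,E_cav,dG
MrCut1,PES,-54.84,-6.20,11.64,-10.53,-9.17
MrCut1,PCL,-50.70,-15.20,18.23,-10.63,-9.00
MrCut1,PET,-47.65,-7.72,11.34,-8.54,-8.40
MrCut3,PES,-48.06,-19.38,-10.82,-9.20,-7.99
MrCut3,PCL,-40.19,29.32,-23.19,-8.03,-7.30
MrCut3,PET,-46.02,-3.12,9.67,-8.86,-7.95
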