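sample_id,pH,Mg,K,Ca,Cl,SO4,H2S,CO2,CH4,H2
IGT1,5.2,5.3,18.005,18.728,528.9,2.77,5.67,10.58,74.7,0.747
IGT2,5.6,15.9,16.215,16.784,530.7,8.31,4.41,8.74,58.1,0.581
IGT3,6.1,26.5,14.425,14.84,532.5,13.85,3.15,6.9,41.5,0.415
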