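drug,cyp,cc,fu_p,rb,observed_clh_mean,observed_clh_sd,n_reports
coumarin,2A6,5.369,0.055,1,1602.5,547.9,1
paclitaxel,2C8,18.938,0.098,0.69,496.4,210.5,6
dextromethorphan,2D6,35.791,0.5,0.55,6471.7,5596.7,1
chlorzoxazone,2E1,4.152,0.028,0.55,131.4,40.1,5
midazolam,3A4/5,0.54,0.042,0.54,426.7,95.4,3
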