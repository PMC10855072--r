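model,group,n_cells
orthotopic,core,36677
orthotopic,margin,41439
kpc,KPC1,12249
kpc,KPC2,14612
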