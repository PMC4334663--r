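map,roi,r
MT,TE1.0,0.3818
MT,TE1.1,0.3212
MT,TE1.2,0.5273
MT,TE3,0.1394
MT,Patt,0.3091
MT,Post,0.4424
R1,TE1.0,0.5030
R1,TE1.1,0.4303
R1,TE1.2,0.6000
R1,TE3,0.4424
R1,Patt,0.4909
R1,Post,0.2970
R2star,TE1.0,0.3576
R2star,TE1.1,0.5152
R2star,TE1.2,0.3818
R2star,TE3,0.3091
R2star,Patt,0.5879
R2star,Post,0.5273
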