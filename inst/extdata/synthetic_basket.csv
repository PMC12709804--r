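indication,n,y
cholangio,20,9
breast,16,5
pancreatic,15,3
glioma_low,7,2
prostate,9,0
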