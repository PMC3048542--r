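region,lower,value,upper
North Africa/Middle East,15.01%,17.36%,19.71%
"Sub-Saharan Africa, Central",3.00%,4.25%,5.50%
"Sub-Saharan Africa, East",12.07%,14.24%,16.41%
"Sub-Saharan Africa, South",19.11%,21.67%,24.22%
"Sub-Saharan Africa, West",11.36%,13.47%,15.59%
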