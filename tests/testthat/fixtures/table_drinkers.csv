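region,men_15-34,men_35-54,men_55+,women_15-34,women_35-54,women_55+
North Africa/Middle East,7.2%,12.0%,5.5%,3.5%,1.1%,0.4%
"Sub-Saharan Africa, Central",51.0%,51.9%,20.5%,32.4%,28.5%,11.9%
"Sub-Saharan Africa, East",24.6%,38.8%,37.2%,16.1%,24.9%,21.4%
"Sub-Saharan Africa, South",38.0%,38.0%,29.5%,12.6%,15.7%,9.8%
"Sub-Saharan Africa, West",36.2%,50.9%,40.5%,20.8%,31.2%,27.1%
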