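symbol,value,ci
P_na,40.1%,(36.9% to 43.3%)
RR_drink,1.82,(1.63 to 2.04)
RR_na,3.13,(1.95 to 5.05)
HR_nontreat,2.63,(1.92 to 3.57)
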